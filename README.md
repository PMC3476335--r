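# releasewise

Version-aware access to Ensembl-style relational genome-annotation
databases: one installation that reads multiple schema releases
transparently, projects annotations across coordinate-system levels,
stitches genomic DNA from hierarchical assemblies, and performs
cross-schema variant and homology lookups. It is aimed at anyone who needs
reproducible access to *archived* annotation releases — comparing a gene's
coordinates across releases, re-running an old analysis against the data
it originally saw — without installing one API per release.

## The core idea

Ensembl-style schemas change between releases (multi-species coordinate
systems at release 51, a supported variation schema from 62, the stable-id
table merge at 65). `releasewise` keeps every SQL statement in named
*mapping sets* — directories of query templates — and resolves the set for
a database from a declarative rules file:

```
core.51-64=57        # templates written for the release-57 layout
core.65-66=65        # refreshed after the stable_id merge
compara.51-66=57
variation.62-66=62
```

A mapping set may import an older one and override only the queries a
migration touched; set `65` overrides exactly five of set `57`'s ten core
queries. Databases whose release resolves to no set are excluded from the
registry with a logged reason — unknown schemas are never guessed at.

Coordinates are 1-based closed intervals with strand ±1. Assembly rows map
`asm[s..e]` onto `cmp[s'..e']` with orientation `ori` (AGP-style: `ori=-1`
aligns the first assembled base to `cmp_end`); projection emits component
intervals with strand `query × ori` plus explicit gap segments, and
sequence retrieval recurses down to the unique sequence-level coordinate
system, reverse-complementing minus segments and filling gaps with `N`.

## Worked example

The package generates its own miniature fixture datasource — six SQLite
databases spanning releases 49–70 in the supported schema dialects:

```r
library(releasewise)

dir <- tempfile()
reference_fixture(dir)
cat <- catalog_from_dir(dir)
#> catalog: excluding testus_exemplaris_core_49_1 (no mapping set configured for core release 49)
#> catalog: excluding testus_exemplaris_core_70_3 (release 70 post-dates the configured mappings)
cat
#> <genome_catalog> 4 database(s), 2 excluded
#>   raw_name                         db_type   schema_release mapping_set_id
#> 1 ensembl_compara_66               compara               66 57
#> 2 testus_exemplaris_core_60_1      core                  60 57
#> 3 testus_exemplaris_core_66_2      core                  66 65
#> 4 testus_exemplaris_variation_66_2 variation             66 62
```

Release 60 binds dialect "57" (separate stable-id tables), release 66
binds dialect "65" (merged) — same calls, same answers:

```r
db <- open_database(cat, "test", "core")          # alias; defaults to release 66
genes_in_region(db, "chr1", 1, 20)
#> # A tibble: 2 × 8
#>   stable_id        biotype        display_name region start   end strand region_length
#> 1 TESTG00000000001 protein_coding G1           chr1       3    11      1            20
#> 2 TESTG00000000002 lincRNA        G2           chr1      14    19     -1            20

gene_across_releases(cat, "test", "TESTG00000000001")   # the through-time view
#> # A tibble: 2 × 5
#>   release region start   end strand
#> 1      60 chr1       2    10      1
#> 2      66 chr1       3    11      1
```

The one-base shift between releases is the fixture's miniature version of
a real assembly update. Sequence is stitched lazily from the contigs
(`ctgA` forward, a 2-base gap, `ctgB` reverse-complemented), and coding
transcripts translate:

```r
db60 <- open_database(cat, "test", "core", 60)
fetch_sequence(db60, "chr1", 1, 20)
#> [1] "AATGAAATAGNNGGGGTTTT"
splice_transcript(db60, "TESTT00000000001")
#> [1] "ATGAAATAG"
translate_cds(db60, "TESTT00000000001")
#> [1] "MK"
variants_in_region(cat, "test", 66, "chr1", 1, 10)
#> # A tibble: 1 × 6
#>   name      allele_string region start   end strand
#> 1 rs0000001 A/G           chr1       5     5      1
homologues_of(cat, "TESTG00000000001")$target_stable_id
#> [1] "OTHERG00000000005"
```

`MK` is the peptide for the 9-base CDS `ATG·AAA·TAG` with the stop
trimmed; the variant and orthologue come back through the release-62
variation and release-57 compara template sets respectively.

A command-line surface mirrors the same workflows
(`inst/exec/genomedb`): `list-species`, `genes` (GFF3/BED/TSV),
`sequence` (FASTA), `gene-history`, `variants`, `homologues`,
`fixtures-build`.

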