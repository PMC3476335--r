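---
title: "Version-aware access to Ensembl-style annotation databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Version-aware access to Ensembl-style annotation databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(releasewise)
```

## The problem

Ensembl-style genome datasources publish a new data release several times a
year, and the relational schema behind those releases evolves: release 51
introduced multi-species databases with species-scoped coordinate systems,
release 62 brought the variation schema into a form worth supporting, and
release 65 merged the separate `*_stable_id` tables into the gene,
transcript, exon and translation tables. Code that embeds SQL alongside its
data model must be re-released for every schema change and loses the
ability to read older archives. `releasewise` takes the opposite stance:
all SQL lives in named *mapping sets* (directories of query templates), and
a small declarative rules file decides which set serves which schema
release. One installation can then read current and archived releases
side by side, which is what makes reproducible "which coordinates did this
gene have in release 60?" questions cheap to ask.

## Version rules and mapping sets

A rules file has one line per supported interval:

```
core.51-64=57
core.65-66=65
compara.51-66=57
variation.62-66=62
```

`resolve_mapping_set(rules, db_type, release)` returns the unique matching
set id or `NA` (unsupported). Two properties are enforced at load time and
tested as invariants: intervals of one database type are pairwise disjoint
(resolution is a function), and anything outside every interval is
unsupported — the package never guesses a schema layout it has not been
configured for, which is also why releases above 66 are deliberately
unmapped in the shipped file: nothing newer has been exercised against
these templates.

Mapping sets absorb migrations by inheritance. Set `65` imports set `57`
and overrides exactly the five queries the stable-id merge touched
(`gene.by_stable_id`, `genes.by_region`, `transcripts.of_gene`,
`exons.of_transcript`, `translation.of_transcript`); the assembly,
sequence and coordinate-system templates are inherited verbatim. After
import resolution every set must cover the full query catalogue of its
database type — the catalogue is partitioned by type, since a variation
set has no business carrying core SQL. Import cycles and incomplete sets
are configuration errors, raised eagerly.

## The registry

`catalog_from_dir()` / `build_catalog()` parse database names with the
Ensembl naming conventions (four productions: plain
`<species>_<type>_<schema>_<build>`, the EnsemblGenomes form with a
leading genomes-release number, `_collection_` multi-species databases,
and `ensembl_compara*`). Where two trailing integers could be read either
as `<schema>_<build>` or as part of the genomes form, they are read as
`<schema>_<build>`: Ensembl-main is the primary target. Unrecognized names
are classified `other` and skipped with a logged reason rather than an
error, and so is any database whose release does not resolve — the
registry only ever exposes databases it can actually serve.

Species are looked up case-insensitively by name or alias. Aliases are
read from each database's `meta` table; members of collection databases
are likewise discovered from `meta`, lazily on first species access, and
flagged `collection_member` because collection species names are less
stable across releases than first-class species. These `meta` reads happen
at the registry layer, before any versioned template is bound; the
catalogued-template provenance guarantee (below) applies to the
annotation-access layer.

When several builds of one (species, type, release) are present the
lexicographically greatest build token wins and the shadowed file is
logged — an arbitrary but deterministic rule for a case the naming
convention leaves open.

## Coordinates, mappings, projection

All coordinates are 1-based, fully closed, strand in {+1, −1} — the
Ensembl convention; the BED exporter converts to 0-based half-open at the
boundary and nowhere else. A *feature mapping* pairs a span in a feature's
own coordinates with a location on a region. Feature-local coordinates
start at 1 at the feature's 5′ end on its own strand; the relative strand
of an inverted or composed mapping is the product of strands. With that
convention inversion is an involution, which the suite checks
property-style.

Assembly projection follows AGP orientation semantics: a block maps
`asm[asm_start..asm_end]` onto `cmp[cmp_start..cmp_end]`, and `ori = -1`
aligns the first assembled base with `cmp_end`. `project_location()` walks
the overlapping blocks in order, clips, emits component intervals with
strand `query_strand × ori`, and turns uncovered positions into explicit
gap segments; segment lengths always sum to the query length.
Out-of-range queries raise errors rather than clamping — silent clamping
hides fixture and caller bugs.

The correctness argument for projection is not the implementation but an
independent per-base oracle kept in the test helpers: map every base of
the query separately, then group maximal runs. Two hundred seeded random
assemblies (half of them two-level chromosome → supercontig → contig),
each with a random query interval, must agree with the oracle exactly,
along with round-trips through inverted blocks.

## Sequence stitching, splicing, translation

DNA is stored only at the unique sequence-level coordinate system.
`fetch_sequence()` projects the query down level by level (components may
themselves be assembled; recursion is bounded by the number of coordinate
systems, so a cyclic assembly is caught as a data-integrity error),
reads only the required substring of each sequence-level component,
reverse-complements minus-orientation segments, fills gaps with uppercase
`N`, and reverse-complements the final string for a minus-strand query.
Projection for stitching is always performed on the forward strand with
the one terminal complement — this makes "minus-strand fetch equals the
reverse complement of the plus-strand fetch" true by construction, while
per-base correctness is checked against the sequence oracle on databases
built from random assemblies.

`splice_transcript()` concatenates exon sequences in transcription order,
each fetched on the transcript strand. `translate_cds()` cuts the CDS out
of the spliced sequence using the translation record's start/end exons and
1-based offsets, then applies the standard nuclear code (via Biostrings),
trimming the trailing stop. A CDS whose length is not divisible by three,
or with an internal stop, or containing `N`, is reported as a
data-integrity error, not translated approximately.

## Laziness, observable

Listing genes in a region returns the genes and their mappings — nothing
else. Transcripts, exons, translations and sequence are loaded by the
dedicated accessors when first needed. Because repeated `open_database()`
calls for one (species, type, release) share a single handle, the handle's
per-query-name counters see *all* traffic to that database, and the suite
asserts the contract directly: after `genes_in_region()`, the
`transcripts.of_gene` and `sequence.of_region` counters are zero and each
increments exactly on first use. The same counters back the template
provenance invariant: every query-name ever executed through a handle
belongs to the canonical catalogue, i.e. there is no ad-hoc SQL in the
access layer.

## The fixture forge

Tests run against miniature SQLite databases generated in code, not
against live servers. The generator emulates the properties that matter to
this package: the naming conventions on the file names; the post-51
species-scoped `coord_system`/`meta` layout (including a two-species
collection); both core dialects with identical logical content (separate
stable-id tables vs merged columns), which is what makes the
dialect-transparency tests meaningful; a minimal variation and compara
schema; and byte-determinism (fixed row order, no timestamps), so
repeated builds are bit-identical.

The reference genome is deliberately tiny — a 20-base chromosome over two
contigs with a 2-base gap, one coding and one non-coding gene, one SNP,
one orthologue — so every expected value in the tests (the stitched
sequence, the spliced cDNA, the peptide `MK`, the gene history rows) was
derived by hand and is frozen in the assertions. Release numbers 49, 60,
66 and 70 straddle every breakpoint of the shipped rules, so registration,
default-release choice and exclusion logging are all exercised by one
directory listing. Property tests use 200 random assemblies for
projection, five database-backed random assemblies for stitching, and 100
random sub-intervals for strand coherence; these sizes keep the whole
suite under a minute while covering every branch of the block arithmetic.

What the fixtures do *not* emulate: production-scale table counts (real
core schemas have hundreds of tables; the forge writes the dozen the query
catalogue touches), MySQL as a backend (the templates are named-parameter
portable SQL and bind unchanged to a server connection, but that pathway
is untested here), haplotype/patch regions, and pseudoautosomal regions —
features annotated on a shared Y/X region will simply not be found on the
Y copy. Passing tests therefore demonstrate the version-mapping,
projection and access logic, not robustness to every production
datasource quirk.

## Design choices where the design was open

* **Unsupported is a value.** `resolve_mapping_set()` returns `NA` rather
  than raising: registration filters on it, and callers can distinguish
  "outside configuration" from genuine errors.
* **Mapping-set ids equal the release that introduced them** ("57", "62",
  "65"), which makes resolution results auditable against the rules file
  at a glance.
* **Per-type query catalogues.** Completeness of a mapping set is judged
  against the queries its database type actually serves.
* **Cross-schema joins happen in code** via shared identifiers (stable
  ids, seq-region ids resolved through the same-release core database),
  never via cross-database SQL; this keeps each dialect's templates
  independent.
* **One session may mix eras**: each database resolves its mapping set
  independently, so a release-60 core (dialect "57") and a release-66
  variation (dialect "62") coexist in one catalog.
* **No result caching** beyond the shared-handle registry and the
  per-handle coordinate-system/region indexes needed for stitching; a
  cache layer would sit naturally behind the single handle but is not
  implemented.

## Limitations

Linear sequences only (no circular bacterial topology); no pseudoautosomal
mechanism; no genomic-alignment half of comparative data (gene homology
only); no write access; live-server connections are architecturally
supported (swap the connection, keep the templates) but carry no tests.
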