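# Version-mapping rules: <db_type>.<min>-<max?>=<mapping_set_id>
# Core and compara template sets were written against the release-57 layout
# and hold back to release 51 (the multi-species coordinate-system change).
# Core templates were refreshed at release 65 (stable_id tables merged into
# gene/transcript/exon/translation). Variation support starts at release 62.
# Releases above 66 are intentionally unmapped: this configuration has not
# been exercised against later schemas, and unknown means unavailable.
core.51-64=57
core.65-66=65
compara.51-66=57
variation.62-66=62
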