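SELECT pli.stable_id, tl.seq_start, tl.seq_end,
       se.stable_id AS start_exon, ee.stable_id AS end_exon
FROM translation tl
JOIN translation_stable_id pli ON pli.translation_id = tl.translation_id
JOIN transcript_stable_id tsi ON tsi.transcript_id = tl.transcript_id
JOIN exon_stable_id se ON se.exon_id = tl.start_exon_id
JOIN exon_stable_id ee ON ee.exon_id = tl.end_exon_id
WHERE tsi.stable_id = :transcript_stable_id
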