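SELECT tl.stable_id, tl.seq_start, tl.seq_end,
       se.stable_id AS start_exon, ee.stable_id AS end_exon
FROM translation tl
JOIN transcript t ON t.transcript_id = tl.transcript_id
JOIN exon se ON se.exon_id = tl.start_exon_id
JOIN exon ee ON ee.exon_id = tl.end_exon_id
WHERE t.stable_id = :transcript_stable_id
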