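SELECT tsi.stable_id,
       sr.name AS region_name, sr.length AS region_length,
       t.seq_region_start, t.seq_region_end, t.seq_region_strand
FROM transcript t
JOIN transcript_stable_id tsi ON tsi.transcript_id = t.transcript_id
JOIN gene g ON g.gene_id = t.gene_id
JOIN gene_stable_id gsi ON gsi.gene_id = g.gene_id
JOIN seq_region sr ON sr.seq_region_id = t.seq_region_id
WHERE gsi.stable_id = :gene_stable_id
ORDER BY t.seq_region_start, tsi.stable_id
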