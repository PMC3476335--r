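SELECT g.stable_id, g.biotype, g.display_label,
       sr.name AS region_name, sr.length AS region_length,
       g.seq_region_start, g.seq_region_end, g.seq_region_strand
FROM gene g
JOIN seq_region sr ON sr.seq_region_id = g.seq_region_id
WHERE g.stable_id = :stable_id
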