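SELECT SUBSTR(d.sequence, :start, :length) AS sequence
FROM dna d
WHERE d.seq_region_id = :seq_region_id
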