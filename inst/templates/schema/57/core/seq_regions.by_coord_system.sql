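SELECT seq_region_id, name, coord_system_id, length
FROM seq_region
WHERE coord_system_id = :coord_system_id
ORDER BY seq_region_id
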