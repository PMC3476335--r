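SELECT sr.seq_region_id, sr.name, sr.coord_system_id, sr.length
FROM seq_region sr
JOIN coord_system cs ON cs.coord_system_id = sr.coord_system_id
WHERE sr.name = :name AND cs.species_id = :species_id
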