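SELECT coord_system_id, species_id, name, version, rank, attrib
FROM coord_system
WHERE species_id = :species_id
ORDER BY rank
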