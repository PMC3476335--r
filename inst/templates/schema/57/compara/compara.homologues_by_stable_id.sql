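SELECT sm.stable_id AS source_stable_id,
       tm.stable_id AS target_stable_id,
       gdb.name AS target_species_name,
       tm.chr_name AS target_region_name,
       tm.chr_start AS target_start,
       tm.chr_end AS target_end,
       h.description AS homology_type
FROM member sm
JOIN homology_member hms ON hms.member_id = sm.member_id
JOIN homology h ON h.homology_id = hms.homology_id
JOIN homology_member hmt
     ON hmt.homology_id = h.homology_id AND hmt.member_id <> sm.member_id
JOIN member tm ON tm.member_id = hmt.member_id
JOIN genome_db gdb ON gdb.genome_db_id = tm.genome_db_id
WHERE sm.stable_id = :stable_id
ORDER BY tm.stable_id
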