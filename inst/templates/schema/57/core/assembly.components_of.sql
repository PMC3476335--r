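SELECT a.asm_seq_region_id, a.asm_start, a.asm_end,
       a.cmp_seq_region_id, a.cmp_start, a.cmp_end, a.ori
FROM assembly a
WHERE a.asm_seq_region_id = :asm_seq_region_id
  AND a.asm_end >= :start AND a.asm_start <= :end
ORDER BY a.asm_start
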