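SELECT vf.variation_name, vf.allele_string,
       vf.seq_region_start, vf.seq_region_end, vf.seq_region_strand
FROM variation_feature vf
WHERE vf.seq_region_id = :seq_region_id
  AND vf.seq_region_end >= :start AND vf.seq_region_start <= :end
ORDER BY vf.seq_region_start, vf.variation_name
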