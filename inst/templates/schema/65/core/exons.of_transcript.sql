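SELECT e.stable_id,
       sr.name AS region_name, sr.length AS region_length,
       e.seq_region_start, e.seq_region_end, e.seq_region_strand,
       et.rank
FROM exon e
JOIN exon_transcript et ON et.exon_id = e.exon_id
JOIN transcript t ON t.transcript_id = et.transcript_id
JOIN seq_region sr ON sr.seq_region_id = e.seq_region_id
WHERE t.stable_id = :transcript_stable_id
ORDER BY et.rank
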