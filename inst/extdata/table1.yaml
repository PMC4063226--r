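# Published per-step duration profile of the paired-end worked example
# (SRR1027730, 45 M reads): serial column vs host/remote split columns,
# with block transfers.  Identical to workload_table1().
dataset_id: SRR1027730
paired: true
reads:
  left: 23000000
  right: 22000000
serial:
  filter_reads: 22
  build_index: 6
  gene_align: 83
  genome_align: 94
  find_juncs: 12
  junc_align: 17
  span_reads: 10
  report: 40
host:
  filter_reads: 21
  build_index: 6
  gene_align: 42
  genome_align: 39
  find_juncs: 9
  junc_align: 2
  span_reads: 3
  report: 41
remote:
  build_index: 6
  gene_align: 37
  genome_align: 41
  junc_align: 2
  span_reads: 3
transfers:
- block: 1
  direction: in
  minutes: 5
- block: 1
  direction: out
  minutes: 3
- block: 2
  direction: in
  minutes: 0.3666666666666667
  negligible: true
- block: 2
  direction: out
  minutes: 0.4
  negligible: true
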