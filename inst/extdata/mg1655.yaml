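# E. coli K-12 MG1655 (NC_000913.3) genome configuration for 1-kb binned
# supercoiling analysis.
#
# External annotation with APPROXIMATE coordinates: the seven rRNA (rrn)
# operon intervals are bin-aligned 5-kb windows around each operon (35
# masked 1-kb bins in total; rrn operons cannot be mapped with short reads),
# and the macrodomain boundaries are rounded to the kb. Override with your
# own genome YAML where exact boundaries matter.
genome_length_bp: 4641652
bin_size_bp: 1000
oric_bp: 3925744
dif_bp: 1588774
masked_intervals:
  - {start: 223000, end: 228000, label: rrnH}
  - {start: 2726000, end: 2731000, label: rrnG}
  - {start: 3423000, end: 3428000, label: rrnD}
  - {start: 3939000, end: 3944000, label: rrnC}
  - {start: 4033000, end: 4038000, label: rrnA}
  - {start: 4164000, end: 4169000, label: rrnB}
  - {start: 4204000, end: 4209000, label: rrnE}
macrodomains:
  - {name: Ori, start: 3923000, end: 131000}
  - {name: NS-R, start: 131000, end: 795000}
  - {name: Right, start: 795000, end: 1605000}
  - {name: Ter, start: 1605000, end: 2365000}
  - {name: Left, start: 2365000, end: 3015000}
  - {name: NS-L, start: 3015000, end: 3923000}
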