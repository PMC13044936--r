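cwlVersion: v1.2
class: CommandLineTool
baseCommand: mock_annotate
inputs:
  vcf:
    type: File
    default: results/cohort.filtered.vcf
    inputBinding: {position: 1, prefix: -i}
  outfile:
    type: string
    default: results/cohort.annotated.tsv
    inputBinding: {position: 2, prefix: -o}
outputs:
  annotated:
    type: File
    outputBinding: {glob: results/cohort.annotated.tsv}
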