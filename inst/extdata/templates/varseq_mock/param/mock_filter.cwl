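cwlVersion: v1.2
class: CommandLineTool
baseCommand: mock_filter
inputs:
  vcf:
    type: File
    default: results/cohort.vcf
    inputBinding: {position: 1, prefix: -i}
  min_qual:
    type: int
    default: 40
    inputBinding: {position: 2, prefix: --min-qual}
  outfile:
    type: string
    default: results/cohort.filtered.vcf
    inputBinding: {position: 3, prefix: -o}
outputs:
  filtered:
    type: File
    outputBinding: {glob: results/cohort.filtered.vcf}
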