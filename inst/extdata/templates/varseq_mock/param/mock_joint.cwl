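cwlVersion: v1.2
class: CommandLineTool
baseCommand: mock_joint
inputs:
  outfile:
    type: string
    default: results/cohort.vcf
    inputBinding: {position: 1, prefix: -o}
  gvcfs:
    type: File[]
    inputBinding: {position: 2}
outputs:
  vcf:
    type: File
    outputBinding: {glob: results/cohort.vcf}
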