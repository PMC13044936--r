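cwlVersion: v1.2
class: CommandLineTool
baseCommand: mock_gvcf
inputs:
  aln:
    type: File
    inputBinding: {position: 1, prefix: -i}
  idx:
    type: File
    default: results/ref.idx
    inputBinding: {position: 2, prefix: -r}
  sample:
    type: string
    default: _SampleName_
    inputBinding: {position: 3, prefix: -s}
  outfile:
    type: string
    default: results/_SampleName_.g.vcf
    inputBinding: {position: 4, prefix: -o}
outputs:
  gvcf:
    type: File
    outputBinding: {glob: results/_SampleName_.g.vcf}
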