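cwlVersion: v1.2
class: CommandLineTool
baseCommand: mock_align
inputs:
  idx:
    type: File
    default: results/ref.idx
    inputBinding: {position: 1, prefix: -x}
  reads:
    type: File
    inputBinding: {position: 2, prefix: -i}
  outfile:
    type: string
    default: results/_SampleName_.sam
    inputBinding: {position: 3, prefix: -o}
outputs:
  sam:
    type: File
    outputBinding: {glob: results/_SampleName_.sam}
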