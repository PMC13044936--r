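cwlVersion: v1.2
class: CommandLineTool
baseCommand: mock_index
inputs:
  reference:
    type: File
    default: data/reference.txt
    inputBinding: {position: 1, prefix: -r}
  outfile:
    type: string
    default: results/ref.idx
    inputBinding: {position: 2, prefix: -o}
outputs:
  idx:
    type: File
    outputBinding: {glob: results/ref.idx}
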