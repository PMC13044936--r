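cwlVersion: v1.2
class: CommandLineTool
baseCommand: mock_trim
inputs:
  reads:
    type: File
    inputBinding: {position: 1, prefix: -i}
  min_len:
    type: int
    default: 10
    inputBinding: {position: 2, prefix: --min-len}
  outfile:
    type: string
    default: results/_SampleName_.trim.txt
    inputBinding: {position: 3, prefix: -o}
outputs:
  trimmed:
    type: File
    outputBinding: {glob: results/_SampleName_.trim.txt}
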