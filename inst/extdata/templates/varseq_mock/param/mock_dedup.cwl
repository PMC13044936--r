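cwlVersion: v1.2
class: CommandLineTool
baseCommand: mock_dedup
inputs:
  insam:
    type: File
    inputBinding: {position: 1, prefix: -i}
  outfile:
    type: string
    default: results/_SampleName_.dedup.sam
    inputBinding: {position: 2, prefix: -o}
outputs:
  dedup:
    type: File
    outputBinding: {glob: results/_SampleName_.dedup.sam}
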