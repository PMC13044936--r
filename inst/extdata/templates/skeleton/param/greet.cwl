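cwlVersion: v1.2
class: CommandLineTool
baseCommand: echo
inputs:
  message:
    type: string
    default: hello _SampleName_
    inputBinding:
      position: 1
outputs:
  greeting:
    type: stdout
stdout: results/_SampleName_.greeting.txt
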