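{
  "segments": {
    "H1": [49, 72],
    "ICL1": [73, 77],
    "H2": [78, 104],
    "ECL1": [105, 112],
    "H3": [113, 152],
    "ICL2": [153, 159],
    "H4": [160, 185],
    "ECL2": [186, 200],
    "H5": [201, 238],
    "ICL3": [239, 241],
    "H6": [242, 268],
    "ECL3": [269, 280],
    "H7": [281, 303]
  },
  "anchors": {
    "53": ["1x43"],
    "95": ["2x57"],
    "132": ["3x33"],
    "184": ["4x64"],
    "234": ["5x58"],
    "267": ["6x59"],
    "301": ["7x61"]
  }
}
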