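{
  "duration": 0.85,
  "gestures": [
    {
      "task": "LA",
      "target": 0,
      "mass": 1,
      "stiffness": 400,
      "damping": "critical",
      "onset": 0,
      "offset": 0.25
    },
    {
      "task": "VEL",
      "target": 0.5,
      "mass": 1,
      "stiffness": 400,
      "damping": "critical",
      "onset": 0,
      "offset": 0.25
    },
    {
      "task": "TBCD",
      "target": 0.8,
      "mass": 1,
      "stiffness": 400,
      "damping": "critical",
      "onset": 0,
      "offset": 0.5
    },
    {
      "task": "TTCD",
      "target": 0,
      "mass": 1,
      "stiffness": 400,
      "damping": "critical",
      "onset": 0.55,
      "offset": 0.8
    }
  ]
}
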