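{
  "baseline": {
    "X1": 1
  },
  "pulses": [
    {
      "species": "X1",
      "start": 5,
      "stop": 15,
      "value": 10
    },
    {
      "species": "X1",
      "start": 25,
      "stop": 35,
      "value": 5
    }
  ]
}
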