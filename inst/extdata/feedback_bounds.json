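{
  "parameters": [
    {
      "kind": "input_scale",
      "species": "X1",
      "name": "alpha_r0",
      "lower": 0.5,
      "upper": 1.5
    },
    {
      "kind": "alpha",
      "reaction": "r1",
      "lower": 5,
      "upper": 15
    },
    {
      "kind": "alpha",
      "reaction": "r2",
      "lower": 5,
      "upper": 15
    },
    {
      "kind": "alpha",
      "reaction": "r3",
      "lower": 5,
      "upper": 15
    },
    {
      "kind": "alpha",
      "reaction": "r4",
      "lower": 1.5,
      "upper": 4.5
    },
    {
      "kind": "alpha",
      "reaction": "r5",
      "lower": 0.05,
      "upper": 0.15
    },
    {
      "kind": "kinetic_order",
      "species": "X4",
      "reaction": "r1",
      "lower": -2,
      "upper": 0
    }
  ],
  "objective": {
    "species": "X4",
    "t_start": 0,
    "t_upper": 20
  }
}
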