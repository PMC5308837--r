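{
  "omega_r": 2.5,
  "f_b": 19,
  "points": [
    {
      "z": 0,
      "A_r": 0.2,
      "p_r": 0,
      "A_b": 1.3,
      "p_b": 0,
      "p_o": 0,
      "w": 0.7
    },
    {
      "z": 3,
      "A_r": 0.35,
      "p_r": 0.5,
      "A_b": 1.1,
      "p_b": -1.2,
      "p_o": 0,
      "w": 1.1
    },
    {
      "z": 6,
      "A_r": 0.5,
      "p_r": 1,
      "A_b": 0.9,
      "p_b": -2.4,
      "p_o": 0,
      "w": 1.4
    },
    {
      "z": 9,
      "A_r": 0.55,
      "p_r": 1.2,
      "A_b": 0.7,
      "p_b": -3.6,
      "p_o": 0,
      "w": 1.5
    },
    {
      "z": 12,
      "A_r": 0.55,
      "p_r": 1.2,
      "A_b": 0.5,
      "p_b": -4.8,
      "p_o": 0,
      "w": 1.5
    },
    {
      "z": 15,
      "A_r": 0.5,
      "p_r": 1.2,
      "A_b": 0.35,
      "p_b": -6,
      "p_o": 0,
      "w": 1.4
    },
    {
      "z": 18,
      "A_r": 0.45,
      "p_r": 1.2,
      "A_b": 0.2,
      "p_b": -7.2,
      "p_o": 0,
      "w": 1.1
    },
    {
      "z": 21,
      "A_r": 0.4,
      "p_r": 1.2,
      "A_b": 0.1,
      "p_b": -8.4,
      "p_o": 0,
      "w": 0.8
    }
  ]
}
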