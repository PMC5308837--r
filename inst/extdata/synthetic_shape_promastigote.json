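{
  "omega_r": 0.15,
  "f_b": 19,
  "points": [
    {
      "z": 0,
      "A_r": 0.15,
      "p_r": 0.8,
      "A_b": 1.5,
      "p_b": 0,
      "p_o": 0,
      "w": 0.6
    },
    {
      "z": 3,
      "A_r": 0.15,
      "p_r": 0.8,
      "A_b": 1.2,
      "p_b": -1.2,
      "p_o": 0,
      "w": 1
    },
    {
      "z": 6,
      "A_r": 0.15,
      "p_r": 0.8,
      "A_b": 0.9,
      "p_b": -2.4,
      "p_o": 0,
      "w": 1.3
    },
    {
      "z": 9,
      "A_r": 0.15,
      "p_r": 0.8,
      "A_b": 0.65,
      "p_b": -3.6,
      "p_o": 0,
      "w": 1.5
    },
    {
      "z": 12,
      "A_r": 0.15,
      "p_r": 0.8,
      "A_b": 0.45,
      "p_b": -4.8,
      "p_o": 0,
      "w": 1.5
    },
    {
      "z": 15,
      "A_r": 0.15,
      "p_r": 0.8,
      "A_b": 0.3,
      "p_b": -6,
      "p_o": 0,
      "w": 1.3
    },
    {
      "z": 18,
      "A_r": 0.15,
      "p_r": 0.8,
      "A_b": 0.15,
      "p_b": -7.2,
      "p_o": 0,
      "w": 1
    },
    {
      "z": 21,
      "A_r": 0.15,
      "p_r": 0.8,
      "A_b": 0.05,
      "p_b": -8.4,
      "p_o": 0,
      "w": 0.7
    }
  ]
}
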