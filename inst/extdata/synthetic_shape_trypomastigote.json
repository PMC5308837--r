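{
  "omega_r": 11,
  "f_b": 19,
  "points": [
    {
      "z": 0,
      "A_r": 0.3,
      "p_r": 0,
      "A_b": 1.2,
      "p_b": 0,
      "p_o": 0,
      "w": 0.8
    },
    {
      "z": 3,
      "A_r": 0.6,
      "p_r": 0.9,
      "A_b": 1,
      "p_b": -1.2,
      "p_o": 0,
      "w": 1.2
    },
    {
      "z": 6,
      "A_r": 0.9,
      "p_r": 1.8,
      "A_b": 0.8,
      "p_b": -2.4,
      "p_o": 0,
      "w": 1.5
    },
    {
      "z": 9,
      "A_r": 1.1,
      "p_r": 2.7,
      "A_b": 0.6,
      "p_b": -3.6,
      "p_o": 0,
      "w": 1.6
    },
    {
      "z": 12,
      "A_r": 1.2,
      "p_r": 3.6,
      "A_b": 0.45,
      "p_b": -4.8,
      "p_o": 0,
      "w": 1.6
    },
    {
      "z": 15,
      "A_r": 1.1,
      "p_r": 4.5,
      "A_b": 0.3,
      "p_b": -6,
      "p_o": 0,
      "w": 1.5
    },
    {
      "z": 18,
      "A_r": 0.9,
      "p_r": 5.4,
      "A_b": 0.2,
      "p_b": -7.2,
      "p_o": 0,
      "w": 1.2
    },
    {
      "z": 21,
      "A_r": 0.7,
      "p_r": 6.3,
      "A_b": 0.1,
      "p_b": -8.4,
      "p_o": 0,
      "w": 0.9
    }
  ]
}
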