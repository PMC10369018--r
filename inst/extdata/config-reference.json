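{
  "side_length": 600,
  "grid_cells_per_side": 20,
  "speed": 50,
  "max_turning_angle": 6.283185307179586,
  "max_lifespan": 5000,
  "turning_penalty": 0,
  "n_hidden": 3,
  "goal": "explore",
  "n": 20000,
  "generations": 150
}
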