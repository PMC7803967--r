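# Desk-scale demo configuration for `egretwatch run`.
seed: 7
sim:
  n_days: 8
  frame_interval: 300
compositor:
  n_images: 6
  frame_width: 320
  frame_height: 240
  write_images: true
heatmap:
  beta: 0.01
  lambda: 0.1
weather:
  noise_sd: 0.25
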