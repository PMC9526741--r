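# Example end-to-end tracking run: a star moving over a static dot field
# behind a scattering layer whose memory range is ~1.7 mm on the object
# plane (about a quarter of the simulated field of view).
backend: statistical
seed: 11
memory_range_mm: 1.72
exclude_radius_px: 6
scene:
  type: dotfield
  n_dots: 8
  min_sep_px: 16
  grid: 128
  n_frames: 6
  star_anchor_mm: [-1.4, 0.0]
  step_mm: [0.4128, 0.0]     # 6 object pixels per frame
out_dir: speckletrack-out
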