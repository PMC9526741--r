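wavelength_mm: 0.0006328
sigma_mm: 0.3
L_mm: 0.01
L_o_mm: 430.0
L_s_mm: 50.0
object_pitch_mm: 0.0688
detector_pitch_mm: 0.008
flip_axes: yes
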