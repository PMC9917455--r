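{"camera":{"focal_length_mm":25,"numerical_aperture":0.03,"pixel_pitch_um":1.4,"sensor_px":[4320,2432],"wavelength_um":0.5},"grid":[8,12],"pitch_mm":19,"working_distance_mm":150,"long_axis":"grid_x"}
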