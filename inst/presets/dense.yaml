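# Many events per stage with smaller spatial separation; stresses the
# temporal association and the matcher.
width: 160
height: 120
fps: 8.66
habituation_s: 120
trial_s: 120
gap_s: 3
floor_margin: 14
floor_temp: 25
floor_sigma: 0.25
ambient_temp: 23
mouse_temp: 35
mouse_radius: 12
step_sigma: 2.5
dwell_prob: 0.05
n_urine: 10
n_feces: 10
urine_radius: [5.0, 8.0]
feces_radius: [1.5, 2.5]
urine_tau: [40.0, 52.0]
feces_tau: [30.0, 45.0]
urine_peak: [8.0, 11.0]
feces_peak: [7.0, 10.0]
dark_offset: 0.5
event_time_range: [8.0, 70.0]
min_mouse_dist: 20
min_event_sep: 28
noise_sigma: 0.08
nuc_amplitude: 0.3
drift_amplitude: 0.4
drift_period_s: 180
blackbody_temp: 37
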