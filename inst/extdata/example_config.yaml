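# Wild-type simulation settings: one generation at 60 min, hydrolysis at
# ln(2)/60 per min (50 % bond survival per generation), steady-fraction
# tethering rate.
generation_time_min: 60
k_t_per_min: 0.011552453
k_h_per_min: 0.011552453
tethered_fraction: 0.333333333
lpp_copies: 1.0e6
donor_ratio: 1.0
septal_factor: 1.0
t_end_min: 60
dt_min: 1
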