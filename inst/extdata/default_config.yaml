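seed: 1
n_param: 180
n_valid: 72
n_hybrids_param: 160
n_hybrids_valid: 34
temperatures:
- 11.75
- 15.51
- 17.33
- 19.03
- 21.44
- 26.49
- 27.0
duration_days: 120
field_days: 120
obs_noise_sd: 2.0
lod_threshold: 2.5
scan_step: 2.0
cofactor_window: 10.0
dh_sites:
- Zeewolde2011
- Zeewolde2012
- Ruthe
- Rostock
hybrid_sites:
- Ocsa2011
- Ocsa2012
- Zeewolde2012
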