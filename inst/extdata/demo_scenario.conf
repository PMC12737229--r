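# Shipped demo: a 90-day synthetic Beijing winter (January-March), with
# regime frequencies dominated by local stagnation and the calibrated
# per-regime concentration and meteorology distributions.
scenario = synthetic
n_days = 90
start = 2024-01-01
seed = 1234
regime_probs = local:0.30,north:0.15,west:0.15,east:0.20,south:0.20
arrival_spacing_h = 3
n_members = 27

# method conventions
apply_weight = true
nave_mode = occupied
tau_mode = endpoint
attribution_weighting = count

# concentration-response model
beta = 0.38
beta_min = 0.31
beta_max = 0.45
c0 = 0
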