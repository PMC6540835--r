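# apexds configuration template
#
# Used both as the fitting config (`apexds fit/compare --config`) and,
# with the scenario keys below, as a simulation/benchmark config
# (`apexds simulate/bench --config`).

# ---- survey geometry (required for fitting) -------------------------------
w: 600            # strip half-width, metres
sides: 1          # 1 = both observers search the same side of the aircraft
area_km2: 7200    # study area; may be a per-stratum mapping, e.g.
                  #   area_km2: {north: 500, south: 500}

# ---- model choices --------------------------------------------------------
form: two_piece_normal    # or half_normal
covariates: []            # distance-model covariates, e.g. [cover, esd_bin]
mr_covariates: []         # mark-recapture model covariates
left_truncation: 0        # metres, or "apex" (half-normal only)

# ---- reproducibility ------------------------------------------------------
seed: 1

# ---- simulation scenario (simulate / bench only) --------------------------
n_groups: 7500            # groups in the study area
n_transects: 120
transect_length_km: 30
theta: 110                # true apex distance (m)
sigma1: 60                # near-side scale (m)
sigma2: 150               # far-side scale (m)
apex_logits: [1.2, 1.0]   # per-observer apex detection on the logit scale
tau: 0.8                  # SD of the shared group-level frailty (logits)
psi: 1                    # daily availability (1 = nothing denned/hidden)
rho: 0                    # day-to-day availability persistence
hotspot_n: 0              # transects with locally multiplied intensity
hotspot_multiplier: 8
group_size_lambda: 1.1    # zero-truncated Poisson rate (mean size ~1.6)

# ---- benchmarking (bench only) --------------------------------------------
replicates: 50
estimators: [cds_2pn, mrds_pi]
# experiment: stakes      # uncomment to run the stake-transect ordering
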