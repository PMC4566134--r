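# Shared study conditions for the analysis scripts.
#
# One toy crystal pair (P212121, 40 residue-scale scatterers, one Hg-like
# site at occupancy 0.7 with f'' = 9.75 e) and one simulation setting
# shared by every numbered script, so results are comparable across steps.

library(sirasfx)
library(data.table)

STUDY_SEED <- 42L
N_PATTERNS <- 1600L

study_truth <- function() make_toy_structure(seed = STUDY_SEED)

# native: plain SFX noise. derivative: same noise plus the low-angle
# absorber (36.36% transmittance below 3.8 A) and a 15% admixture of
# too-weak snapshots, so preselection and absorber correction have work
# to do, as in the real beamtime.
native_config <- function() sim_config(seed = STUDY_SEED + 1L,
                                       n_patterns = N_PATTERNS)
derivative_config <- function() {
  sim_config(seed = STUDY_SEED + 2L, n_patterns = N_PATTERNS,
             absorber = list(T = 0.3636, d_threshold = 3.8),
             weak_fraction = 0.15, weak_scale = 1e-3)
}

# regenerate the cleaned, merge-ready streams (preselected + corrected)
prepared_streams <- function(truth = study_truth()) {
  nat <- simulate_patterns(truth, "native", native_config())
  der <- simulate_patterns(truth, "derivative", derivative_config())
  der_sel <- preselect_patterns(der, adu_threshold = 1000,
                                lowres_bound = 3.8)
  der_cor <- absorber_correct(der_sel$stream, T = 0.3636, d_threshold = 3.8)
  list(native = nat, derivative = der_cor,
       derivative_raw = der, derivative_rejected = der_sel$n_rejected)
}

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

write_result <- function(dt, name) {
  path <- file.path("results", name)
  fwrite(as.data.table(dt), path, sep = "\t")
  message("wrote ", path)
}
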