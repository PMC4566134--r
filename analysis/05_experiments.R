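# The computational experiments: pattern-count titration per phasing mode,
# resolution-cutoff scan, and anomalous-signal growth curves.

source("analysis/00_common.R")

truth <- study_truth()
ns <- simulate_patterns(truth, "native", native_config())
ds <- simulate_patterns(truth, "derivative",
                        sim_config(seed = STUDY_SEED + 2L,
                                   n_patterns = N_PATTERNS))

# -- titration: how many snapshots does each mode need? ---------------------
axes <- c(25, 50, 100, 200, 400)
titr <- rbindlist(lapply(c("SIRAS", "SIR", "SAD"), function(md) {
  run_titration(truth, ns, ds, axes, axes, mode = md, n_cycles = 10)
}))
write_result(titr, "05_titration.tsv")
mins <- titr[, .(min_total = minimal_success_total(.SD),
                 success_cells = sum(success)), by = mode]
write_result(mins, "05_titration_minima.tsv")
print(mins)
message(sprintf("minimal successful total: SIRAS %s, SIR %s; SAD succeeded in %d cells",
                mins[mode == "SIRAS", min_total],
                mins[mode == "SIR", min_total],
                mins[mode == "SAD", success_cells]))

# -- resolution-cutoff scan -------------------------------------------------
scan <- run_resolution_scan(truth,
                            sirasfx:::subset_patterns(ns, 400),
                            sirasfx:::subset_patterns(ds, 400),
                            cutoffs = c(2.5, 3.0, 3.5, 4.0, 5.0, 6.0),
                            modes = c("SIRAS", "SIR"), n_cycles = 10)
write_result(scan, "05_resolution_scan.tsv")
coarsest <- scan[success == TRUE, .(coarsest_ok = max(cutoff)), by = mode]
print(coarsest)

# -- anomalous-signal growth ------------------------------------------------
sig <- run_signal_curves(truth, ds, c(100, 200, 400, 800, 1600))
write_result(sig, "05_signal_curves.tsv")
print(sig)
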