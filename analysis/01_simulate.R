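# Simulate the study's synthetic SFX observations.
#
# Builds the toy crystal pair, simulates 1600 native and 1600 Hg-derivative
# snapshots, and writes the streams (scratch/, they are bulky and fully
# regenerable from the seed), the ground-truth heavy site, and a quick
# signal inventory to results/.

source("analysis/00_common.R")

truth <- study_truth()
message(sprintf("toy structure: %d light scatterers + 1 Hg site, cell %.0fx%.0fx%.0f, d_min %.2f",
                nrow(truth$atoms_native), truth$cell$a, truth$cell$b,
                truth$cell$c, truth$d_min))
message(sprintf("unique reflections (Friedel separate): %d", nrow(truth$refl)))

nat <- simulate_patterns(truth, "native", native_config())
der <- simulate_patterns(truth, "derivative", derivative_config())
write_stream("scratch/native.stream", nat)
write_stream("scratch/derivative.stream", der)
write_pdb_sites("results/true_heavy_site.pdb", truth$heavy_sites,
                truth$cell, truth$sg)

# signal inventory: how big are the isomorphous and anomalous differences?
plus <- truth$refl[branch == 1]
fp <- calc_structure_factors(truth$atoms_native, truth$cell, truth$sg,
                             plus, FALSE)$amp
fph <- calc_structure_factors(truth$atoms_derivative, truth$cell, truth$sg,
                              plus, FALSE)$amp
ano <- merge(sirasfx:::model_ano_differences(truth$sf_derivative),
             data.table(h = plus$h, k = plus$k, l = plus$l, fph2 = fph^2),
             by = c("h", "k", "l"))
inventory <- data.table(
  quantity = c("n_patterns_native", "n_patterns_derivative",
               "mean_obs_per_pattern",
               "true_r_iso", "mean_F_native",
               "rms_iso_difference", "rms_bijvoet_ratio"),
  value = c(length(unique(nat$pattern_id)), length(unique(der$pattern_id)),
            round(nrow(nat) / length(unique(nat$pattern_id)), 1),
            round(sum(abs(fph - fp)) / sum(fp), 4), round(mean(fp), 2),
            round(sqrt(mean((fph - fp)^2)), 2),
            round(sqrt(mean((ano$dI_calc / ano$fph2)^2)), 4))
)
write_result(inventory, "01_signal_inventory.tsv")
print(inventory)
message("round trip check: ",
        nrow(read_stream("scratch/native.stream")) == nrow(nat))
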