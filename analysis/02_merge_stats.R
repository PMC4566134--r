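# Preselect, absorber-correct and Monte-Carlo merge both streams, and
# tabulate the data-quality statistics (multiplicity, R_split, CC_1/2,
# CC_ano, CC_anoref, per-shell table) that frame everything downstream.

source("analysis/00_common.R")

truth <- study_truth()
st <- prepared_streams(truth)
message(sprintf("derivative preselection rejected %d of %d patterns",
                st$derivative_rejected,
                length(unique(st$derivative_raw$pattern_id))))

# the experimental campaign's own selection arithmetic
rates <- rbind(
  data.table(crystal = "native", collected = 133958, selected = 26238,
             indexed = 10792),
  data.table(crystal = "derivative", collected = 583291, selected = 298061,
             indexed = 85747)
)
rates[, selection_pct := vapply(seq_len(.N), function(i)
  summarize_selection(collected[i], selected[i],
                      indexed[i])$selection_rate_pct, 1)]
rates[, indexing_pct := vapply(seq_len(.N), function(i)
  summarize_selection(collected[i], selected[i],
                      indexed[i])$indexing_rate_pct, 1)]
write_result(rates, "02_selection_rates.tsv")

overall <- list()
for (side in c("native", "derivative")) {
  stream <- st[[side]]
  merged <- merge_patterns(stream, truth$cell, truth$sg, TRUE)
  hm <- half_set_metrics(stream, truth$cell, truth$sg, seed = 1)
  model <- if (side == "native") truth$sf_native else truth$sf_derivative
  overall[[side]] <- data.table(
    crystal = side,
    n_patterns = length(unique(stream$pattern_id)),
    multiplicity_friedel_separate = round(attr(merged, "mean_multiplicity"), 1),
    multiplicity_friedel_merged =
      round(mean(merge_patterns(stream, truth$cell, truth$sg, FALSE)$n), 1),
    r_split = round(hm$r_split, 4),
    cc_half = round(hm$cc_half, 4),
    cc_ano = round(hm$cc_ano, 4),
    cc_calc = round(cc_calc(merged, model), 4),
    cc_anoref = if (side == "derivative")
      round(cc_anoref(merged, truth$sf_derivative), 4) else NA_real_
  )
  shells <- shell_statistics(stream, truth$cell, truth$sg, n_shells = 6,
                             d_min = truth$d_min)
  write_result(shells, sprintf("02_shells_%s.tsv", side))
}
overall <- rbindlist(overall)
write_result(overall, "02_merge_overview.tsv")
print(overall)
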