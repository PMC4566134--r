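test_that("preselection keeps a pattern only if its low-res maximum exceeds the threshold", {
  stream <- data.table::data.table(
    pattern_id = c(1L, 1L, 2L, 2L, 3L),
    h = 1L, k = 1L, l = 0L,
    d = c(5, 2, 5, 2, 5),
    I_obs = c(5000, 99999, 5001, 1, 10),
    sigma = 1
  )
  out <- preselect_patterns(stream, adu_threshold = 5000, lowres_bound = 3.8)
  # pattern 1: low-res max exactly 5000 -> "did not exceed" -> rejected,
  # despite a huge high-res record
  expect_equal(sort(unique(out$stream$pattern_id)), 2L)
  expect_equal(out$n_rejected, 2)
  out0 <- preselect_patterns(stream, adu_threshold = 0)
  expect_equal(out0$n_kept, 3)
})

test_that("preselection separates a bimodal weak/strong stream", {
  truth <- small_truth()
  cfg <- sim_config(seed = 19, n_patterns = 200, weak_fraction = 0.5,
                    weak_scale = 1e-4)
  st <- simulate_patterns(truth, "native", cfg)
  sel <- preselect_patterns(st, adu_threshold = 1000, lowres_bound = 3.8)
  frac_rejected <- sel$n_rejected / 200
  expect_gt(frac_rejected, 0.35)
  expect_lt(frac_rejected, 0.65)
})

test_that("absorber correction arithmetic matches the transmission factor", {
  stream <- data.table::data.table(pattern_id = 1L, h = 1L, k = 0L, l = 0L,
                                   d = c(5, 2), I_obs = c(100, 100),
                                   sigma = c(10, 10))
  out <- absorber_correct(stream, T = 0.3636, d_threshold = 3.8)
  expect_equal(round(out$I_obs[1], 2), 275.03)
  expect_equal(round(out$sigma[1], 2), 27.50)
  expect_equal(out$I_obs[2], 100)
  same <- absorber_correct(stream, T = 1, d_threshold = 3.8)
  expect_equal(same$I_obs, stream$I_obs)
  expect_error(absorber_correct(stream, T = 0, d_threshold = 3.8), "\\(0, 1\\]")
})

test_that("simulate-with-absorber then correct matches the no-absorber merge", {
  truth <- small_truth()
  base_cfg <- sim_config(seed = 23, n_patterns = 400)
  abs_cfg <- sim_config(seed = 23, n_patterns = 400,
                        absorber = list(T = 0.3636, d_threshold = 3.8))
  m_plain <- merge_patterns(simulate_patterns(truth, "native", base_cfg),
                            truth$cell, truth$sg, TRUE)
  st <- simulate_patterns(truth, "native", abs_cfg)
  st <- absorber_correct(st, T = 0.3636, d_threshold = 3.8)
  m_corr <- merge_patterns(st, truth$cell, truth$sg, TRUE)
  both <- merge(m_plain, m_corr, by = c("h", "k", "l", "branch"))
  expect_gt(cor(both$I.x, both$I.y), 0.995)
  # no systematic offset between the low-angle regions of the two merges
  low <- both[both$d.x >= 3.8, ]
  expect_lt(abs(median((low$I.y - low$I.x) / pmax(abs(low$I.x), 1))), 0.25)
})

test_that("merging pools symmetry mates and is permutation invariant", {
  cell <- unit_cell(10, 12, 14)
  sg <- space_group("P212121")
  h0 <- c(1, 2, 3)
  orbit <- t(vapply(sg$ops, function(o) as.vector(h0 %*% o$R), numeric(3)))
  stream <- data.table::data.table(
    pattern_id = 1:4, h = orbit[, 1], k = orbit[, 2], l = orbit[, 3],
    d = 2, I_obs = c(10, 12, 14, 16), sigma = 1
  )
  m <- merge_patterns(stream, cell, sg, TRUE)
  expect_equal(nrow(m), 1)
  expect_equal(m$I, 13)
  expect_equal(m$n, 4L)
  perm <- stream[c(3, 1, 4, 2)]
  m2 <- merge_patterns(perm, cell, sg, TRUE)
  expect_equal(m2$I, m$I)
  # single observation keeps its own sigma
  one <- merge_patterns(stream[1], cell, sg, TRUE)
  expect_equal(one$sigma, 1)
  expect_equal(one$n, 1L)
})

test_that("a noiseless full-coverage stream merges to |F|^2 with 100% completeness", {
  truth <- small_truth()
  merged <- exact_merged(truth, "native")
  sf <- truth$sf_native
  key_m <- paste(merged$h, merged$k, merged$l, merged$branch)
  # merged minus-branch rows are keyed by the canonical (plus) index
  key_s <- paste(sf$h * sf$branch, sf$k * sf$branch, sf$l * sf$branch,
                 sf$branch)
  expect_true(all(key_s %in% key_m))
  amp <- sf$amp[match(key_m, key_s)]
  expect_equal(merged$I, amp^2, tolerance = 1e-10)
  theory <- generate_reflections(truth$cell, truth$sg, truth$d_min)
  expect_equal(nrow(sirasfx:::merge_friedel(merged)), nrow(theory))
})

test_that("multiplicity totals equal the observation count", {
  truth <- small_truth()
  st <- simulate_patterns(truth, "native", sim_config(seed = 29,
                                                      n_patterns = 50))
  m <- merge_patterns(st, truth$cell, truth$sg, TRUE)
  expect_equal(sum(m$n), nrow(st))
  m2 <- merge_patterns(st, truth$cell, truth$sg, FALSE)
  expect_equal(sum(m2$n), nrow(st))
})

test_that("half-set metrics: identical halves give R_split 0 and CC 1", {
  truth <- small_truth()
  st1 <- simulate_patterns(truth, "derivative", noiseless_config())
  # two patterns with identical content -> halves agree exactly
  m <- merge_patterns(st1, truth$cell, truth$sg, TRUE)
  res <- sirasfx:::compute_half_metrics(m, m, truth$cell)
  expect_equal(res$r_split, 0)
  expect_equal(res$cc_half, 1)
  expect_equal(res$cc_ano, 1)
})

test_that("anomalous differences of a half against its negation correlate at -1", {
  truth <- small_truth()
  st <- simulate_patterns(truth, "derivative",
                          sim_config(seed = 37, n_patterns = 60))
  m <- merge_patterns(st, truth$cell, truth$sg, TRUE)
  flipped <- data.table::copy(m)
  flipped[flipped$branch == 1L, "I"] <- m$I[m$branch == -1L][
    match(paste(flipped$h, flipped$k, flipped$l)[flipped$branch == 1L],
          paste(m$h, m$k, m$l)[m$branch == -1L])]
  flipped[flipped$branch == -1L, "I"] <- m$I[m$branch == 1L][
    match(paste(flipped$h, flipped$k, flipped$l)[flipped$branch == -1L],
          paste(m$h, m$k, m$l)[m$branch == 1L])]
  res <- sirasfx:::compute_half_metrics(m, flipped, truth$cell)
  expect_equal(res$cc_ano, -1, tolerance = 1e-9)
})

test_that("R_split falls as 1/sqrt(patterns per half)", {
  truth <- small_truth()
  counts <- c(40, 80, 160, 320, 640)
  cfg <- sim_config(seed = 41, n_patterns = max(counts),
                    observed_fraction = 0.8, p_min = 0.999,
                    scale_sdlog = 1e-6, background = 400)
  st <- simulate_patterns(truth, "native", cfg)
  rs <- vapply(counts, function(n) {
    half_set_metrics(sirasfx:::subset_patterns(st, n), truth$cell, truth$sg,
                     seed = 1)$r_split
  }, 1)
  slope <- coef(lm(log(rs) ~ log(counts)))[[2]]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("selection and indexing rates match the printed percentages", {
  nat <- summarize_selection(133958, 26238, 10792)
  expect_equal(nat$selection_rate_pct, 20)
  expect_equal(nat$indexing_rate_pct, 41)
  der <- summarize_selection(583291, 298061, 85747)
  expect_equal(der$selection_rate_pct, 51)
  expect_equal(der$indexing_rate_pct, 29)
  all_in <- summarize_selection(5, 5, 5)
  expect_equal(all_in$selection_rate_pct, 100)
  expect_equal(all_in$indexing_rate_pct, 100)
  expect_error(summarize_selection(0, 0, 0), "denominator")
  expect_error(summarize_selection(10, 5, 7), "satisfy")
})

test_that("model-referenced correlations hit their exact and degenerate limits", {
  truth <- small_truth()
  merged <- exact_merged(truth, "derivative")
  expect_equal(cc_anoref(merged, truth$sf_derivative), 1, tolerance = 1e-9)
  expect_equal(cc_calc(merged, truth$sf_derivative), 1, tolerance = 1e-9)
  expect_error(cc_anoref(merged, truth$sf_native),
               "anomalous")
  # f'' = 0 model: zero-variance calculated side
  flat <- make_toy_structure(seed = 3, n_atoms = 8,
                             cell = unit_cell(15, 18, 21), d_min = 3,
                             heavy = list(occ = 0.7, f0 = 80, fp = -10,
                                          fpp = 0))
  expect_error(cc_anoref(exact_merged(truth, "derivative"),
                         flat$sf_derivative), "zero variance|variance")
  # shuffled intensities decorrelate
  sh <- data.table::copy(merged)
  set.seed(1)
  sh[, "I"] <- sample(sh$I)
  cc <- cc_calc(sh, truth$sf_derivative)
  expect_lt(abs(cc), 3 / sqrt(nrow(sirasfx:::merge_friedel(sh))))
})

test_that("shell statistics partition reflections and report completeness", {
  truth <- small_truth()
  st <- simulate_patterns(truth, "native", noiseless_config(n_patterns = 3))
  shells <- shell_statistics(st, truth$cell, truth$sg, n_shells = 4,
                             d_min = truth$d_min)
  theory <- generate_reflections(truth$cell, truth$sg, truth$d_min)
  expect_equal(sum(shells$n_theory), nrow(theory))
  expect_equal(sum(shells$n_unique), nrow(theory))
  expect_true(all(abs(shells$completeness - 100) < 1e-9))
  expect_equal(nrow(shells), 4)
})
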