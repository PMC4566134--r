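#' Preselect patterns by their low-resolution maximum intensity
#'
#' A snapshot is kept if and only if the maximum observed intensity among
#' its records with `d >= lowres_bound` exceeds (strictly) the threshold
#' — snapshots whose low-angle maximum does not exceed the threshold are
#' discarded. Pattern ordering is preserved.
#'
#' @param stream Pattern stream (needs a `d` column).
#' @param adu_threshold Intensity threshold (>= 0); the experimental
#'   analogue is 5000 detector units.
#' @param lowres_bound Low-resolution bound in Angstrom (default 3.8).
#' @return list(stream = filtered stream, n_kept, n_rejected).
#' @export
preselect_patterns <- function(stream, adu_threshold, lowres_bound = 3.8) {
  stopifnot(adu_threshold >= 0)
  stream <- as.data.table(stream)
  mx <- stream[, .(max_lowres = if (any(d >= lowres_bound))
    max(I_obs[d >= lowres_bound]) else -Inf), by = pattern_id]
  keep_ids <- mx[max_lowres > adu_threshold, pattern_id]
  list(stream = stream[pattern_id %in% keep_ids],
       n_kept = length(keep_ids),
       n_rejected = nrow(mx) - length(keep_ids))
}

#' Undo the low-angle absorber attenuation
#'
#' Records in the absorber region (`d >= d_threshold`) have intensity and
#' sigma divided by the transmission factor `T`; all other records are
#' unchanged. The correction is a plain rescaling and is not idempotent:
#' applying it twice divides by `T` twice.
#'
#' @param stream Pattern stream with a `d` column.
#' @param T Transmittance in (0, 1].
#' @param d_threshold Absorber edge in Angstrom.
#' @return Corrected stream (copy).
#' @export
absorber_correct <- function(stream, T, d_threshold) {
  if (T <= 0 || T > 1) stop("transmission factor must be in (0, 1]")
  out <- copy(as.data.table(stream))
  out[d >= d_threshold, `:=`(I_obs = I_obs / T, sigma = sigma / T)]
  out[]
}

#' Monte-Carlo merge of a pattern stream
#'
#' Maps every observation to its symmetry-reduced asymmetric-unit
#' representative (Friedel branches kept distinct on request) and merges
#' by plain arithmetic mean — the Monte-Carlo integration assumption that
#' partiality and per-pattern scale average out over many snapshots.
#'
#' @param stream Pattern stream.
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param keep_friedel_separate Keep I(+) and I(-) as separate branches?
#' @return data.table of class `merged_data`: canonical `h`, `k`, `l`,
#'   `branch` (+1/-1), `I` (mean), `sigma` (sd/sqrt(n); a lone
#'   observation keeps its own sigma), `n` (multiplicity), `d`.
#'   Attribute `mean_multiplicity` holds the overall mean.
#' @export
merge_patterns <- function(stream, cell, sg, keep_friedel_separate = TRUE) {
  stream <- as.data.table(stream)
  if (nrow(stream) == 0) stop("empty stream: nothing to merge")
  canon <- asu_map(sg, as.matrix(stream[, .(h, k, l)]),
                   friedel_separate = keep_friedel_separate)
  work <- data.table(h = canon$h, k = canon$k, l = canon$l,
                     branch = canon$branch,
                     I_obs = stream$I_obs, sig0 = stream$sigma)
  merged <- work[, .(
    I = mean(I_obs),
    sigma = if (.N > 1) stats::sd(I_obs) / sqrt(.N) else sig0[1],
    n = .N
  ), by = .(h, k, l, branch)]
  merged[, d := 1 / sqrt((h / cell$a)^2 + (k / cell$b)^2 + (l / cell$c)^2)]
  setorder(merged, -d, h, k, l, -branch)
  setattr(merged, "mean_multiplicity", mean(merged$n))
  setattr(merged, "class", c("merged_data", class(merged)))
  merged[]
}

# Friedel-merged view of a branch-separate merged table (mean of branch
# means; multiplicities added).
merge_friedel <- function(merged) {
  merged <- as.data.table(merged)
  out <- merged[, .(I = mean(I), sigma = sqrt(sum(sigma^2)) / .N,
                    n = sum(n), d = d[1]), by = .(h, k, l)]
  setorder(out, -d, h, k, l)
  out[]
}

#' Half-dataset agreement statistics
#'
#' Randomly halves the stream by pattern (seeded; ties at odd counts go
#' to half A), merges each half independently, and computes the standard
#' serial-crystallography metrics over the common reflections:
#' `R_split = 2^(-1/2) sum|I_A - I_B| / (0.5 sum(I_A + I_B))`,
#' `CC_1/2` = Pearson correlation of the two half intensities, and
#' `CC_ano` = Pearson correlation of the half anomalous differences
#' `I(+) - I(-)` over reflections with both branches in both halves.
#'
#' @param stream Pattern stream (>= 2 patterns).
#' @param cell,sg Cell and symmetry.
#' @param seed Seed for the random halving.
#' @param n_shells When > 0, per-shell values are also returned.
#' @return list with `r_split`, `cc_half`, `cc_ano`, `n_common`,
#'   `n_ano`, and (optionally) `shells` (data.table).
#' @export
half_set_metrics <- function(stream, cell, sg, seed = 1L, n_shells = 0L) {
  stream <- as.data.table(stream)
  ids <- sort(unique(stream$pattern_id))
  if (length(ids) < 2) stop("need at least two patterns")
  set.seed(seed)
  perm <- sample(ids)
  half_a <- perm[seq_len(ceiling(length(ids) / 2))]
  ma <- merge_patterns(stream[pattern_id %in% half_a], cell, sg, TRUE)
  mb <- merge_patterns(stream[!pattern_id %in% half_a], cell, sg, TRUE)
  compute_half_metrics(ma, mb, cell, n_shells)
}

# Pearson correlation that degrades to NA instead of warning when one
# side has zero variance
safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# metrics from two already-merged halves
compute_half_metrics <- function(ma, mb, cell, n_shells = 0L) {
  fa <- merge_friedel(ma)
  fb <- merge_friedel(mb)
  common <- merge(fa, fb, by = c("h", "k", "l"), suffixes = c("_a", "_b"))
  if (nrow(common) == 0) stop("halves share no reflections")
  r_split <- function(ia, ib) {
    sum(abs(ia - ib)) / (0.5 * sum(ia + ib)) / sqrt(2)
  }
  da <- ano_differences(ma)
  db <- ano_differences(mb)
  ano <- merge(da, db, by = c("h", "k", "l"), suffixes = c("_a", "_b"))
  out <- list(
    r_split = r_split(common$I_a, common$I_b),
    cc_half = safe_cor(common$I_a, common$I_b),
    cc_ano = safe_cor(ano$dI_a, ano$dI_b),
    n_common = nrow(common),
    n_ano = nrow(ano)
  )
  if (n_shells > 0) {
    common[, shell := resolution_shell(d_a, n_shells, range(d_a))]
    out$shells <- common[, .(
      d_min = min(d_a), d_max = max(d_a), n = .N,
      r_split = r_split(I_a, I_b),
      cc_half = safe_cor(I_a, I_b)
    ), by = shell][order(shell)]
  }
  out
}

# anomalous differences I(+) - I(-) for reflections with both branches
ano_differences <- function(merged) {
  merged <- as.data.table(merged)
  wide <- dcast(merged, h + k + l ~ branch, value.var = "I")
  if (!all(c("1", "-1") %in% names(wide))) {
    return(data.table(h = integer(), k = integer(), l = integer(),
                      dI = numeric()))
  }
  wide <- wide[!is.na(`1`) & !is.na(`-1`)]
  wide[, dI := `1` - `-1`]
  wide[, .(h, k, l, dI)]
}

# shell index from d-spacings: equal volume in 1/d^3
resolution_shell <- function(d, n_shells, d_range) {
  lo <- 1 / max(d_range)^3
  hi <- 1 / min(d_range)^3
  br <- seq(lo, hi, length.out = n_shells + 1)
  idx <- findInterval(1 / d^3, br, rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(idx)
}

#' Correlation of observed anomalous differences with a reference model
#'
#' The reference-based anomalous correlation: Pearson correlation between
#' the observed `I(+) - I(-)` and the model-calculated
#' `|F+|^2 - |F-|^2`, over reflections with both Friedel branches
#' measured. Unlike the half-dataset `CC_ano` it does not pay the noise
#' penalty of halving the data, so it resolves weak anomalous signal at
#' much lower multiplicity.
#'
#' @param merged Branch-separate `merged_data`.
#' @param model_sf Anomalous structure factors ([calc_structure_factors()]
#'   with `include_anomalous = TRUE`) on a Friedel-separate reflection
#'   list.
#' @return Pearson correlation (single number).
#' @export
cc_anoref <- function(merged, model_sf) {
  if (!isTRUE(attr(model_sf, "anomalous"))) {
    stop("model structure factors must include anomalous terms")
  }
  obs <- ano_differences(merged)
  calc <- model_ano_differences(model_sf)
  both <- merge(obs, calc, by = c("h", "k", "l"))
  if (nrow(both) < 3) stop("fewer than 3 reflections with both branches")
  if (stats::sd(both$dI_calc) < 1e-12) {
    stop("model anomalous differences have zero variance (f'' = 0?)")
  }
  stats::cor(both$dI, both$dI_calc)
}

# model |F+|^2 - |F-|^2 keyed by the +1-branch canonical index
model_ano_differences <- function(model_sf) {
  sf <- as.data.table(as.data.frame(model_sf))
  plus <- sf[branch == 1L]
  minus <- sf[branch == -1L][, .(h = -h, k = -k, l = -l, amp_minus = amp)]
  both <- merge(plus[, .(h, k, l, amp_plus = amp)], minus,
                by = c("h", "k", "l"))
  both[, .(h, k, l, dI_calc = amp_plus^2 - amp_minus^2)]
}

#' Correlation of merged intensities with model intensities
#'
#' Pearson correlation of the Friedel-merged observed intensities against
#' model `|F|^2`.
#'
#' @inheritParams cc_anoref
#' @return Pearson correlation.
#' @export
cc_calc <- function(merged, model_sf) {
  obs <- merge_friedel(merged)
  sf <- as.data.table(as.data.frame(model_sf))
  if ("branch" %in% names(sf)) {
    calc <- sf[, .(h = ifelse(branch == 1L, h, -h),
                   k = ifelse(branch == 1L, k, -k),
                   l = ifelse(branch == 1L, l, -l), I2 = amp^2)]
    calc <- calc[, .(I_calc = mean(I2)), by = .(h, k, l)]
  } else {
    calc <- sf[, .(h, k, l, I_calc = amp^2)]
  }
  both <- merge(obs, calc, by = c("h", "k", "l"))
  if (nrow(both) < 3) stop("fewer than 3 common reflections")
  stats::cor(both$I, both$I_calc)
}

#' Selection and indexing rate summary
#'
#' @param collected,selected,indexed Image counts with
#'   `0 <= indexed <= selected <= collected`.
#' @return list with exact and integer-rounded (half away from zero)
#'   percentages: `selection_rate`, `indexing_rate`,
#'   `selection_rate_pct`, `indexing_rate_pct`.
#' @export
summarize_selection <- function(collected, selected, indexed) {
  if (collected <= 0 || selected <= 0) stop("zero denominator")
  if (!(indexed <= selected && selected <= collected && indexed >= 0)) {
    stop("counts must satisfy 0 <= indexed <= selected <= collected")
  }
  round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  sel <- 100 * selected / collected
  ind <- 100 * indexed / selected
  list(selection_rate = sel, indexing_rate = ind,
       selection_rate_pct = round_half_away(sel),
       indexing_rate_pct = round_half_away(ind))
}

#' Per-shell data-quality statistics
#'
#' Equal-volume shells in 1/d^3 between the data's resolution limits.
#' Completeness is measured against the theoretical unique reflection
#' list; multiplicity, R_split, CC_1/2 and mean I/sigma come from the
#' stream.
#'
#' @param stream Pattern stream.
#' @param cell,sg Cell and symmetry.
#' @param n_shells Number of shells (>= 1).
#' @param d_min Theoretical resolution limit used for completeness; when
#'   `NULL`, the minimum observed d-spacing.
#' @param seed Seed for the half-dataset split.
#' @return data.table with one row per shell: `shell`, `d_max`, `d_min`,
#'   `n_unique`, `n_theory`, `completeness`, `multiplicity`,
#'   `mean_i_over_sigma`, `r_split`, `cc_half`.
#' @export
shell_statistics <- function(stream, cell, sg, n_shells = 6L, d_min = NULL,
                             seed = 1L) {
  stopifnot(n_shells >= 1)
  stream <- as.data.table(stream)
  merged <- merge_patterns(stream, cell, sg, keep_friedel_separate = FALSE)
  if (is.null(d_min)) d_min <- min(merged$d)
  theory <- generate_reflections(cell, sg, d_min, keep_friedel_separate = FALSE)
  rng <- c(d_min, max(theory$d))
  theory[, shell := resolution_shell(d, n_shells, rng)]
  merged[, shell := resolution_shell(d, n_shells, rng)]
  hm <- half_set_metrics(stream, cell, sg, seed = seed, n_shells = n_shells)
  th_n <- theory[, .(n_theory = .N), by = shell]
  ob <- merged[, .(n_unique = .N, multiplicity = mean(n),
                   mean_i_over_sigma = mean(I / sigma),
                   d_max = max(d), d_min = min(d)), by = shell]
  out <- merge(th_n, ob, by = "shell", all.x = TRUE)
  out <- merge(out, hm$shells[, .(shell, r_split, cc_half)],
               by = "shell", all.x = TRUE)
  out[is.na(n_unique), n_unique := 0L]
  out[, completeness := 100 * n_unique / n_theory]
  setorder(out, shell)
  out[]
}
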