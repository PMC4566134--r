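#' Convert merged intensities to amplitudes
#'
#' Square-root conversion with zero truncation: `|F| = sqrt(max(I, 0))`,
#' `sigma_F = sigma_I / (2 |F|)` when `|F| > 0`, else `sqrt(sigma_I)`.
#' Negative intensities are truncated to amplitude 0 and counted.
#'
#' @param merged A `merged_data` table (any table with `I`, `sigma`).
#' @return Copy with added columns `F_amp`, `sigma_F`, `truncated`;
#'   attribute `n_truncated`.
#' @export
to_amplitudes <- function(merged) {
  out <- copy(as.data.table(merged))
  out[, truncated := I < 0]
  out[, F_amp := sqrt(pmax(I, 0))]
  out[, sigma_F := ifelse(F_amp > 0, sigma / (2 * F_amp), sqrt(abs(sigma)))]
  setattr(out, "n_truncated", sum(out$truncated))
  out[]
}

#' Scale a derivative dataset onto its native reference
#'
#' Friedel-merged amplitudes of both datasets are compared shell by
#' shell; a straight-line fit of `log(<|F_P|> / <|F_PH|>)` against `s^2`
#' yields a global scale `k` and relative B-factor, and the derivative
#' amplitudes are multiplied by `k * exp(-B_rel s^2 / 4)`. The isomorphous
#' residual `R_iso = sum|dF_iso| / sum|F_P|` is reported after scaling.
#'
#' @param native,derivative Branch-separate `merged_data` tables.
#' @param n_shells Shells for the scaling fit.
#' @return list of class `scaled_pair`: `data` (data.table with `h,k,l,d,
#'   F_P`, `F_PH` (scaled Friedel-mean), `dF_iso`, `dI_ano` (derivative,
#'   scaled by k^2), plus per-branch scaled derivative amplitudes
#'   `F_PH_plus`/`F_PH_minus`), `k`, `b_rel`, `r_iso`, `n_common`.
#' @export
scale_derivative <- function(native, derivative, n_shells = 6L) {
  fn <- to_amplitudes(merge_friedel(native))
  fd <- to_amplitudes(merge_friedel(derivative))
  common <- merge(fn[, .(h, k, l, d, F_P = F_amp)],
                  fd[, .(h, k, l, F_PH = F_amp)], by = c("h", "k", "l"))
  if (nrow(common) < 10) stop("fewer than 10 common reflections")
  common[, s2 := 1 / d^2]
  common[, shell := resolution_shell(d, n_shells, range(d))]
  fit_dt <- common[F_P > 0 & F_PH > 0,
                   .(ratio = log(mean(F_P) / mean(F_PH)), s2 = mean(s2)),
                   by = shell]
  fit <- stats::lm(ratio ~ s2, data = fit_dt)
  k_scale <- exp(coef(fit)[[1]])
  b_rel <- 4 * coef(fit)[[2]]
  # beware: plain `k` would resolve to the Miller-index column in scope
  scale_vec <- k_scale * exp(-b_rel * common$s2 / 4)
  common[, F_PH := F_PH * scale_vec]
  common[, dF_iso := F_PH - F_P]
  r_iso <- common[, sum(abs(dF_iso)) / sum(F_P)]
  # per-branch scaled derivative amplitudes and anomalous differences
  # (both Friedel branches of a merged dataset share the canonical index)
  da <- to_amplitudes(as.data.table(derivative))
  wide <- dcast(da, h + k + l ~ branch, value.var = "F_amp")
  if (!"1" %in% names(wide)) wide[, `1` := NA_real_]
  if (!"-1" %in% names(wide)) wide[, `-1` := NA_real_]
  setnames(wide, c("1", "-1"), c("Fp_raw", "Fm_raw"))
  common <- merge(common, wide, by = c("h", "k", "l"), all.x = TRUE)
  sc2 <- k_scale * exp(-b_rel * common$s2 / 4)
  common[, F_PH_plus := Fp_raw * sc2]
  common[, F_PH_minus := Fm_raw * sc2]
  common[, dI_ano := F_PH_plus^2 - F_PH_minus^2]
  common[, c("Fp_raw", "Fm_raw") := NULL]
  setorder(common, -d)
  structure(list(data = common[], k = k_scale, b_rel = b_rel, r_iso = r_iso,
                 n_common = nrow(common)),
            class = "scaled_pair")
}

#' Difference Patterson synthesis
#'
#' `P(u) = (1/V) sum_h c_h cos(2 pi h.u)` with nonnegative coefficients
#' (squared isomorphous or anomalous differences), expanded over the full
#' symmetry-equivalent set, computed by FFT and standardized to sigma
#' units (mean 0, sd 1).
#'
#' @param hkl n x 3 matrix (or data.frame with `h,k,l`) of unique indices.
#' @param coeff Nonnegative coefficients, same length.
#' @param cell,sg Cell and symmetry.
#' @param grid_dims Grid dimensions (defaults from the data resolution).
#' @param standardize Standardize to sigma units (default) or return the
#'   raw synthesis.
#' @return A standardized [real_space_grid()] of kind `"patterson"`.
#' @export
patterson_map <- function(hkl, coeff, cell, sg, grid_dims = NULL,
                          standardize = TRUE) {
  H <- if (is.matrix(hkl)) hkl else as.matrix(as.data.frame(hkl)[, c("h", "k", "l")])
  storage.mode(H) <- "double"
  keep <- is.finite(coeff) & rowSums(abs(H)) > 0
  H <- H[keep, , drop = FALSE]
  coeff <- coeff[keep]
  if (!length(coeff) || all(coeff == 0)) stop("all Patterson coefficients are zero")
  if (any(coeff < 0)) stop("Patterson coefficients must be nonnegative")
  sf <- data.frame(h = H[, 1], k = H[, 2], l = H[, 3], amp = coeff, phase = 0)
  # the Patterson has the symmetry of the Laue group: expand over the
  # rotation parts only (screw translations carry no phase here)
  laue <- sg
  laue$ops <- lapply(sg$ops, function(o) list(R = o$R, t = c(0, 0, 0)))
  g <- synthesize_map(sf, cell, laue, grid_dims, method = "fft",
                      kind = "patterson")
  if (standardize) standardize_grid(g) else g
}

#' Harker sections of a space group
#'
#' Derives, from pairwise differences of the symmetry operators, the
#' planes that contain single-site self-vectors. For `P212121` these are
#' the three sections `u = 1/2`, `v = 1/2`, `w = 1/2`; `P1` has none.
#'
#' @param sg A [space_group()].
#' @return List of sections, each `list(axis = 1|2|3, level = 1/2,
#'   vector_fn = function(site) fractional self-vector)`.
#' @export
harker_sections <- function(sg) {
  if (!sg$name %in% c("P1", "P212121")) stop("unsupported space group")
  sections <- list()
  ops <- sg$ops
  for (m in seq_along(ops)) {
    if (m == 1) next
    R <- ops[[m]]$R
    t <- ops[[m]]$t
    dR <- diag(3) - R
    const_axes <- which(apply(dR, 1, function(r) all(r == 0)))
    if (length(const_axes) != 1) next
    ax <- const_axes
    level <- (-t[ax]) %% 1
    vector_fn <- local({
      dR_ <- dR; t_ <- t
      function(site) as.vector(dR_ %*% site - t_) %% 1
    })
    sections[[length(sections) + 1]] <- list(axis = ax, level = level,
                                             dR = dR, t = t,
                                             vector_fn = vector_fn)
  }
  sections
}

# all symmetry/origin/hand-equivalent copies of a fractional site
equivalent_sites <- function(sg, site) {
  out <- list()
  for (hand in c(1, -1)) {
    s0 <- hand * site
    for (o in sg$ops) {
      s1 <- (as.vector(o$R %*% s0) + o$t) %% 1
      for (i in seq_len(nrow(sg$origin_shifts))) {
        out[[length(out) + 1]] <- (s1 + sg$origin_shifts[i, ]) %% 1
      }
    }
  }
  do.call(rbind, out)
}

# minimum cartesian distance between a site and any equivalent of a
# reference site (modulo lattice, symmetry, origin shifts, hand)
site_distance <- function(sg, cell, site, reference) {
  eq <- equivalent_sites(sg, reference)
  df <- abs(sweep(eq, 2, site %% 1, "-"))
  df <- pmin(df, 1 - df)
  min(sqrt((df[, 1] * cell$a)^2 + (df[, 2] * cell$b)^2 +
             (df[, 3] * cell$c)^2))
}

#' Heavy-atom site search by the Patterson symmetry-minimum function
#'
#' Scans candidate sites on a fractional grid; each candidate is scored
#' by the minimum, over all Harker self-vectors and over all supplied
#' (standardized) Patterson maps, of the interpolated map value. Nearby
#' candidates are clustered and the survivors ranked by score.
#'
#' @param maps A single [real_space_grid()] or list of them (isomorphous
#'   and/or anomalous difference Pattersons), already standardized.
#' @param cell,sg Cell and symmetry (must have Harker sections).
#' @param step Fractional grid step of the scan (default 1/48).
#' @param n_candidates Number of ranked candidates to return.
#' @param merge_radius Cluster radius in Angstrom.
#' @return data.table: `x`, `y`, `z` (fractional site), `score` (sigma
#'   units), plus the inverted-hand mate `x_inv`, `y_inv`, `z_inv`.
#' @export
search_sites <- function(maps, cell, sg, step = 1 / 48, n_candidates = 10,
                         merge_radius = 2.0) {
  if (inherits(maps, "real_space_grid")) maps <- list(maps)
  sections <- harker_sections(sg)
  if (!length(sections)) stop("space group has no Harker sections")
  min_dim <- min(vapply(maps, function(m) min(m$dim), 1))
  if (step > 1 / (min_dim / 2)) {
    warning("scan step coarser than half the Patterson grid spacing")
  }
  # the Patterson origin peak dominates the map; self-vectors landing
  # within the exclusion radius of the origin (as all three do for a site
  # at the origin) are masked rather than credited
  origin_excl <- 0.1 * min(cell$a, cell$b, cell$c)
  score_candidates <- function(cand) {
    score <- rep(Inf, nrow(cand))
    for (sec in sections) {
      # vectorized self-vector evaluation: v = (I - R) site - t
      vecs <- sweep(cand %*% t(sec$dR), 2, sec$t, "-") %% 1
      df <- pmin(vecs, 1 - vecs)
      dorig <- sqrt((df[, 1] * cell$a)^2 + (df[, 2] * cell$b)^2 +
                      (df[, 3] * cell$c)^2)
      near_origin <- dorig < origin_excl
      for (m in maps) {
        val <- grid_interp(m, vecs)
        val[near_origin] <- -1
        score <- pmin(score, val)
      }
    }
    score
  }
  gx <- seq(0, 0.5 - step, by = step)
  gz <- seq(0, 0.5 - step, by = step)
  cand <- as.matrix(expand.grid(x = gx, y = gx, z = gz))
  score <- score_candidates(cand)
  ord <- order(score, decreasing = TRUE)
  keep <- list()
  for (i in ord) {
    site <- cand[i, ]
    ok <- TRUE
    for (kpt in keep) {
      if (site_distance(sg, cell, site, kpt$site) < merge_radius) {
        ok <- FALSE; break
      }
    }
    if (ok) keep[[length(keep) + 1]] <- list(site = site, score = score[i])
    if (length(keep) >= n_candidates) break
  }
  # local refinement: the coarse scan quantizes the site to the step, a
  # large share of an Angstrom; a fine scan around each survivor removes it
  fine <- seq(-step, step, by = step / 5)
  offsets <- as.matrix(expand.grid(fine, fine, fine))
  keep <- lapply(keep, function(kpt) {
    local <- sweep(offsets, 2, kpt$site, "+") %% 1
    sc <- score_candidates(local)
    j <- which.max(sc)
    list(site = local[j, ], score = sc[j])
  })
  inv <- lapply(keep, function(kpt) (as.vector(sg$enantiomorph_flip %*% kpt$site)) %% 1)
  data.table(
    x = vapply(keep, function(p) p$site[1], 1),
    y = vapply(keep, function(p) p$site[2], 1),
    z = vapply(keep, function(p) p$site[3], 1),
    score = vapply(keep, function(p) p$score, 1),
    x_inv = vapply(inv, `[`, 1, 1),
    y_inv = vapply(inv, `[`, 1, 2),
    z_inv = vapply(inv, `[`, 1, 3)
  )
}

#' Anomalous difference Fourier map
#'
#' Fourier synthesis with coefficients `dF_ano * exp(i (phi - 90 deg))`
#' using protein phases; peaks in sigma units mark anomalous scatterers.
#'
#' @param scaled A [scale_derivative()] result (for `dI_ano` and
#'   amplitudes), or a data.table with `h,k,l` and `dF_ano`.
#' @param phases A phase set (data.table with `h,k,l,phi_best` in
#'   degrees) for the same indices.
#' @param cell,sg Cell and symmetry.
#' @param grid_dims Optional grid dimensions.
#' @param n_peaks Peaks to report.
#' @return list(grid = standardized [real_space_grid()], peaks =
#'   data.table with fractional positions and heights in sigma units).
#' @export
anomalous_difference_fourier <- function(scaled, phases, cell, sg,
                                         grid_dims = NULL, n_peaks = 10) {
  dat <- if (inherits(scaled, "scaled_pair")) {
    d <- scaled$data[!is.na(F_PH_plus) & !is.na(F_PH_minus)]
    d[, dF_ano := F_PH_plus - F_PH_minus]
    d[, .(h, k, l, dF_ano)]
  } else {
    as.data.table(scaled)[, .(h, k, l, dF_ano)]
  }
  both <- merge(dat, as.data.table(phases)[, .(h, k, l, phi_best)],
                by = c("h", "k", "l"))
  if (nrow(both) == 0) stop("no overlap between measured and phased reflections")
  sf <- both[, .(h, k, l, amp = abs(dF_ano),
                 phase = (phi_best - 90 + 180 * (dF_ano < 0)) %% 360)]
  g <- synthesize_map(sf, cell, sg, grid_dims, kind = "density")
  g <- standardize_grid(g)
  list(grid = g, peaks = grid_peaks(g, n_peaks = n_peaks, min_sep = 2.0))
}
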