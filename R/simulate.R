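#' Simulation configuration for synthetic SFX pattern streams
#'
#' Collects every knob of the snapshot generator. The defaults emulate the
#' statistical structure of post-indexing serial femtosecond
#' crystallography observations: each snapshot records a random subset of
#' the reflections, attenuated by an i.i.d. partiality factor and a
#' per-pattern scale, with counting-type Gaussian noise, an optional
#' low-angle absorber, and a fraction of too-weak snapshots that the
#' preselection step is meant to reject.
#'
#' @param seed Integer seed; fully determines the stream.
#' @param n_patterns Number of snapshots.
#' @param observed_fraction Probability that a given unique reflection
#'   (Friedel mates counted separately) appears on a given pattern.
#' @param p_min Lower edge of the uniform partiality law on `[p_min, 1]`.
#' @param scale_sdlog Log-normal sd of the per-pattern scale factor
#'   (meanlog chosen so the expected scale is 1).
#' @param background Additive variance term of the noise model
#'   `sigma(I) = sqrt(max(I,0) + background)`.
#' @param absorber `NULL`, or `list(T = transmittance in (0,1],
#'   d_threshold = Angstrom)`; records with `d >= d_threshold` (the
#'   low-angle region) are multiplied by `T`.
#' @param weak_fraction Fraction of patterns simulated as too weak.
#' @param weak_scale Scale multiplier applied to weak patterns.
#' @param counting_noise When `FALSE` the signal-dependent part of the
#'   noise variance is dropped (with `background = 0` this gives the
#'   noiseless limit; reported sigmas are then floored at 1e-6).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_patterns = 500L, observed_fraction = 0.3,
                       p_min = 0.1, scale_sdlog = 0.4, background = 25,
                       absorber = NULL, weak_fraction = 0, weak_scale = 1e-3,
                       counting_noise = TRUE) {
  stopifnot(observed_fraction > 0, observed_fraction <= 1,
            p_min > 0, p_min <= 1, background >= 0,
            weak_fraction >= 0, weak_fraction <= 1)
  if (!is.null(absorber)) {
    stopifnot(absorber$T > 0, absorber$T <= 1, absorber$d_threshold > 0)
  }
  structure(list(seed = as.integer(seed), n_patterns = as.integer(n_patterns),
                 observed_fraction = observed_fraction, p_min = p_min,
                 scale_sdlog = scale_sdlog, background = background,
                 absorber = absorber, weak_fraction = weak_fraction,
                 weak_scale = weak_scale, counting_noise = counting_noise),
            class = "sim_config")
}

#' Build the toy ground-truth structure (native + heavy-atom derivative)
#'
#' Places `n_atoms` light point scatterers uniformly in the cell with a
#' minimum-separation rejection rule, plus one mercury-like heavy site
#' carrying anomalous corrections. The derivative structure is the native
#' one with the heavy site appended, so the pair is perfectly isomorphous.
#'
#' The default light scatterer is residue-scale (f0 = 30 e, a lumped
#' amino-acid-sized cluster) rather than a single carbon: with 40 sites
#' this makes the heavy-to-protein scattering ratio, and hence the
#' isomorphous (R_iso ~ 0.15) and Bijvoet (a few percent) signal sizes,
#' match the regime of a ~300-residue protein with one Hg, which is the
#' regime the phasing comparison is about.
#'
#' @param seed Integer seed.
#' @param n_atoms Number of light atoms (default 40).
#' @param cell A [unit_cell()] (default 30 x 40 x 50 Angstrom).
#' @param sg A [space_group()] (default P212121).
#' @param d_min Resolution limit for the true reflection list (default 2.5).
#' @param heavy list(occ, f0, fp, fpp) for the heavy site; default
#'   occupancy 0.7, f0 80 e (Hg-like), f' -10 e, f'' 9.75 e (Hg at
#'   12.6 keV).
#' @param light_f0 Normal scattering factor of the light scatterers
#'   (default 30 e, residue-scale).
#' @param b_iso Common isotropic B-factor (Angstrom^2).
#' @param min_sep Minimum inter-atomic separation over all symmetry
#'   copies, Angstrom.
#' @return List of class `ground_truth`: `cell`, `sg`, `d_min`,
#'   `atoms_native`, `atoms_derivative`, `heavy_sites`, `refl`
#'   (Friedel-separate reflection table), `sf_native` (no anomalous),
#'   `sf_derivative` (anomalous included).
#' @export
make_toy_structure <- function(seed = 1L, n_atoms = 40L,
                               cell = unit_cell(30, 40, 50),
                               sg = space_group("P212121"),
                               d_min = 2.5,
                               heavy = list(occ = 0.7, f0 = 80, fp = -10,
                                            fpp = 9.75),
                               light_f0 = 30, b_iso = 10, min_sep = 2.2) {
  stopifnot(n_atoms >= 1, heavy$occ >= 0, heavy$occ <= 1)
  set.seed(seed)
  placed <- matrix(numeric(0), ncol = 3)
  sep_ok <- function(p, others) {
    if (nrow(others) == 0) return(TRUE)
    # p against all symmetry copies of existing atoms (and its own copies)
    test <- rbind(others, p)
    copies <- do.call(rbind, lapply(sg$ops, function(o) {
      sweep(test %*% t(o$R), 2, o$t, "+") %% 1
    }))
    df <- abs(sweep(copies, 2, p, "-"))
    df <- pmin(df, 1 - df)
    dist <- sqrt((df[, 1] * cell$a)^2 + (df[, 2] * cell$b)^2 +
                   (df[, 3] * cell$c)^2)
    dist <- dist[dist > 1e-6]
    all(dist >= min_sep)
  }
  tries <- 0
  while (nrow(placed) < n_atoms + 1) {
    p <- runif(3)
    if (sep_ok(p, placed)) placed <- rbind(placed, p)
    tries <- tries + 1
    if (tries > 200 * (n_atoms + 1)) {
      stop("could not place atoms at the requested minimum separation")
    }
  }
  native <- atom_sites(placed[seq_len(n_atoms), 1], placed[seq_len(n_atoms), 2],
                       placed[seq_len(n_atoms), 3],
                       occ = 1, b = b_iso, f0 = light_f0,
                       label = sprintf("C%03d", seq_len(n_atoms)))
  hvy <- atom_sites(placed[n_atoms + 1, 1], placed[n_atoms + 1, 2],
                    placed[n_atoms + 1, 3],
                    occ = heavy$occ, b = b_iso, f0 = heavy$f0,
                    fp = heavy$fp, fpp = heavy$fpp, label = "HG1")
  deriv <- rbind(native, hvy)
  class(deriv) <- class(native)
  refl <- generate_reflections(cell, sg, d_min, keep_friedel_separate = TRUE)
  sf_nat <- calc_structure_factors(native, cell, sg, refl,
                                   include_anomalous = FALSE)
  sf_der <- calc_structure_factors(deriv, cell, sg, refl,
                                   include_anomalous = TRUE)
  structure(list(cell = cell, sg = sg, d_min = d_min,
                 atoms_native = native, atoms_derivative = deriv,
                 heavy_sites = hvy, refl = refl,
                 sf_native = sf_nat, sf_derivative = sf_der),
            class = "ground_truth")
}

#' Simulate a post-indexing SFX pattern stream
#'
#' For each snapshot: draw a log-normal scale `g` (multiplied by
#' `weak_scale` for the weak fraction); include each unique reflection
#' (Friedel mates as distinct observables) with probability
#' `observed_fraction`; each included record gets
#' `I_obs = g * p * T_eff * |F|^2 + eps` with partiality
#' `p ~ U[p_min, 1]`, absorber transmission `T_eff` applied to records at
#' `d >= d_threshold`, and Gaussian noise
#' `eps ~ N(0, sqrt(max(signal, 0) + background))`. Negative observed
#' intensities are retained.
#'
#' @param truth A [make_toy_structure()] result.
#' @param which `"native"` or `"derivative"`.
#' @param config A [sim_config()].
#' @return data.table (pattern stream) with columns `pattern_id`, `h`,
#'   `k`, `l`, `d`, `I_obs`, `sigma`.
#' @export
simulate_patterns <- function(truth, which = c("native", "derivative"),
                              config = sim_config()) {
  which <- match.arg(which)
  sf <- if (which == "native") truth$sf_native else truth$sf_derivative
  if (nrow(sf) == 0) stop("empty reflection set")
  set.seed(config$seed + if (which == "derivative") 500000L else 0L)
  n_ref <- nrow(sf)
  n_pat <- config$n_patterns
  I_true <- sf$amp^2
  d <- sf$d
  scale <- exp(rnorm(n_pat, -config$scale_sdlog^2 / 2, config$scale_sdlog))
  weak <- runif(n_pat) < config$weak_fraction
  scale[weak] <- scale[weak] * config$weak_scale
  T_eff <- rep(1, n_ref)
  if (!is.null(config$absorber)) {
    T_eff[d >= config$absorber$d_threshold] <- config$absorber$T
  }
  # one Bernoulli draw per (pattern, reflection), pattern-major order
  obs <- runif(n_pat * n_ref) < config$observed_fraction
  pat_idx <- rep(seq_len(n_pat), each = n_ref)[obs]
  ref_idx <- rep(seq_len(n_ref), times = n_pat)[obs]
  n_obs <- length(ref_idx)
  part <- runif(n_obs, config$p_min, 1)
  signal <- scale[pat_idx] * part * T_eff[ref_idx] * I_true[ref_idx]
  sig <- sqrt(if (config$counting_noise) pmax(signal, 0) + config$background
              else config$background + numeric(n_obs))
  I_obs <- signal + if (any(sig > 0)) rnorm(n_obs, 0, sig) else 0
  sig <- pmax(sig, 1e-6)
  out <- data.table(
    pattern_id = pat_idx,
    h = sf$h[ref_idx], k = sf$k[ref_idx], l = sf$l[ref_idx],
    d = d[ref_idx], I_obs = I_obs, sigma = sig
  )
  setattr(out, "which", which)
  out[]
}
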