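#' Heavy-atom structure factors with Friedel-mate bookkeeping
#'
#' Computes, for each reflection `h` of a (Friedel-merged) reflection
#' list, the heavy-atom contribution `F_H(h)` and the conjugated mate
#' `Fbar_H = conj(F_H(-h))`. Without f'' the two coincide. Also returns
#' the magnitude of the imaginary-only component `|F_H''| = f'' |S(h)|`
#' and the normal-component phase, used by the SAD sine-rule
#' parameterization.
#'
#' @param model [atom_sites()] table of heavy sites.
#' @param cell,sg Cell and symmetry.
#' @param refl Reflection table (`h,k,l`; Friedel-merged representatives).
#' @return data.table: `h,k,l`, `FH` (complex), `FHbar` (complex),
#'   `FH_imag` (|F_H''|), `phi_H` (degrees, phase of the normal part).
#' @export
heavy_atom_sf <- function(model, cell, sg, refl) {
  refl <- as.data.frame(refl)[, c("h", "k", "l")]
  plus <- calc_structure_factors(model, cell, sg, refl, include_anomalous = TRUE)
  minus_refl <- data.frame(h = -refl$h, k = -refl$k, l = -refl$l)
  minus <- calc_structure_factors(model, cell, sg, minus_refl,
                                  include_anomalous = TRUE)
  normal <- calc_structure_factors(model, cell, sg, refl,
                                   include_anomalous = FALSE)
  # f''-only component: F(ano) - F(normal+f') = i f'' S
  noimag <- copy(model)
  noimag$fpp <- 0
  base <- calc_structure_factors(noimag, cell, sg, refl, include_anomalous = TRUE)
  data.table(h = refl$h, k = refl$k, l = refl$l,
             FH = plus$F, FHbar = Conj(minus$F),
             FH_imag = Mod(plus$F - base$F),
             phi_H = (Arg(base$F) * 180 / pi) %% 360)
}

# uniform trial-phase grid in degrees
phase_grid <- function(step = 5) seq(0, 360 - step, by = step)

#' Blow-Crick phase probabilities for one mode
#'
#' For every reflection, evaluates the phase probability on a uniform
#' grid of trial phases. With trial native phase `phi`:
#' `F_PHcalc(+/-) = |F_P| e^{i phi} + F_H(+/-)`; the isomorphous lack of
#' closure compares Friedel-mean observed and calculated derivative
#' amplitudes, the anomalous lack of closure compares their Friedel
#' differences. `P(phi) propto exp(-eps_iso^2 / 2 E_iso^2)` (SIR term)
#' `x exp(-eps_ano^2 / 2 E_ano^2)` (anomalous term); SIRAS multiplies
#' both, SIR uses only the first. SAD phases the derivative itself: the
#' trial phase is the derivative total phase and the calculated Bijvoet
#' difference follows the sine rule
#' `D_calc(phi_T) = -2 |F_H''| sin(phi_T - phi_H)`.
#' Centric reflections are evaluated only at their two allowed phases.
#' Probabilities are normalized to sum to 1 per reflection.
#'
#' @param dat data.table with per-reflection columns `F_P` (native
#'   amplitude; NA allowed in SAD mode), `F_PH_plus`, `F_PH_minus`
#'   (observed derivative Friedel amplitudes), `FH`, `FHbar`, `FH_imag`,
#'   `phi_H`, `E_iso`, `E_ano`, `centric`, `phi_restrict`.
#' @param mode `"SIR"`, `"SAD"` or `"SIRAS"`.
#' @param step Trial-phase grid step in degrees (must divide 360).
#' @return list(`prob` = n x n_phi matrix of normalized probabilities,
#'   `phi` = grid in degrees).
#' @export
phase_probability <- function(dat, mode = c("SIRAS", "SIR", "SAD"), step = 5) {
  mode <- match.arg(mode)
  stopifnot(360 %% step == 0)
  phi <- phase_grid(step)
  n <- nrow(dat)
  if (any(!is.finite(dat$E_iso)) && mode != "SAD" ||
      any(!is.finite(dat$E_ano)) && mode != "SIR") {
    stop("lack-of-closure estimates must be finite")
  }
  if (mode != "SAD" && any(dat$E_iso <= 0)) stop("E_iso must be positive")
  if (mode != "SIR" && any(dat$E_ano <= 0)) stop("E_ano must be positive")
  if (mode != "SAD" && any(!is.finite(dat$F_P))) {
    stop("native amplitude required for SIR/SIRAS")
  }
  eiphi <- exp(1i * outer(rep(1, n), phi * pi / 180))
  loglik <- matrix(0, n, length(phi))
  fph_obs_mean <- (dat$F_PH_plus + dat$F_PH_minus) / 2
  dano_obs <- dat$F_PH_plus - dat$F_PH_minus
  if (mode %in% c("SIR", "SIRAS")) {
    Fp_calc <- dat$F_P * eiphi + dat$FH
    Fm_calc <- dat$F_P * eiphi + dat$FHbar
    calc_mean <- (Mod(Fp_calc) + Mod(Fm_calc)) / 2
    eps_iso <- fph_obs_mean - calc_mean
    loglik <- loglik - eps_iso^2 / (2 * dat$E_iso^2)
  }
  if (mode == "SIRAS") {
    dano_calc <- Mod(Fp_calc) - Mod(Fm_calc)
    eps_ano <- dano_obs - dano_calc
    loglik <- loglik - eps_ano^2 / (2 * dat$E_ano^2)
  }
  if (mode == "SAD") {
    # trial phase is the derivative total phase phi_T
    dphi <- outer(-dat$phi_H * pi / 180, phi * pi / 180, "+")
    dano_calc <- -2 * dat$FH_imag * sin(dphi)
    eps_ano <- dano_obs - dano_calc
    loglik <- loglik - eps_ano^2 / (2 * dat$E_ano^2)
  }
  # centric: mask all but the two allowed phases (snapped to the grid)
  cen <- which(dat$centric %in% TRUE & is.finite(dat$phi_restrict))
  if (length(cen)) {
    mask <- matrix(TRUE, length(cen), length(phi))
    for (j in seq_along(cen)) {
      allowed <- (dat$phi_restrict[cen[j]] + c(0, 180)) %% 360
      snap <- vapply(allowed, function(a) {
        which.min(pmin(abs(phi - a), 360 - abs(phi - a)))
      }, 1L)
      mask[j, snap] <- FALSE
    }
    loglik[cen, ][mask] <- -Inf
  }
  loglik <- loglik - apply(loglik, 1, max)
  prob <- exp(loglik)
  prob <- prob / rowSums(prob)
  list(prob = prob, phi = phi)
}

# phase-set summary from a probability matrix
summarize_probabilities <- function(prob, phi) {
  eip <- exp(1i * phi * pi / 180)
  vec <- as.vector(prob %*% eip)
  data.table(
    phi_best = phi[max.col(prob, ties.method = "first")],
    phi_cent = (Arg(vec) * 180 / pi) %% 360,
    fom = Mod(vec)
  )
}

#' Estimate lack-of-closure magnitudes per resolution shell
#'
#' Initializes `E_iso` as the shell RMS isomorphous difference and
#' `E_ano` as the shell RMS observed Bijvoet difference, then refines by
#' a fixed number of phase-and-remeasure iterations (lack of closure at
#' the current best phase). Values are floored at 5% of the initial
#' estimate; an empty shell inherits its neighbour's value.
#'
#' @param dat Per-reflection phasing table (see [phase_probability()]),
#'   with a `d` column.
#' @param mode Phasing mode.
#' @param n_shells Number of shells.
#' @param n_iterations Refinement iterations (default 2).
#' @param step Trial-phase grid step.
#' @param refit_ano Refit `E_ano` from the residuals (default)? When
#'   `FALSE` it stays at the initial data-derived RMS — a
#'   substructure-independent yardstick, which is what a fair comparison
#'   of the two enantiomorph hands requires (a refitted `E_ano` simply
#'   absorbs the wrong hand's anomalous inconsistency).
#' @return `dat` with `E_iso`, `E_ano` columns filled.
#' @export
estimate_lack_of_closure <- function(dat, mode = "SIRAS", n_shells = 6L,
                                     n_iterations = 2L, step = 5,
                                     refit_ano = TRUE) {
  dat <- copy(as.data.table(dat))
  dat[, shell := resolution_shell(d, n_shells, range(d))]
  fill_shells <- function(v) {
    # propagate neighbouring shell values into empty shells
    for (i in seq_along(v)) {
      if (!is.finite(v[i]) || v[i] <= 0) {
        near <- which(is.finite(v) & v > 0)
        if (!length(near)) stop("no shell has a finite error estimate")
        v[i] <- v[near[which.min(abs(near - i))]]
      }
    }
    v
  }
  rms <- function(x) sqrt(mean(x^2, na.rm = TRUE))
  init <- dat[, .(
    e_iso = rms(((F_PH_plus + F_PH_minus) / 2 - F_P)[is.finite(F_P)]),
    e_ano = rms((F_PH_plus - F_PH_minus))
  ), by = shell][order(shell)]
  all_shells <- seq_len(n_shells)
  e_iso0 <- if (mode == "SAD") rep(1, n_shells) else
    fill_shells(init$e_iso[match(all_shells, init$shell)])
  e_ano0 <- if (mode == "SIR") rep(1, n_shells) else
    fill_shells(init$e_ano[match(all_shells, init$shell)])
  e_iso <- e_iso0
  e_ano <- e_ano0
  shell_rms <- function(res) {
    agg <- tapply(res, dat$shell, rms)
    v <- rep(NA_real_, n_shells)
    v[as.integer(names(agg))] <- agg
    fill_shells(v)
  }
  for (it in seq_len(n_iterations)) {
    dat[, E_iso := e_iso[shell]]
    dat[, E_ano := e_ano[shell]]
    pp <- phase_probability(dat, mode = mode, step = step)
    best <- pp$phi[max.col(pp$prob, ties.method = "first")]
    eb <- exp(1i * best * pi / 180)
    if (mode != "SAD") {
      fpc <- Mod(dat$F_P * eb + dat$FH)
      fmc <- Mod(dat$F_P * eb + dat$FHbar)
      res_iso <- (dat$F_PH_plus + dat$F_PH_minus) / 2 - (fpc + fmc) / 2
      e_iso <- pmax(shell_rms(res_iso), 0.05 * e_iso0)
    }
    if (mode != "SIR" && refit_ano) {
      dcalc <- if (mode == "SAD") {
        -2 * dat$FH_imag * sin((best - dat$phi_H) * pi / 180)
      } else {
        Mod(dat$F_P * eb + dat$FH) - Mod(dat$F_P * eb + dat$FHbar)
      }
      res_ano <- (dat$F_PH_plus - dat$F_PH_minus) - dcalc
      e_ano <- pmax(shell_rms(res_ano), 0.05 * e_ano0)
    }
  }
  dat[, E_iso := e_iso[shell]]
  dat[, E_ano := e_ano[shell]]
  dat[]
}
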