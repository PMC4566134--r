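test_that("heavy-atom SF pairs behave under f'' on/off", {
  truth <- small_truth()
  refl <- truth$refl[truth$refl$branch == 1, ][1:30, ]
  model <- truth$heavy_sites
  hsf <- heavy_atom_sf(model, truth$cell, truth$sg, refl)
  expect_gt(max(Mod(hsf$FH - hsf$FHbar)), 0.1)
  model0 <- model
  model0$fpp <- 0
  hsf0 <- heavy_atom_sf(model0, truth$cell, truth$sg, refl)
  expect_lt(max(Mod(hsf0$FH - hsf0$FHbar)), 1e-9)
  # oracle equivalence with the structure-factor module at +/- indices
  plus <- calc_structure_factors(model, truth$cell, truth$sg, refl, TRUE)
  expect_equal(hsf$FH, plus$F, tolerance = 1e-12)
})

test_that("single P1 atom: |F_H - Fbar_H| = 2 f''", {
  cell <- unit_cell(10, 10, 10)
  sg <- space_group("P1")
  at <- atom_sites(0.13, 0.27, 0.41, occ = 1, b = 0, f0 = 80, fp = 0,
                   fpp = 9.75)
  refl <- data.frame(h = c(1, 2), k = c(2, 1), l = c(3, 1))
  hsf <- heavy_atom_sf(at, cell, sg, refl)
  expect_equal(Mod(hsf$FH - hsf$FHbar), c(2 * 9.75, 2 * 9.75),
               tolerance = 1e-9)
  expect_equal(hsf$FH_imag, c(9.75, 9.75), tolerance = 1e-9)
})

test_that("SIR probability is bimodal at the phase-circle intersections; SIRAS breaks the tie", {
  # single-reflection geometric oracle: known F_P, F_H, true phase
  FH <- complex(modulus = 20, argument = 40 * pi / 180)
  FHbar <- complex(modulus = 20, argument = 35 * pi / 180)
  phi_true <- 112
  FP <- 100
  FPHp <- Mod(FP * exp(1i * phi_true * pi / 180) + FH)
  FPHm <- Mod(FP * exp(1i * phi_true * pi / 180) + FHbar)
  dat <- data.table::data.table(
    F_P = FP, F_PH_plus = FPHp, F_PH_minus = FPHm,
    FH = FH, FHbar = FHbar, FH_imag = 2, phi_H = 37.5,
    E_iso = 1, E_ano = 0.2, centric = FALSE, phi_restrict = NA_real_
  )
  sir <- phase_probability(dat, mode = "SIR", step = 1)
  p <- sir$prob[1, ]
  # local maxima of the periodic probability profile
  lmax <- which(p > c(p[-1], p[1]) & p > c(p[length(p)], p[-length(p)]))
  expect_equal(length(lmax), 2)
  expect_true(min(abs(sir$phi[lmax] - phi_true)) <= 2)
  siras <- phase_probability(dat, mode = "SIRAS", step = 1)
  best <- siras$phi[which.max(siras$prob[1, ])]
  expect_lt(min(abs(best - phi_true), 360 - abs(best - phi_true)), 3)
})

test_that("FOM hits its uniform and delta limits", {
  phi <- sirasfx:::phase_grid(5)
  n <- length(phi)
  uni <- matrix(1 / n, 1, n)
  expect_lt(sirasfx:::summarize_probabilities(uni, phi)$fom, 1e-9)
  delta <- matrix(0, 1, n); delta[1, 7] <- 1
  s <- sirasfx:::summarize_probabilities(delta, phi)
  expect_equal(s$fom, 1)
  expect_equal(s$phi_cent, phi[7])
})

test_that("centric reflections phase only on their allowed pair", {
  truth <- small_truth()
  nm <- exact_merged(truth, "native")
  dm <- exact_merged(truth, "derivative")
  ph <- phase_dataset(nm, dm, truth$heavy_sites, truth$cell, truth$sg,
                      mode = "SIRAS")
  cen <- ph[ph$centric == TRUE & is.finite(ph$phi_restrict), ]
  off <- (cen$phi_best - cen$phi_restrict) %% 180
  expect_true(all(pmin(off, 180 - off) < 1e-6))
  expect_true(all(ph$fom >= 0 & ph$fom <= 1))
  p <- attr(ph, "prob")
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
})

test_that("lack-of-closure estimates scale with the data and respect the floor", {
  truth <- small_truth()
  nm <- exact_merged(truth, "native")
  dm <- exact_merged(truth, "derivative")
  sp <- scale_derivative(nm, dm)
  prep <- function(s) {
    dat <- data.table::copy(s$data)
    dat[, "ano_ok"] <- is.finite(dat$F_PH_plus) & is.finite(dat$F_PH_minus)
    dat[dat$ano_ok == FALSE, c("F_PH_plus", "F_PH_minus")] <-
      dat$F_PH[dat$ano_ok == FALSE]
    hsf <- heavy_atom_sf(truth$heavy_sites, truth$cell, truth$sg,
                         dat[, c("h", "k", "l")])
    dat <- merge(dat, hsf, by = c("h", "k", "l"), sort = FALSE)
    fl <- d_spacing_and_flags(truth$cell, truth$sg,
                              as.matrix(dat[, c("h", "k", "l")]))
    dat[, "centric"] <- fl$centric
    dat[, "phi_restrict"] <- sirasfx:::centric_phase_restriction(
      truth$sg, as.matrix(dat[, c("h", "k", "l")]))
    dat
  }
  dat <- prep(sp)
  est <- estimate_lack_of_closure(dat, mode = "SIRAS", n_shells = 4)
  # noiseless data with the true model: errors shrink well below the signal
  expect_lt(mean(est$E_iso), mean(abs(dat$F_PH - dat$F_P)))
  # floor: E never collapses to zero
  expect_true(all(est$E_iso > 0))
  expect_true(all(est$E_ano > 0))
  # scale equivariance: doubling all amplitudes doubles the initial E
  dat2 <- data.table::copy(dat)
  for (cn in c("F_P", "F_PH", "F_PH_plus", "F_PH_minus")) {
    dat2[, (cn)] <- dat2[[cn]] * 2
  }
  est2 <- estimate_lack_of_closure(dat2, mode = "SIRAS", n_shells = 4,
                                   n_iterations = 0)
  est1 <- estimate_lack_of_closure(dat, mode = "SIRAS", n_shells = 4,
                                   n_iterations = 0)
  expect_equal(est2$E_iso, 2 * est1$E_iso, tolerance = 1e-9)
  expect_error(phase_probability(data.table::copy(est1)[, E_iso := 0],
                                 mode = "SIR"), "positive")
})

test_that("correct-hand mean FOM beats a random-site model", {
  truth <- small_truth()
  cfg <- sim_config(seed = 71, n_patterns = 300)
  nm <- merge_patterns(simulate_patterns(truth, "native", cfg),
                       truth$cell, truth$sg, TRUE)
  dm <- merge_patterns(simulate_patterns(truth, "derivative", cfg),
                       truth$cell, truth$sg, TRUE)
  ph_true <- phase_dataset(nm, dm, truth$heavy_sites, truth$cell, truth$sg,
                           mode = "SIRAS")
  set.seed(8)
  wins <- 0
  for (i in 1:3) {
    rnd <- truth$heavy_sites
    rnd$x <- runif(1); rnd$y <- runif(1); rnd$z <- runif(1)
    ph_rnd <- phase_dataset(nm, dm, rnd, truth$cell, truth$sg,
                            mode = "SIRAS")
    wins <- wins + (attr(ph_true, "mean_fom") > attr(ph_rnd, "mean_fom"))
  }
  expect_gte(wins, 2)
})

test_that("SIRAS is at least as informative as SIR on matched data", {
  truth <- small_truth()
  foms <- sapply(c("SIRAS", "SIR"), function(md) {
    cfg <- sim_config(seed = 73, n_patterns = 300)
    nm <- merge_patterns(simulate_patterns(truth, "native", cfg),
                         truth$cell, truth$sg, TRUE)
    dm <- merge_patterns(simulate_patterns(truth, "derivative", cfg),
                         truth$cell, truth$sg, TRUE)
    ph <- phase_dataset(nm, dm, truth$heavy_sites, truth$cell, truth$sg,
                        mode = md)
    ev <- evaluate_map(ph, truth)
    c(fom = attr(ph, "mean_fom"), perr = ev$phase_error)
  })
  expect_gte(foms["fom", "SIRAS"], foms["fom", "SIR"])
  expect_lte(foms["perr", "SIRAS"], foms["perr", "SIR"])
})

test_that("solvent flattening leaves noiseless true phases (nearly) fixed", {
  truth <- small_truth()
  plus <- truth$sf_native[truth$sf_native$branch == 1, ]
  n <- nrow(plus)
  phi <- sirasfx:::phase_grid(5)
  prob <- matrix(1e-12, n, length(phi))
  snap <- vapply(plus$phase, function(a) {
    which.min(pmin(abs(phi - a), 360 - abs(phi - a)))
  }, 1L)
  prob[cbind(seq_len(n), snap)] <- 1
  prob <- prob / rowSums(prob)
  ps <- data.table::data.table(
    h = plus$h, k = plus$k, l = plus$l, d = plus$d,
    centric = plus$centric, phi_restrict = plus$phi_restrict,
    Fobs = plus$amp, phi_best = phi[snap], phi_cent = phi[snap],
    fom = 1)
  data.table::setattr(ps, "prob", prob)
  data.table::setattr(ps, "phi", phi)
  data.table::setattr(ps, "class", c("phase_set", class(ps)))
  fl <- solvent_flatten(ps, truth$cell, truth$sg, n_cycles = 3)
  dphi <- abs((fl$phases$phi_best - ps$phi_best) %% 360)
  dphi <- pmin(dphi, 360 - dphi)
  werr <- sum(ps$Fobs * dphi) / sum(ps$Fobs)
  expect_lt(werr, 10)
  expect_false(fl$diverged)
})

test_that("flattening improves SIRAS phases and discriminates the hand", {
  truth <- small_truth()
  cfg <- sim_config(seed = 79, n_patterns = 300)
  nm <- merge_patterns(simulate_patterns(truth, "native", cfg),
                       truth$cell, truth$sg, TRUE)
  dm <- merge_patterns(simulate_patterns(truth, "derivative", cfg),
                       truth$cell, truth$sg, TRUE)
  bh <- phase_dataset(nm, dm, truth$heavy_sites, truth$cell, truth$sg,
                      mode = "SIRAS", try_both_hands = TRUE,
                      flatten_opts = list(n_cycles = 6))
  expect_true(bh$verdict %in% c("original", "inverted"))
  expect_s3_class(bh$original$phases, "phase_set")
  expect_s3_class(bh$inverted$phases, "phase_set")
  # the correct hand is the one matching the true site
  expect_equal(bh$verdict, "original")
  expect_gt(bh$original$contrast, bh$inverted$contrast)
  # flattening reduces the phase error relative to the unflattened set
  ph0 <- phase_dataset(nm, dm, truth$heavy_sites, truth$cell, truth$sg,
                       mode = "SIRAS")
  e0 <- evaluate_map(ph0, truth)$phase_error
  e1 <- evaluate_map(bh$original$phases, truth)$phase_error
  expect_lt(e1, e0)
})

test_that("amplified anomalous signal improves SAD phasing", {
  mk <- function(fpp) {
    make_toy_structure(seed = 3, n_atoms = 12, cell = unit_cell(18, 22, 26),
                       d_min = 3.0,
                       heavy = list(occ = 0.7, f0 = 80, fp = -10, fpp = fpp))
  }
  perr <- vapply(c(9.75, 5 * 9.75), function(fpp) {
    tr <- mk(fpp)
    cfg <- sim_config(seed = 83, n_patterns = 300)
    nm <- merge_patterns(simulate_patterns(tr, "native", cfg),
                         tr$cell, tr$sg, TRUE)
    dm <- merge_patterns(simulate_patterns(tr, "derivative", cfg),
                         tr$cell, tr$sg, TRUE)
    ph <- phase_dataset(nm, dm, tr$heavy_sites, tr$cell, tr$sg, mode = "SAD")
    evaluate_map(ph, tr, reference_atoms = tr$atoms_derivative)$phase_error
  }, 1)
  expect_lt(perr[2], perr[1])
})

test_that("map evaluation is exact on itself and invariant to origin shifts", {
  truth <- small_truth()
  sf <- calc_structure_factors(truth$atoms_native, truth$cell, truth$sg,
                               truth$refl[truth$refl$branch == 1, ], FALSE)
  g <- synthesize_map(sf, truth$cell, truth$sg)
  ev <- evaluate_map(g, truth, d_min = truth$d_min)
  expect_equal(ev$cc, 1, tolerance = 1e-9)
  expect_true(ev$success)
  # shifted copy: the origin search must recover CC = 1
  shifted <- g
  shifted$values <- sirasfx:::transform_grid_values(g$values, 1,
                                                    round(c(0.5, 0, 0.5) * g$dim))
  ev2 <- evaluate_map(shifted, truth, d_min = truth$d_min)
  expect_equal(ev2$cc, 1, tolerance = 1e-9)
  # random phases decorrelate
  set.seed(10)
  rnd <- sf
  rnd$phase <- runif(nrow(rnd), 0, 360)
  rnd$F <- complex(modulus = rnd$amp, argument = rnd$phase * pi / 180)
  g_rnd <- synthesize_map(rnd, truth$cell, truth$sg)
  ev3 <- evaluate_map(g_rnd, truth, d_min = truth$d_min)
  expect_lt(ev3$cc, 0.4)
  expect_false(ev3$success)
})

test_that("full inversion equivariance: inverted model on inverted data", {
  truth <- small_truth()
  # invert the whole ground truth
  inv <- truth
  for (nm_at in c("atoms_native", "atoms_derivative", "heavy_sites")) {
    a <- inv[[nm_at]]
    a$x <- (-a$x) %% 1; a$y <- (-a$y) %% 1; a$z <- (-a$z) %% 1
    inv[[nm_at]] <- a
  }
  inv$sf_native <- calc_structure_factors(inv$atoms_native, inv$cell,
                                          inv$sg, inv$refl, FALSE)
  inv$sf_derivative <- calc_structure_factors(inv$atoms_derivative, inv$cell,
                                              inv$sg, inv$refl, TRUE)
  cfg <- noiseless_config()
  m_n <- merge_patterns(simulate_patterns(truth, "native", cfg),
                        truth$cell, truth$sg, TRUE)
  m_d <- merge_patterns(simulate_patterns(truth, "derivative", cfg),
                        truth$cell, truth$sg, TRUE)
  i_n <- merge_patterns(simulate_patterns(inv, "native", cfg),
                        inv$cell, inv$sg, TRUE)
  i_d <- merge_patterns(simulate_patterns(inv, "derivative", cfg),
                        inv$cell, inv$sg, TRUE)
  ph <- phase_dataset(m_n, m_d, truth$heavy_sites, truth$cell, truth$sg,
                      mode = "SIRAS")
  ph_i <- phase_dataset(i_n, i_d, inv$heavy_sites, inv$cell, inv$sg,
                        mode = "SIRAS")
  cc <- evaluate_map(ph, truth)$cc
  cc_i <- evaluate_map(ph_i, inv)$cc
  expect_equal(cc, cc_i, tolerance = 0.02)
})
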