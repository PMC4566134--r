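#' One pass of the phasing pipeline on merged data
#'
#' Shared worker for the titration and resolution-scan experiments:
#' optionally locate the heavy site from the difference Pattersons (or
#' take the true site to isolate phasing behaviour), phase, flatten, and
#' score against the ground truth.
#'
#' @param native_merged,derivative_merged Branch-separate `merged_data`.
#' @param truth Ground truth from [make_toy_structure()].
#' @param mode Phasing mode.
#' @param use_true_site Use the true heavy site instead of searching?
#' @param d_cut Optional high-resolution cutoff (Angstrom) applied to
#'   both datasets before phasing.
#' @param n_cycles Solvent-flattening cycles.
#' @param solvent_fraction Solvent fraction for flattening.
#' @param step Trial-phase grid step.
#' @return list: `cc`, `phase_error`, `success`, `mean_fom`,
#'   `mean_fom_initial`, `diverged`, `site_error` (Angstrom or NA).
#' @export
phase_and_evaluate <- function(native_merged, derivative_merged, truth,
                               mode = "SIRAS", use_true_site = TRUE,
                               d_cut = NULL, n_cycles = 10L,
                               solvent_fraction = 0.44, step = 5) {
  cell <- truth$cell
  sg <- truth$sg
  nm <- as.data.table(native_merged)
  dm <- as.data.table(derivative_merged)
  if (!is.null(d_cut)) {
    nm <- nm[d >= d_cut]
    dm <- dm[d >= d_cut]
  }
  site_error <- NA_real_
  if (use_true_site) {
    model <- truth$heavy_sites
  } else {
    loc <- locate_heavy_site(nm, dm, truth)
    model <- loc$model
    site_error <- loc$site_error
  }
  ph <- tryCatch(
    phase_dataset(nm, dm, model, cell, sg, mode = mode, step = step),
    error = function(e) NULL
  )
  if (is.null(ph)) {
    return(list(cc = NA_real_, phase_error = NA_real_, success = FALSE,
                mean_fom = NA_real_, mean_fom_initial = NA_real_,
                diverged = TRUE, site_error = site_error))
  }
  fom0 <- mean(ph$fom)
  fl <- solvent_flatten(ph, cell, sg, solvent_fraction = solvent_fraction,
                        n_cycles = n_cycles)
  ref_atoms <- if (mode == "SAD") truth$atoms_derivative else NULL
  ev <- evaluate_map(fl$phases, truth, reference_atoms = ref_atoms)
  list(cc = ev$cc, phase_error = ev$phase_error, success = ev$success,
       mean_fom = mean(fl$phases$fom), mean_fom_initial = fom0,
       diverged = fl$diverged, site_error = site_error)
}

#' Locate the heavy site from isomorphous + anomalous difference Pattersons
#'
#' @param native_merged,derivative_merged Branch-separate `merged_data`.
#' @param truth Ground truth (for cell/symmetry and the heavy-atom
#'   scattering constants; the true coordinates are used only to report
#'   `site_error`).
#' @param use_anomalous Include the anomalous difference Patterson?
#' @return list: `model` ([atom_sites()] with the located site), `site`
#'   (fractional), `site_error` (Angstrom, modulo allowed origins/hand),
#'   `candidates`.
#' @export
locate_heavy_site <- function(native_merged, derivative_merged, truth,
                              use_anomalous = TRUE) {
  cell <- truth$cell
  sg <- truth$sg
  sp <- scale_derivative(native_merged, derivative_merged)
  maps <- list(patterson_map(sp$data[, .(h, k, l)], sp$data$dF_iso^2, cell, sg))
  if (use_anomalous) {
    ad <- sp$data[is.finite(dI_ano)]
    if (nrow(ad) >= 10 && any(ad$dI_ano != 0)) {
      # normalize against the intensity scale for stability
      w <- (ad$dI_ano / pmax(ad$F_PH^2, stats::quantile(ad$F_PH^2, 0.1)))^2
      maps <- c(maps, list(patterson_map(ad[, .(h, k, l)], w, cell, sg)))
    }
  }
  cand <- search_sites(maps, cell, sg)
  site <- as.numeric(cand[1, c("x", "y", "z")])
  true_site <- as.numeric(truth$heavy_sites[1, c("x", "y", "z")])
  err <- site_distance(sg, cell, site, true_site)
  hv <- truth$heavy_sites
  model <- atom_sites(site[1], site[2], site[3], occ = hv$occ[1], b = hv$b[1],
                      f0 = hv$f0[1], fp = hv$fp[1], fpp = hv$fpp[1],
                      label = "HG1")
  list(model = model, site = site, site_error = err, candidates = cand)
}

# first-n-patterns nested subset of a stream
subset_patterns <- function(stream, n) {
  ids <- sort(unique(stream$pattern_id))
  if (n > length(ids)) stop("requested more patterns than simulated")
  stream[pattern_id %in% ids[seq_len(n)]]
}

#' Pattern-count titration of phasing success
#'
#' For every combination of native and derivative pattern counts,
#' merges nested subsets ("the first N snapshots"), phases in the
#' requested mode, solvent-flattens, and scores success by the map-CC
#' rule (CC > 0.65). Subsets are nested so that larger counts reuse every
#' pattern of the smaller ones, reducing sampling noise across the grid.
#'
#' @param truth Ground truth.
#' @param native_stream,derivative_stream Simulated pattern streams.
#' @param n_native,n_derivative Strictly increasing count axes.
#' @param mode Phasing mode.
#' @param use_true_site,n_cycles,step Passed to [phase_and_evaluate()].
#' @return data.table: `n_nat`, `n_der`, `mode`, `cc`, `success`,
#'   `mean_fom`, `phase_error`, `diverged`.
#' @export
run_titration <- function(truth, native_stream, derivative_stream,
                          n_native, n_derivative, mode = "SIRAS",
                          use_true_site = TRUE, n_cycles = 10L, step = 5) {
  stopifnot(all(diff(n_native) > 0) || length(n_native) == 1,
            all(diff(n_derivative) > 0) || length(n_derivative) == 1)
  ids_n <- unique(native_stream$pattern_id)
  ids_d <- unique(derivative_stream$pattern_id)
  if (max(n_native) > length(ids_n) || max(n_derivative) > length(ids_d)) {
    stop("titration grid exceeds the number of simulated patterns")
  }
  cell <- truth$cell; sg <- truth$sg
  res <- list()
  for (nn in n_native) {
    nm <- merge_patterns(subset_patterns(native_stream, nn), cell, sg, TRUE)
    for (nd in n_derivative) {
      dm <- merge_patterns(subset_patterns(derivative_stream, nd), cell, sg, TRUE)
      r <- phase_and_evaluate(nm, dm, truth, mode = mode,
                              use_true_site = use_true_site,
                              n_cycles = n_cycles, step = step)
      res[[length(res) + 1]] <- data.table(
        n_nat = nn, n_der = nd, mode = mode, cc = r$cc,
        success = isTRUE(r$success), mean_fom = r$mean_fom,
        phase_error = r$phase_error, diverged = isTRUE(r$diverged))
    }
  }
  rbindlist(res)
}

#' Minimal successful pattern total from a titration grid
#'
#' @param titration A [run_titration()] result.
#' @return Smallest `n_nat + n_der` among successful cells (`Inf` when
#'   none succeeded).
#' @export
minimal_success_total <- function(titration) {
  ok <- titration[success == TRUE]
  if (nrow(ok) == 0) return(Inf)
  min(ok$n_nat + ok$n_der)
}

#' Resolution-cutoff scan of phasing success
#'
#' Repeats the phasing pipeline with reflections truncated at each
#' high-resolution cutoff.
#'
#' @param truth Ground truth.
#' @param native_stream,derivative_stream Pattern streams.
#' @param cutoffs d-spacing cutoffs in Angstrom (each >= the simulated
#'   d_min).
#' @param modes Phasing modes to scan.
#' @param n_cycles,use_true_site,step Passed to [phase_and_evaluate()].
#' @return data.table: `cutoff`, `mode`, `cc`, `success`, `mean_fom`.
#' @export
run_resolution_scan <- function(truth, native_stream, derivative_stream,
                                cutoffs, modes = c("SIRAS", "SIR"),
                                n_cycles = 10L, use_true_site = TRUE,
                                step = 5) {
  if (any(cutoffs < truth$d_min)) {
    stop("cutoff finer than the simulated resolution limit")
  }
  cell <- truth$cell; sg <- truth$sg
  nm <- merge_patterns(native_stream, cell, sg, TRUE)
  dm <- merge_patterns(derivative_stream, cell, sg, TRUE)
  res <- list()
  for (cut in cutoffs) {
    for (md in modes) {
      r <- phase_and_evaluate(nm, dm, truth, mode = md, d_cut = cut,
                              use_true_site = use_true_site,
                              n_cycles = n_cycles, step = step)
      res[[length(res) + 1]] <- data.table(
        cutoff = cut, mode = md, cc = r$cc, success = isTRUE(r$success),
        mean_fom = r$mean_fom)
    }
  }
  rbindlist(res)
}

#' Anomalous-signal growth with pattern count
#'
#' For nested subsets of the derivative stream, computes the half-dataset
#' `CC_ano`, the reference-based `CC_anoref`, and the anomalous
#' difference Patterson height (sigma units) at the true Harker
#' self-vector positions.
#'
#' @param truth Ground truth.
#' @param derivative_stream Pattern stream.
#' @param pattern_counts Increasing counts.
#' @param seed Seed for the half-dataset splits.
#' @return data.table: `n_patterns`, `cc_ano`, `cc_anoref`,
#'   `patterson_height`.
#' @export
run_signal_curves <- function(truth, derivative_stream, pattern_counts,
                              seed = 1L) {
  cell <- truth$cell; sg <- truth$sg
  true_site <- as.numeric(truth$heavy_sites[1, c("x", "y", "z")])
  harker <- harker_sections(sg)
  res <- list()
  for (np in pattern_counts) {
    sub <- subset_patterns(derivative_stream, np)
    merged <- merge_patterns(sub, cell, sg, TRUE)
    hm <- half_set_metrics(sub, cell, sg, seed = seed)
    ccr <- cc_anoref(merged, truth$sf_derivative)
    # anomalous difference Patterson from (dI / <I>)^2 coefficients
    amp <- to_amplitudes(merged)
    obs <- ano_differences(merged)
    im <- merge_friedel(merged)
    obs <- merge(obs, im[, .(h, k, l, I)], by = c("h", "k", "l"))
    coeff <- (obs$dI / pmax(obs$I, stats::quantile(abs(obs$I), 0.1)))^2
    pmap <- patterson_map(obs[, .(h, k, l)], coeff, cell, sg)
    hts <- vapply(harker, function(sec) {
      grid_interp(pmap, rbind(sec$vector_fn(true_site)))
    }, 1)
    res[[length(res) + 1]] <- data.table(
      n_patterns = np, cc_ano = hm$cc_ano, cc_anoref = ccr,
      patterson_height = max(hts))
  }
  rbindlist(res)
}
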