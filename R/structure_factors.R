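#' Atom site table
#'
#' Builds the atom-site data.frame used throughout the package. Scattering
#' is modelled with a constant normal factor `f0` per atom (no
#' Cromer-Mann s-dependence) plus anomalous corrections `f'` and `f''`;
#' isotropic B-factor damping is applied as `exp(-B s^2 / 4)`.
#'
#' @param x,y,z Fractional coordinates (wrapped into `[0,1)`).
#' @param occ Occupancy in `[0,1]`.
#' @param b Isotropic B-factor in Angstrom^2 (>= 0).
#' @param f0 Normal scattering factor, electrons (> 0).
#' @param fp,fpp Anomalous corrections f' and f'', electrons.
#' @param label Atom labels.
#' @return A data.frame of class `atom_sites`.
#' @export
atom_sites <- function(x, y, z, occ = 1, b = 0, f0 = 6, fp = 0, fpp = 0,
                       label = NULL) {
  n <- length(x)
  df <- data.frame(
    label = if (is.null(label)) sprintf("X%03d", seq_len(n)) else label,
    x = x %% 1, y = y %% 1, z = z %% 1,
    occ = rep_len(occ, n), b = rep_len(b, n),
    f0 = rep_len(f0, n), fp = rep_len(fp, n), fpp = rep_len(fpp, n),
    stringsAsFactors = FALSE
  )
  stopifnot(all(df$occ >= 0 & df$occ <= 1), all(df$b >= 0), all(df$f0 > 0))
  class(df) <- c("atom_sites", "data.frame")
  df
}

#' Structure factors with optional anomalous scattering
#'
#' Direct summation over atoms and symmetry operators:
#' `F(h) = sum_j occ_j (f0_j + f'_j + i f''_j) exp(-B_j s^2/4)
#'         sum_m exp(2 pi i h.(R_m x_j + t_m))` with `s = 1/d`.
#'
#' @param atoms An [atom_sites()] table (nonempty).
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param refl Reflection table from [generate_reflections()] or any
#'   data.frame with integer columns `h`, `k`, `l`.
#' @param include_anomalous Include the f'/f'' terms?
#' @return data.table with the reflection columns plus `F` (complex),
#'   `amp` and `phase` (degrees in `[0,360)`); attribute `anomalous`
#'   records the flag.
#' @export
calc_structure_factors <- function(atoms, cell, sg, refl,
                                   include_anomalous = TRUE) {
  if (nrow(atoms) == 0) stop("atom list is empty")
  H <- as.matrix(as.data.frame(refl)[, c("h", "k", "l")])
  storage.mode(H) <- "double"
  s2 <- (H[, 1] / cell$a)^2 + (H[, 2] / cell$b)^2 + (H[, 3] / cell$c)^2
  X <- t(as.matrix(atoms[, c("x", "y", "z")]))  # 3 x natoms
  G <- matrix(0 + 0i, nrow(H), ncol(X))
  for (o in sg$ops) {
    ph <- (H %*% (o$R %*% X)) + matrix(as.vector(H %*% o$t),
                                       nrow(H), ncol(X))
    G <- G + exp(2i * pi * ph)
  }
  D <- exp(-outer(s2 / 4, atoms$b))
  f <- if (include_anomalous) {
    atoms$occ * complex(real = atoms$f0 + atoms$fp, imaginary = atoms$fpp)
  } else {
    atoms$occ * complex(real = atoms$f0, imaginary = 0)
  }
  Fv <- as.vector((D * G) %*% f)
  out <- as.data.table(as.data.frame(refl))
  set(out, j = "F", value = Fv)
  set(out, j = "amp", value = Mod(Fv))
  set(out, j = "phase", value = (Arg(Fv) * 180 / pi) %% 360)
  setattr(out, "anomalous", include_anomalous)
  out[]
}
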