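#' Real-space grid container
#'
#' A periodic 3-D grid over the unit cell holding electron density or
#' Patterson values. Grid point `(i1,i2,i3)` (0-based) corresponds to the
#' fractional position `(i1/n1, i2/n2, i3/n3)`.
#'
#' @param values 3-D numeric array.
#' @param cell A [unit_cell()].
#' @param kind `"density"` or `"patterson"`.
#' @return Object of class `real_space_grid`.
#' @export
real_space_grid <- function(values, cell, kind = c("density", "patterson")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(values)) == 3, all(is.finite(values)))
  structure(list(values = values, dim = dim(values), cell = cell, kind = kind),
            class = "real_space_grid")
}

#' @export
print.real_space_grid <- function(x, ...) {
  cat(sprintf("%s grid %d x %d x %d, sd = %.4g\n", x$kind,
              x$dim[1], x$dim[2], x$dim[3], stats::sd(x$values)))
  invisible(x)
}

# smallest even 2^a*3^b*5^c >= n (FFT-friendly)
good_grid_size <- function(n) {
  n <- max(4L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1 && n %% 2 == 0) return(n)
    n <- n + 1L
  }
}

#' Default map sampling for a resolution limit
#'
#' Grid dimensions sampling each cell edge at `d_min/3`, rounded up to
#' even FFT-friendly sizes.
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in Angstrom.
#' @return Integer vector of 3 grid dimensions.
#' @export
default_grid_dims <- function(cell, d_min) {
  vapply(c(cell$a, cell$b, cell$c),
         function(e) good_grid_size(3 * e / d_min), integer(1))
}

# Expand a unique-reflection SF set over symmetry ops and Friedel mates and
# deposit into a complex reciprocal grid array (first-come wins for
# coincident equivalents). H: n x 3; Fv complex.
fill_reciprocal_grid <- function(H, Fv, sg, dims) {
  m <- length(sg$ops)
  allH <- vector("list", 2 * m)
  allF <- vector("list", 2 * m)
  for (i in seq_len(m)) {
    o <- sg$ops[[i]]
    Hp <- hkl_transform(H, o$R)
    Fp <- Fv * exp(-2i * pi * as.vector(H %*% o$t))
    allH[[i]] <- Hp
    allF[[i]] <- Fp
    allH[[m + i]] <- -Hp
    allF[[m + i]] <- Conj(Fp)
  }
  He <- do.call(rbind, allH)
  Fe <- do.call(c, allF)
  idx <- cbind(He[, 1] %% dims[1], He[, 2] %% dims[2], He[, 3] %% dims[3])
  lin <- idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3]) + 1
  keep <- !duplicated(lin)
  A <- array(0 + 0i, dims)
  A[lin[keep]] <- Fe[keep]
  A
}

#' Fourier synthesis of an electron-density (or difference) map
#'
#' Computes `rho(x) = (1/V) sum_h F(h) exp(-2 pi i h.x)` on a periodic
#' grid. The reflection list is expanded internally over the symmetry
#' operators and Friedel mates (Hermitian completion, so the output is
#' real); F(000) is excluded, so the grid mean is 0.
#'
#' @param sf data.frame with columns `h`, `k`, `l` and either a complex
#'   column `F` or columns `amp` and `phase` (degrees).
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param grid_dims Integer vector of 3 grid dimensions; even values
#'   required (allows exact half-cell origin shifts).
#' @param method `"fft"` (production path) or `"direct"` (slow direct
#'   summation; the oracle used in tests).
#' @param kind Grid kind label.
#' @return A [real_space_grid()].
#' @export
synthesize_map <- function(sf, cell, sg, grid_dims = NULL, method = c("fft", "direct"),
                           kind = "density") {
  method <- match.arg(method)
  sf <- as.data.frame(sf)
  if (is.null(grid_dims)) {
    d_min <- if (nrow(sf)) min(d_spacing_and_flags(cell, sg, as.matrix(sf[, c("h", "k", "l")]))$d) else 3
    grid_dims <- default_grid_dims(cell, d_min)
  }
  grid_dims <- as.integer(grid_dims)
  if (any(grid_dims %% 2 != 0)) stop("grid dimensions must be even")
  if (nrow(sf) == 0) {
    return(real_space_grid(array(0, grid_dims), cell, kind))
  }
  H <- as.matrix(sf[, c("h", "k", "l")])
  storage.mode(H) <- "double"
  Fv <- if ("F" %in% names(sf)) sf$F else
    complex(modulus = sf$amp, argument = sf$phase * pi / 180)
  dmin_data <- min(d_spacing_and_flags(cell, sg, H)$d)
  if (any(grid_dims < 2 * c(cell$a, cell$b, cell$c) / dmin_data)) {
    warning("grid too coarse for the data resolution; map is aliased")
  }
  A <- fill_reciprocal_grid(H, Fv, sg, grid_dims)
  if (method == "fft") {
    rho <- Re(stats::fft(A)) / cell$volume
  } else {
    rho <- direct_synthesis(A, grid_dims) / cell$volume
  }
  real_space_grid(rho, cell, kind)
}

# O(n_refl * n_grid) direct summation over the nonzero entries of the
# reciprocal grid; test oracle for the FFT path.
direct_synthesis <- function(A, dims) {
  nz <- which(A != 0)
  idx <- arrayInd(nz, dims) - 1
  # wrap to signed indices
  hs <- ifelse(idx[, 1] > dims[1] / 2, idx[, 1] - dims[1], idx[, 1])
  ks <- ifelse(idx[, 2] > dims[2] / 2, idx[, 2] - dims[2], idx[, 2])
  ls <- ifelse(idx[, 3] > dims[3] / 2, idx[, 3] - dims[3], idx[, 3])
  Fv <- A[nz]
  g1 <- (0:(dims[1] - 1)) / dims[1]
  g2 <- (0:(dims[2] - 1)) / dims[2]
  g3 <- (0:(dims[3] - 1)) / dims[3]
  rho <- array(0, dims)
  for (j in seq_along(nz)) {
    phx <- exp(-2i * pi * hs[j] * g1)
    phy <- exp(-2i * pi * ks[j] * g2)
    phz <- exp(-2i * pi * ls[j] * g3)
    rho <- rho + Re(Fv[j] * outer(outer(phx, phy), phz))
  }
  Re(rho)
}

#' Inverse operation: structure factors from a map
#'
#' Reads `F(h) = (V/N) sum_g rho(g) exp(+2 pi i h.g/n)` off the FFT of the
#' grid at the requested Miller indices.
#'
#' @param grid A [real_space_grid()].
#' @param H n x 3 matrix of Miller indices.
#' @return Complex vector of structure factors.
#' @export
map_to_sf <- function(grid, H) {
  dims <- grid$dim
  A <- stats::fft(grid$values, inverse = TRUE) * grid$cell$volume / prod(dims)
  lin <- (H[, 1] %% dims[1]) + dims[1] * ((H[, 2] %% dims[2]) +
           dims[2] * (H[, 3] %% dims[3])) + 1
  A[lin]
}

# periodic trilinear interpolation of grid values at fractional positions
# (n x 3 matrix)
grid_interp <- function(grid, frac) {
  frac <- rbind(frac)
  dims <- grid$dim
  v <- grid$values
  out <- numeric(nrow(frac))
  g <- sweep(frac %% 1, 2, dims, "*")
  i0 <- floor(g)
  w <- g - i0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- cbind((i0[, 1] + dx) %% dims[1],
                (i0[, 2] + dy) %% dims[2],
                (i0[, 3] + dz) %% dims[3]) + 1
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
      (if (dy) w[, 2] else 1 - w[, 2]) *
      (if (dz) w[, 3] else 1 - w[, 3])
    out <- out + wt * v[ii]
  }
  out
}

# standardize a grid to mean 0, sd 1 (sigma units); a flat grid stays flat
standardize_grid <- function(grid) {
  v <- grid$values
  s <- stats::sd(v)
  if (s < .Machine$double.eps) {
    grid$values <- v - mean(v)
  } else {
    grid$values <- (v - mean(v)) / s
  }
  grid
}

# Greedy peak picking: highest grid values, suppressing anything within
# min_sep_frac (fractional metric scaled by cell) of an already-kept peak.
# exclude_origin_radius is in Angstrom.
grid_peaks <- function(grid, n_peaks = 10, min_sep = 2.0,
                       exclude_origin_radius = 0) {
  dims <- grid$dim
  cell <- grid$cell
  v <- grid$values
  ord <- order(v, decreasing = TRUE)[seq_len(min(length(v), 5000L))]
  idx <- arrayInd(ord, dims) - 1
  frac <- sweep(idx, 2, dims, "/")
  # minimum-image cartesian distance helper
  cart_dist <- function(f1, f2) {
    df <- (f1 - f2) %% 1
    df <- pmin(df, 1 - df)
    sqrt((df[1] * cell$a)^2 + (df[2] * cell$b)^2 + (df[3] * cell$c)^2)
  }
  keep <- list()
  for (i in seq_len(nrow(frac))) {
    f <- frac[i, ]
    if (exclude_origin_radius > 0 &&
        cart_dist(f, c(0, 0, 0)) < exclude_origin_radius) next
    ok <- TRUE
    for (kpt in keep) if (cart_dist(f, kpt$frac) < min_sep) { ok <- FALSE; break }
    if (ok) keep[[length(keep) + 1]] <- list(frac = f, height = v[ord[i]])
    if (length(keep) >= n_peaks) break
  }
  if (!length(keep)) {
    return(data.table(x = numeric(), y = numeric(), z = numeric(),
                      height = numeric()))
  }
  data.table(
    x = vapply(keep, function(p) p$frac[1], 1),
    y = vapply(keep, function(p) p$frac[2], 1),
    z = vapply(keep, function(p) p$frac[3], 1),
    height = vapply(keep, function(p) p$height, 1)
  )
}

# reciprocal-space Gaussian smoothing of a real grid, radius in Angstrom
smooth_grid <- function(grid, radius) {
  dims <- grid$dim
  cell <- grid$cell
  A <- stats::fft(grid$values)
  wrap <- function(n) { i <- 0:(n - 1); ifelse(i > n / 2, i - n, i) }
  hs <- wrap(dims[1]) / cell$a
  ks <- wrap(dims[2]) / cell$b
  ls <- wrap(dims[3]) / cell$c
  s2 <- outer(outer(hs^2, ks^2, "+"), ls^2, "+")
  A <- A * exp(-2 * pi^2 * radius^2 * s2 / 3)
  grid$values <- Re(stats::fft(A, inverse = TRUE)) / prod(dims)
  grid
}
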