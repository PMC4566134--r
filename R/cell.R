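#' Orthorhombic unit cell
#'
#' Constructs a unit-cell object. Only orthorhombic cells (all angles 90
#' degrees) are supported; the angle fields are carried so that a general
#' metric tensor can be added later without breaking the interface.
#'
#' @param a,b,c Cell edges in Angstrom, all positive.
#' @param alpha,beta,gamma Cell angles in degrees (must be 90).
#' @return An object of class `unit_cell` with fields `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma` and the derived `volume` (Angstrom^3).
#' @export
#' @examples
#' cl <- unit_cell(30, 40, 50)
#' cl$volume # 60000
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  if (any(abs(c(alpha, beta, gamma) - 90) > 1e-9)) {
    stop("only orthorhombic cells (90/90/90) are supported")
  }
  structure(
    list(a = a, b = b, c = c,
         alpha = alpha, beta = beta, gamma = gamma,
         volume = a * b * c),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell %.3f %.3f %.3f Angstrom (orthorhombic), V = %.1f A^3\n",
              x$a, x$b, x$c, x$volume))
  invisible(x)
}

#' Space-group description
#'
#' Returns the symmetry operators, enantiomorph flip and allowed origin
#' shifts for the supported space groups, `P1` and `P212121`.
#'
#' Operators act on fractional coordinates as `x' = R x + t`. For
#' `P212121` there are 4 operators, the enantiomorph flip is the inversion
#' `(-x,-y,-z)`, and the 8 allowed origin shifts have components 0 or 1/2.
#'
#' @param name Space-group symbol: `"P1"` or `"P212121"`.
#' @return An object of class `space_group` with fields `name`, `ops`
#'   (list of `list(R = 3x3 matrix, t = length-3 vector)`),
#'   `enantiomorph_flip` (3x3 matrix) and `origin_shifts`
#'   (matrix with one shift per row).
#' @export
space_group <- function(name) {
  name <- toupper(gsub("[^A-Za-z0-9]", "", name))
  op <- function(rdiag, t) list(R = diag(rdiag), t = t)
  if (name == "P1") {
    ops <- list(op(c(1, 1, 1), c(0, 0, 0)))
    shifts <- matrix(0, nrow = 1, ncol = 3)
  } else if (name == "P212121") {
    ops <- list(
      op(c( 1,  1,  1), c(0,   0,   0)),
      op(c(-1, -1,  1), c(0.5, 0,   0.5)),
      op(c(-1,  1, -1), c(0,   0.5, 0.5)),
      op(c( 1, -1, -1), c(0.5, 0.5, 0))
    )
    shifts <- as.matrix(expand.grid(c(0, 0.5), c(0, 0.5), c(0, 0.5)))
    dimnames(shifts) <- NULL
  } else {
    stop("unsupported space group: ", name)
  }
  structure(
    list(name = if (name == "P1") "P1" else "P212121",
         ops = ops,
         enantiomorph_flip = diag(c(-1, -1, -1)),
         origin_shifts = shifts),
    class = "space_group"
  )
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("space group %s: %d operator(s), %d allowed origin shift(s)\n",
              x$name, length(x$ops), nrow(x$origin_shifts)))
  invisible(x)
}

# h as a row vector transforms as h' = h %*% R under operator (R, t);
# F(h R) = F(h) exp(-2 pi i h.t).
hkl_transform <- function(H, R) H %*% R

#' Resolution and symmetry flags for Miller indices
#'
#' Computes the d-spacing, centricity flag and epsilon (reflection
#' multiplicity) factor for one or more Miller indices.
#'
#' A reflection is centric when some operator maps `h` to `-h`; epsilon is
#' the number of operators mapping `h` to itself. Both are derived directly
#' from the operator list, not from tabulated zone rules.
#'
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param hkl Integer vector of length 3, or an n x 3 matrix of indices.
#' @return A data.frame with columns `h`, `k`, `l`, `d` (Angstrom),
#'   `centric` (logical), `epsilon` (integer).
#' @export
d_spacing_and_flags <- function(cell, sg, hkl) {
  H <- rbind(hkl)
  storage.mode(H) <- "double"
  if (any(rowSums(H != 0) == 0)) stop("Miller index (0,0,0) has no d-spacing")
  d <- 1 / sqrt((H[, 1] / cell$a)^2 + (H[, 2] / cell$b)^2 + (H[, 3] / cell$c)^2)
  centric <- rep(FALSE, nrow(H))
  epsilon <- rep(0L, nrow(H))
  for (o in sg$ops) {
    Ht <- hkl_transform(H, o$R)
    centric <- centric | rowSums(abs(Ht + H)) == 0
    epsilon <- epsilon + as.integer(rowSums(abs(Ht - H)) == 0)
  }
  data.frame(h = H[, 1], k = H[, 2], l = H[, 3],
             d = d, centric = centric, epsilon = epsilon)
}

# TRUE for reflections extinguished by a screw-axis (or other translational)
# symmetry element: some op fixes h but contributes a non-unit phase factor.
systematic_absent <- function(sg, H) {
  H <- rbind(H)
  absent <- rep(FALSE, nrow(H))
  for (o in sg$ops) {
    fixes <- rowSums(abs(hkl_transform(H, o$R) - H)) == 0
    ht <- as.vector(H %*% o$t)
    absent <- absent | (fixes & abs(ht - round(ht)) > 1e-9)
  }
  absent
}

# Restricted phase (degrees, mod 180) for centric reflections: the operator
# with h R = -h forces 2 phi = -360 h.t (mod 360).
centric_phase_restriction <- function(sg, H) {
  H <- rbind(H)
  phi0 <- rep(NA_real_, nrow(H))
  for (o in sg$ops) {
    inverts <- rowSums(abs(hkl_transform(H, o$R) + H)) == 0
    idx <- which(inverts & is.na(phi0))
    if (length(idx)) {
      phi0[idx] <- (-180 * as.vector(H[idx, , drop = FALSE] %*% o$t)) %% 180
    }
  }
  phi0
}

# Encode index triples (|index| < 500) into a single orderable number.
encode_hkl <- function(H) (H[, 1] * 1001 + H[, 2]) * 1001 + H[, 3]

# Map observed Miller indices to a canonical asymmetric-unit representative.
# Returns canonical indices plus the Friedel branch (+1 when the canonical
# representative comes from the orbit of +h, -1 otherwise; centric
# reflections always report +1). Intensities are invariant along the orbit,
# so no phase bookkeeping is needed here.
asu_map <- function(sg, H, friedel_separate = TRUE) {
  H <- rbind(H)
  n <- nrow(H)
  m <- length(sg$ops)
  cand_code <- matrix(NA_real_, n, 2 * m)
  cand <- vector("list", 2 * m)
  for (i in seq_len(m)) {
    Hp <- hkl_transform(H, sg$ops[[i]]$R)
    cand[[i]] <- Hp
    cand[[m + i]] <- -Hp
    cand_code[, i] <- encode_hkl(Hp)
    cand_code[, m + i] <- encode_hkl(-Hp)
  }
  plus_best <- max.col(cand_code[, seq_len(m), drop = FALSE], ties.method = "first")
  minus_best <- max.col(cand_code[, m + seq_len(m), drop = FALSE], ties.method = "first")
  plus_code <- cand_code[cbind(seq_len(n), plus_best)]
  minus_code <- cand_code[cbind(seq_len(n), m + minus_best)]
  if (!friedel_separate) {
    # canonical over the full orbit including Friedel mates
    best <- max.col(cand_code, ties.method = "first")
    out <- matrix(0, n, 3)
    for (j in seq_len(2 * m)) {
      sel <- best == j
      out[sel, ] <- cand[[j]][sel, , drop = FALSE]
    }
    return(data.frame(h = out[, 1], k = out[, 2], l = out[, 3],
                      branch = 1L))
  }
  use_plus <- plus_code >= minus_code
  out <- matrix(0, n, 3)
  branch <- integer(n)
  for (i in seq_len(m)) {
    sel_p <- use_plus & plus_best == i
    out[sel_p, ] <- cand[[i]][sel_p, , drop = FALSE]
    branch[sel_p] <- 1L
    sel_m <- !use_plus & minus_best == i
    out[sel_m, ] <- cand[[m + i]][sel_m, , drop = FALSE]
    branch[sel_m] <- -1L
  }
  data.frame(h = out[, 1], k = out[, 2], l = out[, 3], branch = branch)
}

#' Generate the unique reflection list to a resolution limit
#'
#' Enumerates all Miller indices with d-spacing at or above `d_min`,
#' removes systematic absences (screw-axis conditions tested operator by
#' operator), and reduces to one representative per symmetry-unique
#' reflection.
#'
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param d_min High-resolution cutoff in Angstrom (> 0).
#' @param keep_friedel_separate When `TRUE`, acentric reflections are listed
#'   twice, once per Friedel mate, and cross-linked via the `mate` column.
#' @return A data.table with columns `h`, `k`, `l`, `d`, `centric`,
#'   `epsilon`, `phi_restrict` (allowed centric phase mod 180, `NA` for
#'   acentric) and, when Friedel mates are kept, `branch` (+1/-1) and
#'   `mate` (row index of the Friedel partner).
#' @export
generate_reflections <- function(cell, sg, d_min, keep_friedel_separate = FALSE) {
  if (d_min <= 0) stop("d_min must be positive")
  hmax <- floor(cell$a / d_min)
  kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
  d <- 1 / sqrt((grid[, 1] / cell$a)^2 + (grid[, 2] / cell$b)^2 +
                  (grid[, 3] / cell$c)^2)
  grid <- grid[d >= d_min, , drop = FALSE]
  grid <- grid[!systematic_absent(sg, grid), , drop = FALSE]
  # reduce to unique canonical representatives of the Friedel-merged orbit
  canon <- asu_map(sg, grid, friedel_separate = FALSE)
  canon <- unique(as.data.table(canon)[, c("h", "k", "l")])
  flags <- d_spacing_and_flags(cell, sg, as.matrix(canon))
  flags$phi_restrict <- centric_phase_restriction(sg, as.matrix(canon))
  dt <- as.data.table(flags)
  setorder(dt, -d, h, k, l)
  if (!keep_friedel_separate) return(dt[])
  plus <- copy(dt)[, branch := 1L]
  minus <- dt[centric == FALSE]
  minus[, `:=`(h = -h, k = -k, l = -l, branch = -1L,
               phi_restrict = NA_real_)]
  out <- rbind(plus, minus)
  out[, `:=`(ah = abs(h), ak = abs(k), al = abs(l))]
  setorder(out, -d, ah, ak, al, -branch)
  out[, c("ah", "ak", "al") := NULL]
  # pair rows that are Friedel mates of each other; centric rows self-pair
  out[, mate := {
    code <- paste(-h, -k, -l)
    idx <- match(code, out[, paste(h, k, l)])
    idx[is.na(idx)] <- .I[is.na(idx)]  # centric: mate is itself
    idx
  }]
  out[]
}
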