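#' Write a SHELX HKLF4 reflection file
#'
#' Fixed-width records: `h`, `k`, `l` in 4 columns each, intensity and
#' sigma in 8 columns with 2 decimals, terminated by an all-zero record.
#'
#' @param path Output file path.
#' @param data data.frame with columns `h`, `k`, `l`, `I`, `sigma`.
#' @export
write_shelx_hkl <- function(path, data) {
  data <- as.data.frame(data)
  if (nrow(data)) {
    if (any(abs(data$h) > 999 | abs(data$k) > 999 | abs(data$l) > 999)) {
      bad <- which(abs(data$h) > 999 | abs(data$k) > 999 | abs(data$l) > 999)[1]
      stop("Miller index overflows 4-column field in record ", bad)
    }
    iv <- sprintf("%8.2f", data$I)
    sv <- sprintf("%8.2f", data$sigma)
    if (any(nchar(iv) > 8) || any(nchar(sv) > 8)) {
      bad <- which(nchar(iv) > 8 | nchar(sv) > 8)[1]
      stop("intensity/sigma overflows 8-column field in record ", bad)
    }
    lines <- sprintf("%4d%4d%4d%s%s", data$h, data$k, data$l, iv, sv)
  } else {
    lines <- character()
  }
  writeLines(c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0)), path)
  invisible(path)
}

#' Read a SHELX HKLF4 reflection file
#'
#' @param path Input file path.
#' @return data.table with columns `h`, `k`, `l`, `I`, `sigma`; parsing
#'   stops at the all-zero terminator record.
#' @export
read_shelx_hkl <- function(path) {
  lines <- readLines(path)
  out <- data.table(
    h = as.integer(substr(lines, 1, 4)),
    k = as.integer(substr(lines, 5, 8)),
    l = as.integer(substr(lines, 9, 12)),
    I = as.numeric(substr(lines, 13, 20)),
    sigma = as.numeric(substr(lines, 21, 28))
  )
  term <- which(out$h == 0 & out$k == 0 & out$l == 0)
  if (length(term)) out <- out[seq_len(term[1] - 1)]
  out[]
}

#' Write heavy-atom / toy-structure sites as a minimal PDB subset
#'
#' Emits `CRYST1` (cell + space group), one `HETATM` per site with
#' orthogonal Angstrom coordinates (diagonal conversion for the
#' orthorhombic restriction), and `END`.
#'
#' @param path Output file path.
#' @param sites An [atom_sites()] table (fractional coordinates).
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @export
write_pdb_sites <- function(path, sites, cell, sg) {
  sites <- as.data.frame(sites)
  if (nrow(sites) > 9999) stop("at most 9999 sites supported")
  sg_field <- if (sg$name == "P212121") "P 21 21 21" else "P 1"
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                   cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
                   sg_field)
  if (nrow(sites)) {
    el <- toupper(substr(sites$label, 1, 2))
    lines <- c(lines, sprintf(
      "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(sites)), substr(sites$label, 1, 4), "UNK",
      seq_len(nrow(sites)),
      sites$x * cell$a, sites$y * cell$b, sites$z * cell$c,
      sites$occ, sites$b, substr(el, 1, 2)))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read sites from a minimal PDB-subset file
#'
#' @param path Input file path.
#' @return list with `cell` ([unit_cell()]), `sg_name` (text from the
#'   CRYST1 record) and `sites` ([atom_sites()], fractional coordinates;
#'   f0/f'/f'' are not stored in PDB and default to carbon-like values).
#' @export
read_pdb_sites <- function(path) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) stop("missing CRYST1 record")
  a <- as.numeric(substr(cr[1], 7, 15))
  b <- as.numeric(substr(cr[1], 16, 24))
  c_ <- as.numeric(substr(cr[1], 25, 33))
  if (any(is.na(c(a, b, c_)))) stop("malformed CRYST1 record")
  cell <- unit_cell(a, b, c_)
  sg_name <- trimws(substr(cr[1], 56, 66))
  at <- grep("^(HETATM|ATOM  )", lines, value = TRUE)
  if (length(at)) {
    sites <- atom_sites(
      x = as.numeric(substr(at, 31, 38)) / cell$a,
      y = as.numeric(substr(at, 39, 46)) / cell$b,
      z = as.numeric(substr(at, 47, 54)) / cell$c,
      occ = as.numeric(substr(at, 55, 60)),
      b = as.numeric(substr(at, 61, 66)),
      label = trimws(substr(at, 13, 16))
    )
  } else {
    sites <- atom_sites(numeric(), numeric(), numeric())
  }
  list(cell = cell, sg_name = sg_name, sites = sites)
}

#' Write a pattern stream to its line-oriented text format
#'
#' Each snapshot is a `BEGIN_PATTERN <id>` header, one `h k l I sigma`
#' line per record, and `END_PATTERN`.
#'
#' @param path Output file path.
#' @param stream A pattern stream (data.table with `pattern_id`, `h`,
#'   `k`, `l`, `I_obs`, `sigma`, `d`).
#' @export
write_stream <- function(path, stream) {
  stream <- as.data.table(stream)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(stream)) {
    grp <- split(stream, by = "pattern_id", sorted = TRUE)
    for (g in grp) {
      writeLines(sprintf("BEGIN_PATTERN %d", g$pattern_id[1]), con)
      writeLines(sprintf("%d %d %d %.6g %.6g", g$h, g$k, g$l, g$I_obs, g$sigma),
                 con)
      writeLines("END_PATTERN", con)
    }
  }
  invisible(path)
}

#' Read a pattern stream text file
#'
#' @param path Input file path.
#' @param cell Optional [unit_cell()]; when given, the per-record
#'   d-spacing column is recomputed.
#' @return data.table with columns `pattern_id`, `h`, `k`, `l`, `I_obs`,
#'   `sigma` (and `d` when a cell is supplied).
#' @export
read_stream <- function(path, cell = NULL) {
  lines <- readLines(path)
  begins <- grep("^BEGIN_PATTERN", lines)
  ends <- grep("^END_PATTERN", lines)
  if (length(begins) != length(ends) ||
      (length(begins) && any(ends < begins))) {
    bad <- if (length(begins) > length(ends)) begins[length(ends) + 1] else
      ends[length(begins) + 1]
    stop("unbalanced BEGIN/END_PATTERN at line ", bad)
  }
  if (!length(begins)) {
    out <- data.table(pattern_id = integer(), h = integer(), k = integer(),
                      l = integer(), I_obs = numeric(), sigma = numeric())
    return(out)
  }
  ids <- as.integer(sub("^BEGIN_PATTERN\\s+", "", lines[begins]))
  nrec <- ends - begins - 1
  rec_lines <- lines[-c(begins, ends)]
  parts <- strsplit(rec_lines, "\\s+")
  m <- matrix(as.numeric(unlist(parts)), ncol = 5, byrow = TRUE)
  out <- data.table(
    pattern_id = rep(ids, nrec),
    h = as.integer(m[, 1]), k = as.integer(m[, 2]), l = as.integer(m[, 3]),
    I_obs = m[, 4], sigma = m[, 5]
  )
  if (!is.null(cell)) {
    out[, d := 1 / sqrt((h / cell$a)^2 + (k / cell$b)^2 + (l / cell$c)^2)]
  }
  out[]
}
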