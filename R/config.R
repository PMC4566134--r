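#' Read a structured key-value run configuration
#'
#' TOML-dialect subset: `[section]` headers, `key = value` lines, `#`
#' comments. Values are parsed as numbers, logicals (`true`/`false`) or
#' bare/quoted strings. Unknown sections or keys are rejected by name —
#' a typo in a config must fail loudly, not silently fall back to a
#' default.
#'
#' @param path Config file path.
#' @return Nested named list `list(simulation = ..., merge = ...,
#'   phasing = ..., experiment = ...)` with only the keys present.
#' @export
read_run_config <- function(path) {
  schema <- list(
    simulation = c("seed", "n_patterns", "observed_fraction", "p_min",
                   "scale_sdlog", "background", "absorber_t",
                   "absorber_d_threshold", "weak_fraction", "weak_scale",
                   "counting_noise", "n_atoms", "d_min"),
    merge = c("adu_threshold", "lowres_bound", "n_shells", "seed"),
    phasing = c("mode", "step", "n_cycles", "solvent_fraction",
                "use_true_site"),
    experiment = c("n_native", "n_derivative", "cutoffs", "pattern_counts",
                   "repeats", "output_dir")
  )
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% names(schema)) {
        stop("unknown config section: ", section)
      }
      out[[section]] <- out[[section]] %||% list()
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    if (is.null(section)) stop("key outside any [section]: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% schema[[section]]) {
      stop("unknown config key: ", section, ".", key)
    }
    out[[section]][[key]] <- parse_config_value(val)
  }
  out
}

parse_config_value <- function(val) {
  if (grepl('^".*"$', val)) return(gsub('^"|"$', "", val))
  if (tolower(val) %in% c("true", "false")) return(tolower(val) == "true")
  if (grepl("^\\[.*\\]$", val)) {
    parts <- trimws(strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]])
    return(vapply(parts, function(p) as.numeric(p), 1, USE.NAMES = FALSE))
  }
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

#' Build a [sim_config()] from the `simulation` section of a run config
#'
#' @param conf A [read_run_config()] result.
#' @return A [sim_config()].
#' @export
sim_config_from_run <- function(conf) {
  s <- conf$simulation %||% list()
  absorber <- NULL
  if (!is.null(s$absorber_t)) {
    absorber <- list(T = s$absorber_t,
                     d_threshold = s$absorber_d_threshold %||% 3.8)
  }
  sim_config(
    seed = s$seed %||% 1L,
    n_patterns = s$n_patterns %||% 500L,
    observed_fraction = s$observed_fraction %||% 0.3,
    p_min = s$p_min %||% 0.1,
    scale_sdlog = s$scale_sdlog %||% 0.4,
    background = s$background %||% 25,
    absorber = absorber,
    weak_fraction = s$weak_fraction %||% 0,
    weak_scale = s$weak_scale %||% 1e-3,
    counting_noise = s$counting_noise %||% TRUE
  )
}
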