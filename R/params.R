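#' Neuron model parameters
#'
#' Loads the parameter set for one neuron class from the versioned parameter
#' file shipped with the package (or a user-supplied file in the same flat
#' two-level `section: / key: value` format) and applies optional overrides.
#'
#' The motoneuron is a two-compartment (soma + dendrite) conductance-based
#' model with fast sodium, delayed-rectifier potassium, N- and L-type calcium,
#' calcium-dependent potassium, persistent sodium (dendrite only) and leak
#' currents.  The interneuron is a single-compartment reduction with only
#' sodium, potassium and leak currents.  Units: conductances mS/cm^2,
#' potentials mV, capacitance uF/cm^2, time ms, Ca concentration uM.
#'
#' @param class `"motoneuron"` or `"interneuron"`.
#' @param file Path to a parameter file; defaults to the shipped file.
#' @param overrides Named list of values replacing entries of the loaded set.
#' @return An object of class `neuron_params` (a named list).
#' @examples
#' p <- neuron_params("interneuron")
#' p$g_Na
#' @export
neuron_params <- function(class = c("motoneuron", "interneuron"),
                          file = NULL, overrides = NULL) {
  class <- match.arg(class)
  if (is.null(file)) {
    file <- system.file("extdata", "neuron_params.yaml", package = "nmcoupling")
  }
  all <- read_param_file(file)
  if (is.null(all[[class]])) {
    stop("parameter file has no section '", class, "'")
  }
  p <- all[[class]]
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    unknown <- setdiff(names(overrides), c(names(p), "E_L"))
    if (length(unknown) > 0) {
      stop("unknown parameter override(s): ", paste(unknown, collapse = ", "))
    }
    p[names(overrides)] <- overrides
  }
  p$class <- class
  structure(p, class = "neuron_params")
}

#' Read a flat two-level parameter file
#'
#' Parses the minimal YAML subset used by the shipped parameter file: top-level
#' `section:` lines and indented `key: value` scalar entries.  Comments (`#`)
#' and blank lines are ignored.
#'
#' @param file Path to the file.
#' @return Named list of sections, each a named list of numeric scalars.
#' @export
read_param_file <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    indented <- grepl("^\\s", ln)
    parts <- strsplit(trimws(ln), ":", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    val <- if (length(parts) >= 2) trimws(paste(parts[-1], collapse = ":")) else ""
    if (!indented) {
      if (nzchar(val)) stop("top-level entries must be sections: ", ln)
      section <- key
      out[[section]] <- list()
    } else {
      if (is.null(section)) stop("indented entry before any section: ", ln)
      num <- suppressWarnings(as.numeric(val))
      out[[section]][[key]] <- if (is.na(num)) val else num
    }
  }
  out
}

#' Write a flat two-level parameter file
#'
#' Inverse of [read_param_file()]; used to export modified parameter sets.
#'
#' @param params Named list of sections (named lists of scalars).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_param_file <- function(params, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (section in names(params)) {
    writeLines(paste0(section, ":"), con)
    sec <- params[[section]]
    for (key in names(sec)) {
      writeLines(sprintf("  %s: %s", key, format(sec[[key]], digits = 15)), con)
    }
  }
  invisible(file)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params> class:", x$class,
      " compartments:", x$n_compartments, "\n")
  nm <- setdiff(names(x), c("class", "n_compartments"))
  vals <- unlist(x[nm])
  print(vals)
  invisible(x)
}

# Validate a parameter set; called by simulation entry points.
validate_params <- function(p) {
  stopifnot(inherits(p, "neuron_params"))
  g <- unlist(p[grep("^g_", names(p))])
  if (any(g < 0)) stop("maximal conductances must be >= 0")
  if (p$C <= 0) stop("C must be > 0")
  if (p$tau_synE <= 0) stop("tau_synE must be > 0")
  if (p$n_compartments == 2) {
    if (p$p <= 0 || p$p >= 1) stop("somatic surface ratio p must be in (0, 1)")
  }
  if (!(p$E_Na > 0 && p$E_K < 0 && p$E_L > p$E_K && p$E_L < p$E_Na)) {
    stop("reversal potentials violate E_Na > 0 > E_K, E_L in (E_K, E_Na)")
  }
  invisible(TRUE)
}

# Deterministic polynomial hash of an R object modulo 2^31 - 1 (used for
# calibration cache keys and run manifests; not cryptographic).  All
# intermediate values stay below 2^53 so the arithmetic is exact in doubles.
object_hash <- function(x) {
  s <- paste(deparse(x, control = "exact"), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Derive a child RNG seed (< 2^31) from a master seed and a string tag.
derive_seed <- function(seed, tag) {
  h <- strtoi(object_hash(list(as.integer(seed), as.character(tag))), 16L)
  (h %% 2147483562L) + 1L
}
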