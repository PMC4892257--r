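#' Species tracked per cell
#'
#' Order used by all state matrices: Notch receptor (N), Delta (D), Jagged
#' (J), NICD (I), miR-34, SNAIL mRNA (mS), SNAIL protein (S), miR-200, ZEB
#' mRNA (mZ), ZEB protein (Z) and the optional glycosyltransferase Fringe
#' (F, identically zero unless the Fringe module is enabled).
#'
#' @return Character vector of the 11 species names.
#' @export
species_names <- function() {
  c("N", "D", "J", "I", "miR34", "mS", "S", "miR200", "mZ", "Z", "F")
}

.hill_rows <- c("I_N", "I_D", "I_J", "Z_u200", "S_u200", "Z_mz", "S_mz",
                "S_u34", "Z_u34", "S_ms", "I_ms", "Iext_ms",
                "I_F", "F_delta", "F_jagged")

#' Default model parameters
#'
#' Loads the packaged parameter set (`inst/extdata/default_params.yaml`)
#' and applies any overrides. Overrides may be given either as top-level
#' scalar names (`default_parameters(gD = 70, gJ = 20)` finds `gD` inside
#' the `notch` block) or as nested lists
#' (`default_parameters(coupling = list(hill_I_ms = list(lambda = 6)))`).
#'
#' @param ... Overrides, see above.
#' @return A validated object of class `ndj_params`.
#' @export
default_parameters <- function(...) {
  path <- system.file("extdata", "default_params.yaml", package = "notchemt")
  p <- load_config(path, base = NULL)
  overrides <- list(...)
  if (length(overrides)) p <- apply_overrides(p, overrides)
  validate_params(p)
}

#' Load a model/run configuration file
#'
#' Reads a YAML (or JSON) parameter file, checks every key against the
#' packaged schema and fills unspecified fields from the defaults.
#'
#' @param path Path to the config file.
#' @param base Parameter set supplying defaults for unspecified fields;
#'   `NULL` only when loading the packaged defaults themselves.
#' @return A validated `ndj_params` object.
#' @export
load_config <- function(path, base = default_parameters()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed config '", path, "': ", conditionMessage(e))
  })
  if (is.null(base)) {
    p <- raw
  } else {
    check_known_keys(raw, base, "")
    p <- merge_lists(unclass(base), raw)
  }
  class(p) <- "ndj_params"
  validate_params(p)
}

check_known_keys <- function(x, ref, prefix) {
  if (!is.list(x)) return(invisible())
  bad <- setdiff(names(x), names(ref))
  if (length(bad)) {
    stop("unknown config key", if (length(bad) > 1) "s", ": ",
         paste0(prefix, bad, collapse = ", "))
  }
  for (nm in names(x)) {
    if (is.list(x[[nm]]) && is.list(ref[[nm]])) {
      check_known_keys(x[[nm]], ref[[nm]], paste0(prefix, nm, "."))
    }
  }
  invisible()
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

apply_overrides <- function(p, overrides) {
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    stop("parameter overrides must be named")
  }
  for (nm in names(overrides)) {
    val <- overrides[[nm]]
    if (nm %in% names(p)) {
      p[[nm]] <- if (is.list(val)) merge_lists(p[[nm]], val) else val
      next
    }
    hit <- FALSE
    for (blk in names(p)) {
      if (is.list(p[[blk]]) && nm %in% names(p[[blk]])) {
        p[[blk]][[nm]] <- if (is.list(val)) merge_lists(p[[blk]][[nm]], val) else val
        hit <- TRUE
        break
      }
    }
    if (!hit) stop("unknown parameter override: ", nm)
  }
  p
}

rate_names <- function() {
  list(notch = c("gN", "gD", "gJ", "kc", "kt", "affinityD", "affinityJ",
                 "gammaN", "gammaD", "gammaJ", "gammaI"),
       emt = c("gu34", "gms", "gs", "gu200", "gmz", "gz",
               "gammau34", "gammams", "gammas",
               "gammau200", "gammamz", "gammaz"),
       fringe = c("gF", "gammaF"))
}

#' Validate a parameter set
#'
#' Checks that all rates are non-negative, that every regulatory edge has a
#' valid shifted-Hill specification, and that the microRNA binding-site
#' ladders are well formed.
#'
#' @param p An `ndj_params` object (or plain list with the same structure).
#' @return The validated object, invisibly classed as `ndj_params`.
#' @export
validate_params <- function(p) {
  rn <- rate_names()
  for (blk in names(rn)) {
    for (nm in rn[[blk]]) {
      v <- p[[blk]][[nm]]
      if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
        stop("parameter ", blk, ".", nm, " must be a single non-negative number")
      }
    }
  }
  for (h in .hill_rows) {
    spec <- find_hill(p, h)
    do.call(hill_spec, spec[c("X0", "n", "lambda")])  # validates
  }
  for (m in c("mir34_N", "mir34_D", "mir200_J", "mir34_ms", "mir200_mz")) {
    get_mirna_spec(p, m)  # validates
  }
  if (!is.logical(p$fringe$enabled) && !(p$fringe$enabled %in% c(0, 1))) {
    stop("fringe.enabled must be logical")
  }
  structure(p, class = "ndj_params")
}

find_hill <- function(p, name) {
  key <- paste0("hill_", name)
  for (blk in c("notch", "emt", "coupling", "fringe")) {
    if (key %in% names(p[[blk]])) return(p[[blk]][[key]])
  }
  stop("missing Hill specification: ", key)
}

#' Extract one microRNA repression record from a parameter set
#'
#' @param p An `ndj_params` object.
#' @param name One of `"mir34_N"`, `"mir34_D"`, `"mir200_J"`, `"mir34_ms"`,
#'   `"mir200_mz"`.
#' @return A [mirna_spec()].
#' @export
get_mirna_spec <- function(p, name) {
  for (blk in c("notch", "emt")) {
    if (name %in% names(p[[blk]])) {
      m <- p[[blk]][[name]]
      return(mirna_spec(sites = length(m$translation) - 1, mu0 = m$mu0,
                        translation = m$translation,
                        mrna_deg = if (is.null(m$mrna_deg))
                          rep(0, length(m$translation)) else m$mrna_deg,
                        mirna_deg = if (is.null(m$mirna_deg))
                          rep(0, length(m$translation)) else m$mirna_deg))
    }
  }
  stop("missing microRNA record: ", name)
}

# Flatten a parameter set into the list consumed by the compiled core.
params_to_cpp <- function(p) {
  sc <- c(unlist(p$notch[rate_names()$notch]),
          unlist(p$emt[rate_names()$emt]),
          unlist(p$fringe[rate_names()$fringe]),
          fringe = as.numeric(isTRUE(p$fringe$enabled) || identical(p$fringe$enabled, 1)))
  hills <- t(vapply(.hill_rows, function(h) {
    s <- find_hill(p, h)
    c(s$X0, s$n, s$lambda)
  }, numeric(3)))
  mir <- lapply(c("mir34_N", "mir34_D", "mir200_J", "mir34_ms", "mir200_mz"),
                function(nm) {
                  m <- get_mirna_spec(p, nm)
                  list(mu0 = m$mu0, l = m$translation,
                       gm = m$mrna_deg, gu = m$mirna_deg)
                })
  names(mir) <- c("mir34_N", "mir34_D", "mir200_J", "mir34_ms", "mir200_mz")
  list(scalars = sc, hills = hills, mir = mir)
}
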