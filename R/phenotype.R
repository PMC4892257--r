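#' Phenotype classification thresholds
#'
#' EMT phenotypes are read off the miR-200 level: epithelial (E) above
#' `mir200_upper`, mesenchymal (M) below `mir200_lower`, hybrid E/M in
#' between. Signalling roles use per-species "high" boundaries for Notch,
#' Delta and Jagged.
#'
#' @param mir200_lower,mir200_upper miR-200 band boundaries, molecules
#'   (`upper > lower > 0`).
#' @param notch_high,delta_high,jagged_high Boundaries above which the
#'   receptor/ligand counts as high, molecules.
#' @return Object of class `phenotype_thresholds`.
#' @export
phenotype_thresholds <- function(mir200_lower, mir200_upper,
                                 notch_high, delta_high, jagged_high) {
  stopifnot(mir200_lower > 0, mir200_upper > mir200_lower,
            notch_high > 0, delta_high > 0, jagged_high > 0)
  structure(list(mir200_lower = mir200_lower, mir200_upper = mir200_upper,
                 notch_high = notch_high, delta_high = delta_high,
                 jagged_high = jagged_high),
            class = "phenotype_thresholds")
}

#' Default thresholds from a parameter set
#'
#' @param params Parameter set whose `phenotype` block carries the
#'   boundaries (see [derive_thresholds()] for how the packaged defaults
#'   were computed from the model itself).
#' @return A [phenotype_thresholds()] object.
#' @export
default_thresholds <- function(params = default_parameters()) {
  ph <- params$phenotype
  phenotype_thresholds(ph$mir200_lower, ph$mir200_upper,
                       ph$notch_high, ph$delta_high, ph$jagged_high)
}

#' Derive phenotype thresholds from the model
#'
#' miR-200 band boundaries: run the Notch-decoupled EMT core (`kt = 0`,
#' no receptor/ligand production) across an `I_ext` sweep, locate a value
#' where the three phenotype branches coexist, and place the boundaries at
#' the geometric midpoints between adjacent branch miR-200 levels.
#' Notch/Delta "high" boundaries: geometric mean of the Sender-state and
#' Receiver-state values at the reference bistable operating point
#' (`D_ext = 0`, `J_ext = 600`, `N_ext = 5000`). Jagged "high" boundary:
#' geometric mean between the largest epithelial-branch Jagged level and
#' the smallest post-EMT (E/M or M branch) Jagged level along a `J_ext`
#' sweep, since Jagged separates the phenotypes across the EMT transition
#' rather than across the Sender/Receiver pair.
#'
#' @param params Parameter set.
#' @param i_ext_values `I_ext` grid for the decoupled sweep.
#' @param j_ext_values `J_ext` grid for the Jagged-boundary sweep.
#' @param n_starts,seed Passed to [find_stable_states()].
#' @return A [phenotype_thresholds()] object.
#' @export
derive_thresholds <- function(params = default_parameters(),
                              i_ext_values = seq(0, 100, by = 2),
                              j_ext_values = seq(0, 2100, by = 300),
                              n_starts = 30, seed = 421) {
  decoupled <- params
  decoupled$notch$kt <- 0
  decoupled$notch$gN <- 0
  decoupled$notch$gD <- 0
  decoupled$notch$gJ <- 0
  best <- NULL
  for (v in i_ext_values) {
    env <- cell_environment(I_ext = v)
    st <- suppressWarnings(
      find_stable_states(env, decoupled, n_starts = n_starts, seed = seed))
    if (nrow(st) >= 3 && is.null(best)) best <- sort(st$miR200)
  }
  if (is.null(best)) {
    stop("decoupled EMT core did not produce three coexisting miR-200 ",
         "branches; cannot derive thresholds")
  }
  m <- length(best)
  lower <- sqrt(max(best[1], 1) * best[2])
  upper <- sqrt(best[m - 1] * best[m])
  ref <- find_stable_states(cell_environment(N_ext = 5000, J_ext = 600),
                            params, n_starts = n_starts, seed = seed)
  if (nrow(ref) < 2) stop("reference operating point is not bistable")
  gm <- function(x) sqrt(max(min(x), 1) * max(x))
  # Jagged boundary from the EMT transition along J_ext
  j_epi <- numeric(0)
  j_mes <- numeric(0)
  env <- as_env_matrix(cell_environment(N_ext = 5000))
  prev <- NULL
  for (v in j_ext_values) {
    env[, "J_ext"] <- v
    st <- suppressWarnings(
      find_stable_states(env, params, n_starts = n_starts, seed = seed,
                         extra_starts = prev))
    if (!nrow(st)) next
    prev <- as.matrix(st[, species_names()])
    epi <- st$miR200 > upper
    j_epi <- c(j_epi, st$J[epi])
    j_mes <- c(j_mes, st$J[!epi])
  }
  if (!length(j_mes)) {
    stop("no post-EMT branch found along the J_ext sweep; ",
         "cannot derive the Jagged boundary")
  }
  phenotype_thresholds(mir200_lower = lower, mir200_upper = upper,
                       notch_high = gm(ref$N), delta_high = gm(ref$D),
                       jagged_high = sqrt(max(j_epi) * min(j_mes)))
}

# split sorted miR-200 levels into branches separated by > 3x gaps
cluster_mir200_branches <- function(u) {
  u <- pmax(u, 1)
  cl <- list()
  cur <- u[1]
  for (x in u[-1]) {
    if (x / max(cur) > 3) {
      cl[[length(cl) + 1]] <- cur
      cur <- x
    } else cur <- c(cur, x)
  }
  cl[[length(cl) + 1]] <- cur
  cl
}

#' Classify the EMT phenotype of a cell state
#'
#' @param state State vector or matrix (only the miR-200 level is used).
#' @param th Thresholds from [phenotype_thresholds()].
#' @return Character label(s): `"E"`, `"E/M"` or `"M"`.
#' @export
classify_emt <- function(state, th) {
  y <- as_state_matrix(state)
  u <- y[, "miR200"]
  unname(ifelse(u > th$mir200_upper, "E",
                ifelse(u < th$mir200_lower, "M", "E/M")))
}

#' Classify the Notch signalling role of a cell state
#'
#' Sender (S): ligand-high (Delta or Jagged) with Notch low. Receiver (R):
#' Notch-high with both ligands low. Hybrid S/R: Notch-high together with
#' a high ligand. `"none"` otherwise.
#'
#' @param state State vector or matrix.
#' @param th Thresholds from [phenotype_thresholds()].
#' @return Character label(s): `"S"`, `"R"`, `"S/R"` or `"none"`.
#' @export
classify_sr <- function(state, th) {
  y <- as_state_matrix(state)
  notch_hi <- y[, "N"] > th$notch_high
  lig_hi <- y[, "D"] > th$delta_high | y[, "J"] > th$jagged_high
  unname(ifelse(notch_hi & lig_hi, "S/R",
                ifelse(notch_hi, "R", ifelse(lig_hi, "S", "none"))))
}
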