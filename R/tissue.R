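#' Simulate a multicellular hexagonal tissue
#'
#' Every lattice cell runs the full per-cell circuit; at each time step the
#' per-cell environments are assembled from the current neighbour states
#' (synchronous update), then all cells advance one RK4 step together.
#' Deterministic given the initial states.
#'
#' @param lattice A [build_lattice()] object.
#' @param states0 `n_cells x 11` initial state matrix, e.g. from
#'   [random_initial_states()] or a previous snapshot's states (via
#'   [snapshot_states()]), so any run can seed another.
#' @param params Parameter set.
#' @param t_end Final time, hours.
#' @param snapshot_times Times (hours, within `[0, t_end]`) at which to
#'   emit snapshots; defaults to `t_end` only.
#' @param dt Step size, hours.
#' @param I_ext,sD_ext,sJ_ext Global external signals.
#' @param aggregation Neighbour aggregation rule: `"sum"` (default; six
#'   neighbouring membranes each present their ligand/receptor, so their
#'   contributions add, which also makes a resting tissue's aggregated
#'   receptor match the one-cell boundary convention `N_ext = 5000`) or
#'   `"mean"`.
#' @param thresholds Phenotype thresholds used to label snapshots.
#' @return A list of snapshots (class `tissue_run`); each snapshot is a
#'   `data.frame` with `cell`, `row`, `col`, `time_h`, the 11 species
#'   columns, `emt_label` and `sr_label`. Attributes record the lattice,
#'   aggregation rule and external signals.
#' @export
simulate_tissue <- function(lattice, states0, params, t_end,
                            snapshot_times = NULL, dt = 0.1,
                            I_ext = 0, sD_ext = 0, sJ_ext = 0,
                            aggregation = c("sum", "mean"),
                            thresholds = default_thresholds(params)) {
  aggregation <- match.arg(aggregation)
  states0 <- as_state_matrix(states0)
  check_state(states0)
  if (nrow(states0) != lattice$n_cells) {
    stop("states0 must have one row per lattice cell")
  }
  if (is.null(snapshot_times)) snapshot_times <- t_end
  if (any(snapshot_times < 0) || any(snapshot_times > t_end)) {
    stop("snapshot times must lie within [0, t_end]")
  }
  snapshot_times <- sort(round(snapshot_times / dt) * dt)
  res <- cpp_simulate_tissue(states0, lattice$nbrs,
                             if (aggregation == "mean") 0L else 1L,
                             c(I_ext, sD_ext, sJ_ext),
                             params_to_cpp(params), t_end, dt, snapshot_times)
  snaps <- lapply(seq_along(res$times), function(i) {
    make_snapshot(res$snapshots[[i]], res$times[i], lattice, thresholds)
  })
  structure(snaps,
            class = "tissue_run",
            lattice = lattice, aggregation = aggregation,
            I_ext = I_ext, sD_ext = sD_ext, sJ_ext = sJ_ext, dt = dt)
}

make_snapshot <- function(states, time_h, lattice, thresholds) {
  colnames(states) <- species_names()
  idx <- seq_len(lattice$n_cells)
  out <- data.frame(cell = idx,
                    row = (idx - 1) %/% lattice$cols,
                    col = (idx - 1) %% lattice$cols,
                    time_h = time_h,
                    states)
  out$emt_label <- classify_emt(states, thresholds)
  out$sr_label <- classify_sr(states, thresholds)
  attr(out, "lattice") <- lattice
  class(out) <- c("tissue_snapshot", "data.frame")
  out
}

#' Extract the state matrix from a snapshot
#'
#' @param snapshot A snapshot `data.frame` from [simulate_tissue()].
#' @return `n_cells x 11` numeric state matrix.
#' @export
snapshot_states <- function(snapshot) {
  as.matrix(snapshot[, species_names()])
}

#' Write / read a tissue snapshot as CSV
#'
#' The header comment line records the lattice geometry, boundary,
#' aggregation rule and external signals so a saved snapshot can seed a
#' later run.
#'
#' @param snapshot Snapshot `data.frame`.
#' @param path File path.
#' @param aggregation,I_ext,sD_ext,sJ_ext Run metadata stored in the
#'   header comment.
#' @return `write_snapshot`: the path, invisibly. `read_snapshot`: a
#'   snapshot `data.frame` with a `lattice` attribute.
#' @export
write_snapshot <- function(snapshot, path, aggregation = "sum",
                           I_ext = 0, sD_ext = 0, sJ_ext = 0) {
  lat <- attr(snapshot, "lattice")
  hdr <- sprintf("# rows=%d cols=%d boundary=%s aggregation=%s I_ext=%g sD_ext=%g sJ_ext=%g",
                 lat$rows, lat$cols, lat$boundary, aggregation,
                 I_ext, sD_ext, sJ_ext)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(snapshot), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshot
#' @param path File path.
#' @param thresholds Thresholds used to refresh the labels on load.
#' @export
read_snapshot <- function(path, thresholds = NULL) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "#")) stop("snapshot file lacks its metadata header")
  kv <- strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1]]
  meta <- stats::setNames(
    lapply(kv, function(x) strsplit(x, "=")[[1]][2]),
    vapply(kv, function(x) strsplit(x, "=")[[1]][1], character(1)))
  df <- utils::read.csv(path, comment.char = "#")
  lat <- build_lattice(as.integer(meta$rows), as.integer(meta$cols),
                       boundary = meta$boundary)
  if (!is.null(thresholds)) {
    st <- as.matrix(df[, species_names()])
    df$emt_label <- classify_emt(st, thresholds)
    df$sr_label <- classify_sr(st, thresholds)
  }
  attr(df, "lattice") <- lat
  attr(df, "meta") <- meta
  class(df) <- c("tissue_snapshot", "data.frame")
  df
}
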