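#' Build a hexagonal cell lattice
#'
#' Cells sit on an odd-r offset hexagonal grid (odd rows shifted right by
#' half a cell). Interior cells have exactly six neighbours; with periodic
#' boundaries every cell does. Periodic wrapping of the offset stencil is
#' only consistent for an even number of rows, which is enforced.
#'
#' @param rows,cols Lattice dimensions (>= 2).
#' @param boundary `"periodic"` (default) or `"open"`.
#' @return Object of class `hex_lattice`: list with `rows`, `cols`,
#'   `boundary`, `n_cells` and the `n_cells x 6` integer neighbour matrix
#'   `nbrs` (0 marks a missing neighbour on open boundaries). Cell `i`
#'   sits at row `(i - 1) %/% cols`, column `(i - 1) %% cols` (0-based).
#' @export
build_lattice <- function(rows, cols, boundary = c("periodic", "open")) {
  boundary <- match.arg(boundary)
  if (rows < 2 || cols < 2) stop("lattice dimensions must be at least 2 x 2")
  if (boundary == "periodic" && rows %% 2 != 0) {
    stop("periodic hexagonal lattices require an even number of rows")
  }
  n <- rows * cols
  nbrs <- matrix(0L, n, 6)
  # odd-r offset neighbour stencil, (dr, dc) depending on row parity
  even_off <- cbind(dr = c(0, 0, -1, -1, 1, 1), dc = c(-1, 1, -1, 0, -1, 0))
  odd_off <- cbind(dr = c(0, 0, -1, -1, 1, 1), dc = c(-1, 1, 0, 1, 0, 1))
  for (r in 0:(rows - 1)) {
    off <- if (r %% 2 == 0) even_off else odd_off
    for (c0 in 0:(cols - 1)) {
      i <- r * cols + c0 + 1
      for (k in 1:6) {
        rr <- r + off[k, "dr"]
        cc <- c0 + off[k, "dc"]
        if (boundary == "periodic") {
          rr <- rr %% rows
          cc <- cc %% cols
        } else if (rr < 0 || rr >= rows || cc < 0 || cc >= cols) {
          next
        }
        nbrs[i, k] <- rr * cols + cc + 1L
      }
    }
  }
  structure(list(rows = rows, cols = cols, boundary = boundary,
                 n_cells = n, nbrs = nbrs),
            class = "hex_lattice")
}

#' Neighbour index sets of a lattice
#'
#' @param lattice A [build_lattice()] object.
#' @return List of integer vectors, one per cell.
#' @export
lattice_neighbours <- function(lattice) {
  apply(lattice$nbrs, 1, function(x) sort(x[x > 0]), simplify = FALSE)
}

#' Seeded random initial tissue states
#'
#' Independent random draws per species per cell, reproducible by seed.
#' The default `"log-uniform"` sampling draws each species uniformly on a
#' log scale across three decades below its range upper bound, so the
#' initial tissue populates every phenotype basin (epithelial, hybrid and
#' mesenchymal compositions are all represented); plain `"uniform"`
#' sampling concentrates nearly all cells in the epithelial basin because
#' the epithelial microRNA levels dominate the linear range.
#'
#' @param lattice A [build_lattice()] object.
#' @param params Parameter set (sets the default ranges, see
#'   [default_state_ranges()]).
#' @param seed RNG seed.
#' @param ranges Optional 11 x 2 range matrix overriding the defaults.
#' @param sampling `"log-uniform"` (default) or `"uniform"`.
#' @return `n_cells x 11` state matrix.
#' @export
random_initial_states <- function(lattice, params, seed,
                                  ranges = default_state_ranges(params),
                                  sampling = c("log-uniform", "uniform")) {
  sampling <- match.arg(sampling)
  if (any(ranges < 0) || any(ranges[, 2] < ranges[, 1])) {
    stop("ranges must be non-negative with upper >= lower")
  }
  set.seed(seed)
  n <- lattice$n_cells
  out <- sapply(seq_len(nrow(ranges)), function(k) {
    lo <- ranges[k, 1]
    hi <- ranges[k, 2]
    if (hi <= lo) return(rep(lo, n))
    if (sampling == "uniform") {
      stats::runif(n, lo, hi)
    } else {
      lo_pos <- max(lo, hi / 1000)
      exp(stats::runif(n, log(lo_pos), log(hi)))
    }
  })
  colnames(out) <- species_names()
  out
}

#' Assemble per-cell environments from neighbour states
#'
#' For each cell the juxtacrine inputs are the aggregate (sum by default,
#' or mean) of its neighbours' Notch, Delta and Jagged; soluble ligands and
#' the EMT-inducing signal are added globally.
#'
#' @param lattice A [build_lattice()] object.
#' @param states `n_cells x 11` state matrix.
#' @param I_ext,sD_ext,sJ_ext Global external signals, molecules.
#' @param aggregation `"sum"` (default) or `"mean"`.
#' @return `n_cells x 6` environment matrix.
#' @export
neighbour_environment <- function(lattice, states, I_ext = 0, sD_ext = 0,
                                  sJ_ext = 0,
                                  aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  states <- as_state_matrix(states)
  if (nrow(states) != lattice$n_cells) {
    stop("states must have one row per lattice cell")
  }
  agg_one <- function(col) {
    vals <- matrix(0, lattice$n_cells, 6)
    hit <- lattice$nbrs > 0
    vals[hit] <- states[lattice$nbrs[hit], col]
    s <- rowSums(vals)
    if (aggregation == "mean") s <- s / pmax(rowSums(hit), 1)
    s
  }
  cbind(N_ext = agg_one("N"), D_ext = agg_one("D"),
        J_ext = agg_one("J") , sD_ext = sD_ext, sJ_ext = sJ_ext,
        I_ext = I_ext)
}
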