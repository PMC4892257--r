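#' Brute-force bifurcation sweep of one external parameter
#'
#' Runs [find_stable_states()] at every value of the swept environment
#' input. Stable states found at the previous value are re-used as extra
#' starts (poor man's continuation), which keeps branches tracked through
#' the sweep. EMT and Sender/Receiver labels are attached to every branch.
#'
#' @param name One of `"J_ext"`, `"D_ext"`, `"I_ext"`, `"sJ_ext"`,
#'   `"sD_ext"`.
#' @param values Sorted numeric vector of parameter values.
#' @param base_env Environment holding the non-swept inputs (e.g.
#'   `cell_environment(N_ext = 5000)`).
#' @param params Parameter set.
#' @param n_starts,seed,... Passed to [find_stable_states()].
#' @param thresholds Phenotype thresholds for labelling.
#' @return `data.frame` with columns `param`, `value`, species levels,
#'   `residual`, `emt_label`, `sr_label`; one row per (value, branch).
#' @export
sweep_parameter <- function(name, values, base_env, params,
                            n_starts = 30, seed = 1,
                            thresholds = default_thresholds(params), ...) {
  stopifnot(name %in% c("J_ext", "D_ext", "I_ext", "sJ_ext", "sD_ext"))
  if (is.unsorted(values)) stop("sweep values must be sorted")
  env <- as_env_matrix(base_env)
  prev <- NULL
  out <- list()
  for (v in values) {
    env[, name] <- v
    st <- tryCatch(
      find_stable_states(env, params, n_starts = n_starts, seed = seed,
                         extra_starts = prev, ...),
      error = function(e) {
        stop("sweep failed at ", name, " = ", v, ": ", conditionMessage(e))
      })
    if (nrow(st)) {
      prev <- as.matrix(st[, species_names()])
      res <- data.frame(param = name, value = v, st)
      res$emt_label <- classify_emt(prev, thresholds)
      res$sr_label <- classify_sr(prev, thresholds)
      out[[length(out) + 1]] <- res
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Notch/Delta nullclines of the one-cell system
#'
#' Operationalises the reduced-plane picture: for the Delta curve, Delta is
#' held fixed at each grid value and every other species (Notch included)
#' is relaxed to quasi-steady state, giving points where all time
#' derivatives vanish except possibly dD/dt; the Notch curve swaps the
#' roles. Multiple quasi-steady sheets are captured by relaxing from
#' several starts. Curve crossings are fixed points of the full system;
#' each intersection is classified stable/unstable by integrating the full
#' system from a small perturbation.
#'
#' @param env Environment (the reference setting is
#'   `cell_environment(N_ext = 5000, J_ext = 600)`).
#' @param params Parameter set.
#' @param n_grid Grid resolution along each held axis.
#' @param N_max,D_max Upper ends of the grids; default to twice the
#'   unregulated steady scales.
#' @param t_relax Relaxation horizon (hours) for the quasi-steady solve.
#' @return List with `curve_dN` and `curve_dD` (`data.frame`s of plane
#'   points, with a `branch` sheet index and `converged` flag) and
#'   `intersections` (plane points with full states, `residual` and
#'   `stable` flag).
#' @export
nullclines_nd <- function(env, params, n_grid = 40, N_max = NULL,
                          D_max = NULL, t_relax = 500) {
  rng <- default_state_ranges(params)
  if (is.null(N_max)) N_max <- rng["N", "upper"]
  if (is.null(D_max)) D_max <- rng["D", "upper"]
  e <- as_env_matrix(env)
  # dN-free curve: N fixed on grid, everything else relaxed -> D*(N)
  curve_dN <- qss_curve(fixed = "N", grid = seq(0, N_max, length.out = n_grid),
                        read = "D", e, params, t_relax)
  curve_dD <- qss_curve(fixed = "D", grid = seq(0, D_max, length.out = n_grid),
                        read = "N", e, params, t_relax)
  inter <- curve_intersections(curve_dN, curve_dD)
  inter <- classify_intersections(inter, e, params, t_relax)
  list(curve_dN = curve_dN, curve_dD = curve_dD, intersections = inter)
}

qss_curve <- function(fixed, grid, read, e, params, t_relax) {
  rng <- default_state_ranges(params)
  # starts spanning low/high signalling x low/high EMT sheets
  base <- rng[, "upper"] / 2
  starts0 <- rbind(
    low  = base * c(0.05, 1, 1, 0.05, 1, 1, 1, 1, 1, 1, 1),
    high = base * c(1.8, 0.05, 1.5, 1.5, 1, 1, 1, 1, 1, 1, 1),
    mes  = base * c(1.8, 0.05, 1.5, 1.5, 0.02, 1, 1.8, 0.02, 1.8, 1.8, 1),
    epi  = base * c(0.5, 1, 0.2, 0.1, 1.8, 0.5, 0.2, 1.8, 0.1, 0.02, 1)
  )
  colnames(starts0) <- species_names()
  ifix <- match(fixed, species_names()) - 1L
  pts <- list()
  cp <- params_to_cpp(params)
  for (g in grid) {
    st <- starts0
    st[, fixed] <- g
    res <- cpp_integrate_converge(st, e, cp, t_relax, 0.1, 10, 1e-5,
                                  as.integer(ifix))
    fin <- res$final
    colnames(fin) <- species_names()
    dd <- dedup_states(fin, steady_state_residual(fin, e, params, eps = 1),
                       0.02)
    dd <- dd[order(dd[[read]]), ]
    pts[[length(pts) + 1]] <- data.frame(value = g, branch = seq_len(nrow(dd)),
                                         dd, converged = TRUE)
  }
  out <- do.call(rbind, pts)
  out$fixed_species <- fixed
  rownames(out) <- NULL
  out
}

# polyline segment intersections between the two quasi-steady curves
curve_intersections <- function(curve_dN, curve_dD) {
  segs <- function(curve, xcol, ycol) {
    pieces <- split(curve, curve$branch)
    do.call(rbind, lapply(pieces, function(p) {
      p <- p[order(p$value), ]
      if (nrow(p) < 2) return(NULL)
      data.frame(x0 = p[[xcol]][-nrow(p)], y0 = p[[ycol]][-nrow(p)],
                 x1 = p[[xcol]][-1], y1 = p[[ycol]][-1])
    }))
  }
  # plane coordinates: x = N, y = D
  a <- segs(curve_dN, "value", "D")   # N fixed -> (N, D*)
  b <- segs(curve_dD, "N", "value")   # D fixed -> (N*, D)
  hits <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      p <- seg_intersect(a$x0[i], a$y0[i], a$x1[i], a$y1[i],
                         b$x0[j], b$y0[j], b$x1[j], b$y1[j])
      if (!is.null(p)) hits[[length(hits) + 1]] <- data.frame(N = p[1], D = p[2])
    }
  }
  if (!length(hits)) return(data.frame(N = numeric(0), D = numeric(0)))
  out <- unique(do.call(rbind, hits))
  # merge near-duplicates (relative 2%)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j <= i || !keep[j]) next
      if (max(abs(out[i, ] - out[j, ]) / pmax(abs(out[i, ]), 1)) < 0.02) {
        keep[j] <- FALSE
      }
    }
  }
  out[keep, , drop = FALSE]
}

seg_intersect <- function(x0, y0, x1, y1, u0, v0, u1, v1) {
  d1 <- c(x1 - x0, y1 - y0)
  d2 <- c(u1 - u0, v1 - v0)
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(NULL)
  t <- ((u0 - x0) * d2[2] - (v0 - y0) * d2[1]) / den
  s <- ((u0 - x0) * d1[2] - (v0 - y0) * d1[1]) / den
  if (t < 0 || t > 1 || s < 0 || s > 1) return(NULL)
  c(x0 + t * d1[1], y0 + t * d1[2])
}

classify_intersections <- function(inter, e, params, t_relax) {
  if (!nrow(inter)) return(inter)
  cp <- params_to_cpp(params)
  rows <- list()
  for (i in seq_len(nrow(inter))) {
    st <- matrix(0, 1, 11, dimnames = list(NULL, species_names()))
    st[1, "N"] <- inter$N[i]
    st[1, "D"] <- inter$D[i]
    rng <- default_state_ranges(params)
    st[1, setdiff(species_names(), c("N", "D"))] <-
      rng[setdiff(species_names(), c("N", "D")), "upper"] / 2
    # fill the remaining species on the quasi-steady sheet
    res <- cpp_integrate_converge(st, e, cp, t_relax, 0.1, 10, 1e-5,
                                  as.integer(match(c("N", "D"), species_names()) - 1L))
    full <- res$final
    colnames(full) <- species_names()
    # stability: release the clamp from a 1% perturbation; a stable
    # intersection relaxes onto the nearby fixed point, an unstable one
    # flees to a different attractor
    pert <- full * 1.01 + 1e-6
    rel <- cpp_integrate_converge(pert, e, cp, 500, 0.1, 10, 1e-6, integer(0))
    fin <- rel$final
    colnames(fin) <- species_names()
    # flee distance on a mixed scale: relative for abundant species, but a
    # small fraction of the species' dynamic range for near-empty ones
    scale <- pmax(abs(full[1, ]),
                  0.02 * default_state_ranges(params)[, "upper"], 1)
    moved <- max(abs(fin[1, ] - full[1, ]) / scale)
    stable <- moved < 0.1
    # report the refined fixed point for stable intersections
    if (stable) full <- fin
    resid <- steady_state_residual(full, e, params)
    rows[[i]] <- data.frame(as.data.frame(full), residual = resid,
                            stable = stable)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-parameter (D_ext, J_ext) phase diagram
#'
#' Enumerates the coexisting stable states on a grid of external Delta and
#' Jagged levels and records the sorted set of (EMT, signalling) labels at
#' every grid point.
#'
#' @param D_values,J_values Sorted grids (>= 2 points each).
#' @param base_env Environment for the non-swept inputs.
#' @param params Parameter set.
#' @param n_starts,seed,... Passed to [find_stable_states()].
#' @param thresholds Phenotype thresholds.
#' @return `data.frame` with `D_ext`, `J_ext`, `n_states` and `labels`
#'   (sorted unique `"EMT,SR"` pairs joined by `|`).
#' @export
phase_diagram <- function(D_values, J_values, base_env, params,
                          n_starts = 24, seed = 1,
                          thresholds = default_thresholds(params), ...) {
  if (is.unsorted(D_values) || is.unsorted(J_values)) {
    stop("phase-diagram grids must be sorted")
  }
  env <- as_env_matrix(base_env)
  out <- list()
  prev_col <- vector("list", length(J_values))
  for (d in D_values) {
    for (ji in seq_along(J_values)) {
      env[, "D_ext"] <- d
      env[, "J_ext"] <- J_values[ji]
      st <- find_stable_states(env, params, n_starts = n_starts, seed = seed,
                               extra_starts = prev_col[[ji]], ...)
      if (nrow(st)) {
        m <- as.matrix(st[, species_names()])
        prev_col[[ji]] <- m
        lab <- paste(classify_emt(m, thresholds), classify_sr(m, thresholds),
                     sep = ",")
        lab <- paste(sort(unique(lab)), collapse = "|")
      } else {
        lab <- ""
      }
      out[[length(out) + 1]] <- data.frame(D_ext = d, J_ext = J_values[ji],
                                           n_states = nrow(st), labels = lab)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
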