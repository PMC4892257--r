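#' Integrate a single cell under a fixed environment
#'
#' Deterministic fixed-step fourth-order Runge-Kutta integration of the
#' per-cell circuit. Species are floored at zero after every step, which
#' guards the non-negativity invariant against rare integrator undershoot.
#'
#' @param state0 Initial state from [cell_state()] (or an n x 11 matrix to
#'   integrate several independent cells sharing the environment).
#' @param env Environment from [cell_environment()].
#' @param params Parameter set.
#' @param t_end Final time, hours.
#' @param dt Step size, hours (default 0.1).
#' @param record_times Times (hours) at which to record the state; snapped
#'   to the step grid. Defaults to ~200 evenly spaced points.
#' @return A `data.frame` with column `time_h` followed by one column per
#'   species (for matrix input, an additional `cell` column).
#' @export
integrate_cell <- function(state0, env, params, t_end, dt = 0.1,
                           record_times = NULL) {
  stopifnot(dt > 0, t_end >= dt)
  y <- as_state_matrix(state0)
  check_state(y)
  e <- as_env_matrix(env)
  if (is.null(record_times)) {
    by <- max(dt, round(t_end / 200 / dt) * dt)
    record_times <- unique(c(seq(0, t_end, by = by), t_end))
  }
  record_times <- sort(round(record_times / dt) * dt)
  res <- cpp_integrate(y, e, params_to_cpp(params), t_end, dt, record_times)
  rows <- lapply(seq_along(res$times), function(i) {
    snap <- res$snapshots[[i]]
    colnames(snap) <- species_names()
    data.frame(time_h = res$times[i], cell = seq_len(nrow(snap)), snap)
  })
  out <- do.call(rbind, rows)
  if (nrow(y) == 1) out$cell <- NULL
  rownames(out) <- NULL
  out
}

#' Default random initial-condition ranges
#'
#' Per-species uniform sampling ranges used for random starts and random
#' tissue initial conditions: twice the species' unregulated steady scale
#' (production over degradation, with protein scales composed through
#' their mRNA). The ZEB arm additionally carries its self-activation fold
#' change so that starts cover the mesenchymal basin, whose ZEB levels sit
#' far above the unregulated scale. NICD, a fast variable slaved to
#' receptor and external ligand, gets a quarter of the receptor scale.
#'
#' @param params Parameter set.
#' @return An 11 x 2 matrix (`lower`, `upper`), rows named by species.
#' @export
default_state_ranges <- function(params) {
  p <- params
  mz_scale <- (p$emt$gmz / p$emt$gammamz) *
    max(1, find_hill(p, "Z_mz")$lambda)
  up <- c(
    N = 2 * p$notch$gN / p$notch$gammaN,
    D = 2 * p$notch$gD / p$notch$gammaD,
    J = 2 * p$notch$gJ / p$notch$gammaJ,
    I = 0.25 * p$notch$gN / p$notch$gammaN,
    miR34 = 2 * p$emt$gu34 / p$emt$gammau34,
    mS = 2 * p$emt$gms / p$emt$gammams,
    S = 2 * (p$emt$gs / p$emt$gammas) * (p$emt$gms / p$emt$gammams),
    miR200 = 2 * p$emt$gu200 / p$emt$gammau200,
    mZ = 2 * mz_scale,
    Z = 2 * (p$emt$gz / p$emt$gammaz) * mz_scale,
    F = if (isTRUE(p$fringe$enabled)) 2 * p$fringe$gF / p$fringe$gammaF else 0
  )
  cbind(lower = 0 * up, upper = up)
}

#' Enumerate stable steady states by multi-start relaxation
#'
#' Integrates `n_starts` random initial conditions to convergence
#' (relative change below `reltol` over a trailing `window`), verifies each
#' converged end point against the scale-free steady-state residual, and
#' deduplicates at `dedup_tol` relative L-infinity distance (the
#' representative with the smaller residual is kept). Relaxation cannot
#' land on unstable saddles, so every reported state is stable.
#'
#' @param env Environment from [cell_environment()].
#' @param params Parameter set.
#' @param n_starts Number of random starts (>= 20).
#' @param seed RNG seed for the starts.
#' @param tol Residual tolerance for accepting a steady state.
#' @param t_max Maximum integration time, hours.
#' @param dt Step size, hours.
#' @param window,reltol Convergence window (hours) and relative tolerance.
#' @param dedup_tol Relative L-infinity deduplication distance.
#' @param extra_starts Optional matrix of additional (deterministic)
#'   starts, e.g. branch continuation from a neighbouring parameter value.
#' @return A `data.frame` with one row per distinct stable state: species
#'   columns plus `residual`. Zero rows (with a warning) if no start
#'   converged.
#' @export
find_stable_states <- function(env, params, n_starts = 30, seed = 1,
                               tol = 1e-3, t_max = 2000, dt = 0.1,
                               window = 10, reltol = 1e-6,
                               dedup_tol = 0.01, extra_starts = NULL) {
  stopifnot(n_starts >= 20)
  rng <- default_state_ranges(params)
  set.seed(seed)
  starts <- sapply(seq_len(nrow(rng)), function(k) {
    stats::runif(n_starts, rng[k, 1], rng[k, 2])
  })
  colnames(starts) <- species_names()
  starts <- rbind(starts, canonical_starts(params, env))
  if (!is.null(extra_starts)) starts <- rbind(starts, as_state_matrix(extra_starts))
  e <- as_env_matrix(env)
  res <- cpp_integrate_converge(starts, e, params_to_cpp(params),
                                t_max, dt, window, reltol, integer(0))
  final <- res$final
  colnames(final) <- species_names()
  keep <- res$converged
  if (!any(keep)) {
    warning("no start converged to a steady state")
    out <- as.data.frame(final[0, , drop = FALSE])
    out$residual <- numeric(0)
    return(out)
  }
  final <- final[keep, , drop = FALSE]
  resid <- steady_state_residual(final, e, params)
  ok <- resid < tol
  if (!any(ok)) {
    warning("no converged end point passed the residual test")
    out <- as.data.frame(final[0, , drop = FALSE])
    out$residual <- numeric(0)
    return(out)
  }
  final <- final[ok, , drop = FALSE]
  resid <- resid[ok]
  dedup_states(final, resid, dedup_tol)
}

# Deterministic starts covering the canonical basins: the four signalling
# roles (quiescent, Sender-like, Receiver-like, hybrid) crossed with the
# epithelial and mesenchymal EMT-core compositions. Random starts alone can
# miss a narrow basin (e.g. the Receiver branch when cis-inhibition is
# strong); these compositions make the enumeration reproducibly exhaustive
# for the circuit's known attractor types.
canonical_starts <- function(params, env) {
  p <- params
  e <- as_env_matrix(env)[1, ]
  lig <- e[["D_ext"]] + e[["J_ext"]] + e[["sD_ext"]] + e[["sJ_ext"]]
  Ns <- p$notch$gN / p$notch$gammaN
  Ds <- p$notch$gD / (p$notch$gammaD +
                        p$notch$kt * p$notch$affinityD * e[["N_ext"]])
  Js <- p$notch$gJ / (p$notch$gammaJ +
                        p$notch$kt * p$notch$affinityJ * e[["N_ext"]])
  Imax <- p$notch$kt * 3 * Ns * lig / p$notch$gammaI
  sig <- rbind(
    quiet = c(N = 0, D = 0, J = 0, I = 0),
    sender = c(N = 0.05 * Ns, D = Ds, J = 0, I = 0),
    receiver = c(N = 3 * Ns, D = 0, J = Js, I = Imax),
    receiver_mild = c(N = Ns, D = 0, J = Js, I = Imax / 3),
    hybrid = c(N = 3 * Ns, D = 0, J = 3 * Js, I = Imax)
  )
  mz_scale <- (p$emt$gmz / p$emt$gammamz) * max(1, find_hill(p, "Z_mz")$lambda)
  S_scale <- (p$emt$gs / p$emt$gammas) * (p$emt$gms / p$emt$gammams)
  emt <- rbind(
    epi = c(miR34 = p$emt$gu34 / p$emt$gammau34, mS = 0, S = 0,
            miR200 = p$emt$gu200 / p$emt$gammau200, mZ = 0, Z = 0),
    hyb = c(miR34 = 0.3 * p$emt$gu34 / p$emt$gammau34,
            mS = p$emt$gms / p$emt$gammams, S = 1.4 * S_scale,
            miR200 = 0.25 * p$emt$gu200 / p$emt$gammau200,
            mZ = 0.25 * mz_scale,
            Z = 0.25 * (p$emt$gz / p$emt$gammaz) * mz_scale),
    mes = c(miR34 = 0, mS = 2 * p$emt$gms / p$emt$gammams,
            S = 1.5 * S_scale,
            miR200 = 0, mZ = mz_scale,
            Z = 0.5 * (p$emt$gz / p$emt$gammaz) * mz_scale)
  )
  out <- matrix(0, nrow(sig) * nrow(emt), length(species_names()),
                dimnames = list(NULL, species_names()))
  k <- 0
  for (i in seq_len(nrow(sig))) {
    for (j in seq_len(nrow(emt))) {
      k <- k + 1
      out[k, names(sig[i, ])] <- sig[i, ]
      out[k, names(emt[j, ])] <- emt[j, ]
    }
  }
  out
}

# relative L-infinity deduplication keeping the smallest-residual member
dedup_states <- function(states, resid, dedup_tol) {
  ord <- order(resid)
  states <- states[ord, , drop = FALSE]
  resid <- resid[ord]
  kept <- integer(0)
  for (i in seq_len(nrow(states))) {
    dup <- FALSE
    for (j in kept) {
      d <- max(abs(states[i, ] - states[j, ]) /
                 pmax(abs(states[i, ]), abs(states[j, ]), 1))
      if (d < dedup_tol) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  out <- as.data.frame(states[kept, , drop = FALSE])
  out$residual <- resid[kept]
  rownames(out) <- NULL
  out[order(-out$miR200, out$N), ]
}
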