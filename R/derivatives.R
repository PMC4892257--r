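#' Right-hand side of the per-cell ODE system
#'
#' Reference (pure R) implementation of the coupled Notch-Delta-Jagged /
#' EMT circuit. Production of every species is its basal rate times the
#' shifted-Hill factor of each incoming transcriptional edge, times the
#' microRNA translation factor where the species is a microRNA target.
#' Losses are linear degradation, microRNA-mediated active mRNA
#' degradation (SNAIL and ZEB mRNAs), cis-inhibition (`kc * N * D`,
#' `kc * N * J` remove receptor and ligand together) and trans-interaction:
#' the receptor is consumed by external ligand
#' (`kt * N * (D_ext + J_ext + sD_ext + sJ_ext)`, which is also the NICD
#' production flux) and the ligands by external receptor (`kt * D * N_ext`,
#' `kt * J * N_ext`; soluble ligands are not presented on a membrane and
#' engage neither cis-inhibition nor this term). All trans-interaction
#' terms carry the ligand-specific affinity factors `affinityD` /
#' `affinityJ`; with Fringe enabled these are further scaled up (Delta)
#' and down (Jagged) by shifted-Hill functions of F.
#'
#' The compiled integrator uses an independent C++ transcription of the
#' same equations; the test suite checks the two against each other.
#'
#' @param state Named state vector from [cell_state()], or an n x 11 matrix
#'   (one row per cell).
#' @param env Environment from [cell_environment()], or a matrix with one
#'   row per cell.
#' @param params An `ndj_params` parameter set.
#' @return Rate-of-change vector (molecules/h), same shape as `state`.
#' @export
cell_derivatives <- function(state, env, params) {
  vec_in <- is.null(dim(state))
  y <- as_state_matrix(state)
  check_state(y)
  e <- as_env_matrix(env)
  if (nrow(e) == 1 && nrow(y) > 1) e <- e[rep(1, nrow(y)), , drop = FALSE]
  if (any(!is.finite(e)) || any(e < 0)) stop("environment must be finite and non-negative")
  p <- params

  hs <- function(X, name) shifted_hill(X, do.call(hill_spec, find_hill(p, name)[c("X0", "n", "lambda")]))
  N <- y[, "N"]; D <- y[, "D"]; J <- y[, "J"]; I <- y[, "I"]
  u34 <- y[, "miR34"]; ms <- y[, "mS"]; S <- y[, "S"]
  u200 <- y[, "miR200"]; mz <- y[, "mZ"]; Z <- y[, "Z"]; F <- y[, "F"]
  Next <- e[, "N_ext"]; Dext <- e[, "D_ext"]; Jext <- e[, "J_ext"]
  sDext <- e[, "sD_ext"]; sJext <- e[, "sJ_ext"]; Iext <- e[, "I_ext"]

  fringe_on <- isTRUE(p$fringe$enabled) || identical(p$fringe$enabled, 1)
  fD <- p$notch$affinityD * (if (fringe_on) hs(F, "F_delta") else 1)
  fJ <- p$notch$affinityJ * (if (fringe_on) hs(F, "F_jagged") else 1)
  ktD <- p$notch$kt * fD; ktJ <- p$notch$kt * fJ
  kcD <- p$notch$kc; kcJ <- p$notch$kc

  L34N <- mirna_repression(u34, get_mirna_spec(p, "mir34_N"))$translation
  L34D <- mirna_repression(u34, get_mirna_spec(p, "mir34_D"))$translation
  L200J <- mirna_repression(u200, get_mirna_spec(p, "mir200_J"))$translation
  r34 <- mirna_repression(u34, get_mirna_spec(p, "mir34_ms"))
  r200 <- mirna_repression(u200, get_mirna_spec(p, "mir200_mz"))

  sig <- ktD * N * (Dext + sDext) + ktJ * N * (Jext + sJext)

  out <- cbind(
    N = p$notch$gN * hs(I, "I_N") * L34N -
      kcD * N * D - kcJ * N * J - sig - p$notch$gammaN * N,
    D = p$notch$gD * hs(I, "I_D") * L34D -
      kcD * N * D - ktD * D * Next - p$notch$gammaD * D,
    J = p$notch$gJ * hs(I, "I_J") * L200J -
      kcJ * N * J - ktJ * J * Next - p$notch$gammaJ * J,
    I = sig - p$notch$gammaI * I,
    miR34 = p$emt$gu34 * hs(S, "S_u34") * hs(Z, "Z_u34") -
      ms * r34$mirna_loss - p$emt$gammau34 * u34,
    mS = p$emt$gms * hs(S, "S_ms") * hs(I, "I_ms") * hs(Iext, "Iext_ms") -
      ms * r34$degradation - p$emt$gammams * ms,
    S = p$emt$gs * ms * r34$translation - p$emt$gammas * S,
    miR200 = p$emt$gu200 * hs(S, "S_u200") * hs(Z, "Z_u200") -
      mz * r200$mirna_loss - p$emt$gammau200 * u200,
    mZ = p$emt$gmz * hs(S, "S_mz") * hs(Z, "Z_mz") -
      mz * r200$degradation - p$emt$gammamz * mz,
    Z = p$emt$gz * mz * r200$translation - p$emt$gammaz * Z,
    F = if (fringe_on) p$fringe$gF * hs(I, "I_F") - p$fringe$gammaF * F else 0 * N
  )
  if (vec_in) out[1, ] else out
}

#' Steady-state residual of a candidate fixed point
#'
#' Scale-free residual `max |dX/dt| / (gamma_X * X + eps)` used to verify
#' reported stable states.
#'
#' @param state State vector or matrix.
#' @param env Environment.
#' @param params Parameter set.
#' @param eps Softening constant (molecules/h) protecting empty species.
#' @return Numeric residual, one per state row.
#' @export
steady_state_residual <- function(state, env, params, eps = 1) {
  y <- as_state_matrix(state)
  d <- cell_derivatives(y, env, params)
  if (is.null(dim(d))) d <- matrix(d, nrow = 1, dimnames = list(NULL, species_names()))
  g <- c(params$notch$gammaN, params$notch$gammaD, params$notch$gammaJ,
         params$notch$gammaI, params$emt$gammau34, params$emt$gammams,
         params$emt$gammas, params$emt$gammau200, params$emt$gammamz,
         params$emt$gammaz, params$fringe$gammaF)
  scale <- sweep(y, 2, g, "*") + eps
  apply(abs(d) / scale, 1, max)
}
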