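#' Shifted-Hill regulatory edge specification
#'
#' A shifted Hill function is the regulation primitive used by every
#' transcriptional edge of the circuit. It equals 1 when the regulator is
#' absent and saturates at the fold change `lambda`: values of `lambda`
#' below 1 encode repression, above 1 activation, and `lambda = 1` a
#' neutral (disconnected) edge.
#'
#' @param X0 Half-response threshold of the regulator, in molecules (> 0).
#' @param n Hill coefficient (>= 1).
#' @param lambda Fold change at saturating regulator (>= 0).
#' @return An object of class `hill_spec`.
#' @examples
#' sp <- hill_spec(X0 = 200, n = 2, lambda = 2)
#' shifted_hill(200, sp)  # midpoint: (1 + lambda)/2
#' @export
hill_spec <- function(X0, n, lambda) {
  stopifnot(is.numeric(X0), length(X0) == 1, is.finite(X0), X0 > 0)
  stopifnot(is.numeric(n), length(n) == 1, is.finite(n), n >= 1)
  stopifnot(is.numeric(lambda), length(lambda) == 1, is.finite(lambda), lambda >= 0)
  structure(list(X0 = X0, n = n, lambda = lambda), class = "hill_spec")
}

#' Evaluate a shifted Hill function
#'
#' Computes `(1 + lambda * (X/X0)^n) / (1 + (X/X0)^n)`, the
#' (1 - lambda)-weighted inhibitory Hill function plus `lambda`. The result
#' is 1 at `X = 0`, `(1 + lambda)/2` at `X = X0` and tends to `lambda` as
#' `X` grows; it is continuous and monotone in `X`.
#'
#' @param X Regulator abundance in molecules (vectorised, >= 0).
#' @param spec A [hill_spec()].
#' @return Dimensionless positive multiplier, same length as `X`.
#' @export
shifted_hill <- function(X, spec) {
  if (!inherits(spec, "hill_spec")) spec <- do.call(hill_spec, as.list(spec))
  if (any(!is.finite(X)) || any(X < 0)) {
    stop("shifted_hill: regulator abundance must be finite and non-negative")
  }
  r <- (X / spec$X0)^spec$n
  (1 + spec$lambda * r) / (1 + r)
}

#' MicroRNA-mRNA combinatorial repression specification
#'
#' Models a microRNA that binds `sites` sites on a target mRNA. Occupancy
#' of `i` sites is binomially weighted,
#' `M_i(mu) = choose(sites, i) * (mu/mu0)^i / (1 + mu/mu0)^sites`, and each
#' occupancy level carries a translation factor `l_i` (non-increasing in
#' `i`), an active mRNA degradation rate `gm_i` and a microRNA consumption
#' rate `gu_i` (degradation of the microRNA together with its target).
#'
#' @param sites Number of binding sites (>= 1).
#' @param mu0 MicroRNA threshold, molecules.
#' @param translation Numeric vector of length `sites + 1`, per-occupancy
#'   translation factors in `[0, 1]`, non-increasing, first element 1.
#' @param mrna_deg Per-occupancy active mRNA degradation rates (1/h),
#'   non-negative, first element 0. Defaults to all zero (translational
#'   silencing only, used for the Notch-pathway proteins which are not
#'   modelled with an explicit mRNA).
#' @param mirna_deg Per-occupancy microRNA consumption rates (1/h),
#'   non-negative, first element 0. Defaults to all zero.
#' @return An object of class `mirna_spec`.
#' @export
mirna_spec <- function(sites, mu0, translation,
                       mrna_deg = rep(0, sites + 1),
                       mirna_deg = rep(0, sites + 1)) {
  stopifnot(sites >= 1, sites == round(sites), mu0 > 0)
  stopifnot(length(translation) == sites + 1,
            length(mrna_deg) == sites + 1,
            length(mirna_deg) == sites + 1)
  if (any(translation < 0) || any(translation > 1) ||
      any(diff(translation) > 1e-12)) {
    stop("mirna_spec: translation factors must lie in [0,1] and be non-increasing")
  }
  if (any(mrna_deg < 0) || any(mirna_deg < 0)) {
    stop("mirna_spec: degradation rates must be non-negative")
  }
  structure(list(sites = as.integer(sites), mu0 = mu0,
                 translation = as.numeric(translation),
                 mrna_deg = as.numeric(mrna_deg),
                 mirna_deg = as.numeric(mirna_deg)),
            class = "mirna_spec")
}

#' Evaluate microRNA repression of a target
#'
#' @param mu MicroRNA abundance, molecules (vectorised, >= 0).
#' @param rep A [mirna_spec()].
#' @return A list with components `translation` (dimensionless factor in
#'   `[0, 1]`, equals 1 at `mu = 0`), `degradation` (active mRNA degradation
#'   rate, 1/h, 0 at `mu = 0`) and `mirna_loss` (microRNA consumption rate
#'   per target mRNA molecule, 1/h).
#' @export
mirna_repression <- function(mu, rep) {
  if (!inherits(rep, "mirna_spec")) stop("rep must be a mirna_spec")
  if (any(!is.finite(mu)) || any(mu < 0)) {
    stop("mirna_repression: microRNA abundance must be finite and non-negative")
  }
  x <- mu / rep$mu0
  n <- rep$sites
  denom <- (1 + x)^n
  L <- 0; Ym <- 0; Yu <- 0
  for (i in 0:n) {
    Mi <- choose(n, i) * x^i / denom
    L <- L + rep$translation[i + 1] * Mi
    Ym <- Ym + rep$mrna_deg[i + 1] * Mi
    Yu <- Yu + i * rep$mirna_deg[i + 1] * Mi
  }
  list(translation = L, degradation = Ym, mirna_loss = Yu)
}
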