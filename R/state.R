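#' Construct a per-cell state vector
#'
#' @param N,D,J,I Notch receptor, Delta, Jagged and NICD (molecules).
#' @param miR34,mS,S miR-34, SNAIL mRNA and SNAIL protein (molecules).
#' @param miR200,mZ,Z miR-200, ZEB mRNA and ZEB protein (molecules).
#' @param F Fringe (molecules; ignored unless the Fringe module is enabled).
#' @return Named numeric vector in the canonical [species_names()] order.
#' @export
cell_state <- function(N = 0, D = 0, J = 0, I = 0, miR34 = 0, mS = 0, S = 0,
                       miR200 = 0, mZ = 0, Z = 0, F = 0) {
  out <- c(N = N, D = D, J = J, I = I, miR34 = miR34, mS = mS, S = S,
           miR200 = miR200, mZ = mZ, Z = Z, F = F)
  check_state(out)
  out
}

check_state <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("cell state must be finite and non-negative")
  }
  invisible(x)
}

#' Construct a cell environment
#'
#' External inputs seen by a single cell: the receptor and ligands presented
#' by neighbouring membranes (`N_ext`, `D_ext`, `J_ext`), soluble ligands
#' (`sD_ext`, `sJ_ext`) and the lumped EMT-inducing signal `I_ext` (e.g.
#' TGF-beta/Wnt) acting on SNAIL transcription.
#'
#' @param N_ext,D_ext,J_ext Juxtacrine receptor/ligand abundances, molecules.
#' @param sD_ext,sJ_ext Soluble ligand abundances, molecules.
#' @param I_ext EMT-inducing signal, molecules.
#' @return Named numeric vector of length 6.
#' @export
cell_environment <- function(N_ext = 0, D_ext = 0, J_ext = 0,
                             sD_ext = 0, sJ_ext = 0, I_ext = 0) {
  out <- c(N_ext = N_ext, D_ext = D_ext, J_ext = J_ext,
           sD_ext = sD_ext, sJ_ext = sJ_ext, I_ext = I_ext)
  if (any(!is.finite(out)) || any(out < 0)) {
    stop("environment entries must be finite and non-negative")
  }
  out
}

# Coerce a state (vector or matrix/data.frame) to an n x 11 matrix.
as_state_matrix <- function(state) {
  if (is.data.frame(state)) state <- as.matrix(state[species_names()])
  if (is.null(dim(state))) {
    state <- matrix(state, nrow = 1,
                    dimnames = list(NULL, names(state)))
  }
  if (!is.null(colnames(state))) {
    missing <- setdiff(species_names(), colnames(state))
    if (length(missing)) stop("state lacks species: ", paste(missing, collapse = ", "))
    state <- state[, species_names(), drop = FALSE]
  } else if (ncol(state) != length(species_names())) {
    stop("state must have ", length(species_names()), " columns")
  }
  storage.mode(state) <- "double"
  colnames(state) <- species_names()
  state
}

as_env_matrix <- function(env, n = NULL) {
  env_names <- c("N_ext", "D_ext", "J_ext", "sD_ext", "sJ_ext", "I_ext")
  if (is.data.frame(env)) env <- as.matrix(env)
  if (is.null(dim(env))) {
    full <- cell_environment()
    full[names(env)] <- env
    env <- matrix(full, nrow = 1, dimnames = list(NULL, env_names))
  }
  if (!is.null(colnames(env))) env <- env[, env_names, drop = FALSE]
  storage.mode(env) <- "double"
  colnames(env) <- env_names
  env
}
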