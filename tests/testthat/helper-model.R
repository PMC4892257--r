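# Shared helpers for the suite.

# Parameter set with every regulatory edge neutralised: no Hills (lambda = 1),
# no microRNA repression, no binding. The model then reduces to independent
# linear birth-death processes with closed-form steady state g/gamma.
neutral_params <- function() {
  p <- default_parameters()
  for (blk in c("notch", "emt", "coupling", "fringe")) {
    for (nm in names(p[[blk]])) {
      if (startsWith(nm, "hill_")) p[[blk]][[nm]]$lambda <- 1
    }
  }
  for (nm in c("mir34_N", "mir34_D", "mir200_J")) {
    k <- length(p$notch[[nm]]$translation)
    p$notch[[nm]]$translation <- rep(1, k)
  }
  for (nm in c("mir34_ms", "mir200_mz")) {
    k <- length(p$emt[[nm]]$translation)
    p$emt[[nm]]$translation <- rep(1, k)
    p$emt[[nm]]$mrna_deg <- rep(0, k)
    p$emt[[nm]]$mirna_deg <- rep(0, k)
  }
  p$notch$kt <- 0
  p$notch$kc <- 0
  validate_params(p)
}

# closed-form steady state of the neutral model, in species order
neutral_fixed_point <- function(p) {
  c(N = p$notch$gN / p$notch$gammaN,
    D = p$notch$gD / p$notch$gammaD,
    J = p$notch$gJ / p$notch$gammaJ,
    I = 0,
    miR34 = p$emt$gu34 / p$emt$gammau34,
    mS = p$emt$gms / p$emt$gammams,
    S = (p$emt$gs / p$emt$gammas) * (p$emt$gms / p$emt$gammams),
    miR200 = p$emt$gu200 / p$emt$gammau200,
    mZ = p$emt$gmz / p$emt$gammamz,
    Z = (p$emt$gz / p$emt$gammaz) * (p$emt$gmz / p$emt$gammamz),
    F = 0)
}

# Notch pathway removed: the isolated EMT core driven by I_ext only
decoupled_params <- function(p = default_parameters()) {
  p$notch$kt <- 0
  p$notch$gN <- 0
  p$notch$gD <- 0
  p$notch$gJ <- 0
  p
}

random_state_matrix <- function(n, params, seed) {
  rng <- default_state_ranges(params)
  set.seed(seed)
  out <- vapply(seq_len(nrow(rng)),
                function(k) runif(n, rng[k, 1], rng[k, 2]), numeric(n))
  out <- matrix(out, nrow = n, dimnames = list(NULL, species_names()))
  out
}

# independent brute-force connected components by breadth-first flood fill
flood_fill_sizes <- function(inset, lattice) {
  seen <- rep(FALSE, lattice$n_cells)
  sizes <- integer(0)
  for (s in which(inset)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(queue)) {
      i <- queue[1]
      queue <- queue[-1]
      size <- size + 1L
      for (j in lattice$nbrs[i, ]) {
        if (j > 0 && inset[j] && !seen[j]) {
          seen[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}
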