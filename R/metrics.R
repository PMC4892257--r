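#' Phenotype fractions of a snapshot
#'
#' @param snapshot Labelled snapshot `data.frame` (column `emt_label`).
#' @return Named numeric vector `c(E = , `E/M` = , M = )`, summing to 1.
#' @export
phenotype_fractions <- function(snapshot) {
  lab <- factor(snapshot$emt_label, levels = c("E", "E/M", "M"))
  f <- as.vector(table(lab)) / nrow(snapshot)
  stats::setNames(f, c("E", "E/M", "M"))
}

#' Connected-component cluster sizes of a phenotype
#'
#' Connected components of the cells carrying `label` under the hexagonal
#' neighbour relation, computed by union-find. `label = "non-E"` pools the
#' E/M and M cells.
#'
#' @param snapshot Labelled snapshot.
#' @param label `"E"`, `"E/M"`, `"M"` or `"non-E"`.
#' @param lattice Lattice; defaults to the snapshot's `lattice` attribute.
#' @return Decreasing integer vector of cluster sizes (empty if no cell
#'   carries the label).
#' @export
cluster_components <- function(snapshot, label,
                               lattice = attr(snapshot, "lattice")) {
  if (is.null(lattice)) stop("no lattice attached to the snapshot")
  known <- c("E", "E/M", "M", "non-E")
  if (!label %in% known) stop("unknown label: ", label)
  inset <- if (label == "non-E") snapshot$emt_label != "E"
           else snapshot$emt_label == label
  n <- lattice$n_cells
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in which(inset)) {
    for (j in lattice$nbrs[i, ]) {
      if (j > 0 && j > i && inset[j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(which(inset), function(i) as.integer(find(i)), integer(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

#' Fraction of neighbour pairs with unlike EMT labels
#'
#' Counts each unordered neighbour pair once; open-boundary lattices count
#' only existing pairs. A checkerboard-like 'salt-and-pepper' arrangement
#' scores high, clustered arrangements score low.
#'
#' @param snapshot Labelled snapshot.
#' @param lattice Lattice; defaults to the snapshot's attribute.
#' @return Value in `[0, 1]`.
#' @export
unlike_neighbour_fraction <- function(snapshot,
                                      lattice = attr(snapshot, "lattice")) {
  if (is.null(lattice)) stop("no lattice attached to the snapshot")
  lab <- snapshot$emt_label
  i <- rep(seq_len(lattice$n_cells), 6)
  j <- as.vector(lattice$nbrs)
  keep <- j > 0 & j > i   # each unordered pair once
  mean(lab[i[keep]] != lab[j[keep]])
}

#' Mean NICD of a snapshot
#'
#' @param snapshot Snapshot with the NICD column `I`.
#' @param reference Optional reference snapshot (typically the
#'   `I_ext = 0` run); when given, the relative variant
#'   `mean(I) / mean(I_reference)` is returned.
#' @return Molecules, or the dimensionless relative level.
#' @export
mean_nicd <- function(snapshot, reference = NULL) {
  m <- mean(snapshot$I)
  if (is.null(reference)) return(m)
  if (is.null(reference$I)) stop("reference snapshot lacks the NICD column")
  m / mean(reference$I)
}

#' Full pattern summary of a snapshot
#'
#' @param snapshot Labelled snapshot.
#' @param lattice Lattice; defaults to the snapshot's attribute.
#' @return List with phenotype `fractions`, per-label `cluster_sizes`
#'   (including the pooled `non-E`), `mean_cluster_non_e`,
#'   `max_cluster_non_e`, `unlike_neighbour_fraction` and `mean_nicd`.
#' @export
pattern_summary <- function(snapshot, lattice = attr(snapshot, "lattice")) {
  cs <- lapply(stats::setNames(nm = c("E", "E/M", "M", "non-E")),
               function(l) cluster_components(snapshot, l, lattice))
  non_e <- cs[["non-E"]]
  list(fractions = phenotype_fractions(snapshot),
       cluster_sizes = cs,
       mean_cluster_non_e = if (length(non_e)) mean(non_e) else 0,
       max_cluster_non_e = if (length(non_e)) max(non_e) else 0,
       unlike_neighbour_fraction = unlike_neighbour_fraction(snapshot, lattice),
       mean_nicd = mean_nicd(snapshot))
}
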