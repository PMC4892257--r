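make_labelled_snapshot <- function(labels, lattice) {
  idx <- seq_len(lattice$n_cells)
  sn <- data.frame(cell = idx, row = (idx - 1) %/% lattice$cols,
                   col = (idx - 1) %% lattice$cols, time_h = 0,
                   I = seq_along(idx))
  sn$emt_label <- labels
  attr(sn, "lattice") <- lattice
  sn
}

test_that("phenotype fractions are normalised counts", {
  lat <- build_lattice(4, 4, "periodic")
  sn <- make_labelled_snapshot(rep("E", 16), lat)
  expect_equal(phenotype_fractions(sn), c(E = 1, `E/M` = 0, M = 0))
  for (seed in 1:5) {
    set.seed(seed)
    sn <- make_labelled_snapshot(sample(c("E", "E/M", "M"), 16, TRUE), lat)
    expect_equal(sum(phenotype_fractions(sn)), 1, tolerance = 1e-12)
  }
})

test_that("cluster components match hand-built cases", {
  lat <- build_lattice(6, 6, "periodic")
  labs <- rep("E", 36)
  labs[15] <- "M"
  sn <- make_labelled_snapshot(labs, lat)
  expect_equal(cluster_components(sn, "M"), 1L)
  # a cell plus its six neighbours form one 7-cluster
  labs <- rep("E", 36)
  labs[c(15, lat$nbrs[15, ])] <- "E/M"
  sn <- make_labelled_snapshot(labs, lat)
  expect_equal(cluster_components(sn, "E/M"), 7L)
  expect_error(cluster_components(sn, "X"), "unknown label")
})

test_that("cluster components agree with an independent flood fill", {
  lat <- build_lattice(10, 10, "periodic")
  lat_open <- build_lattice(10, 10, "open")
  for (seed in 1:10) {
    set.seed(seed)
    labs <- sample(c("E", "E/M", "M"), 100, TRUE, prob = c(.5, .3, .2))
    for (l in list(lat, lat_open)) {
      sn <- make_labelled_snapshot(labs, l)
      for (lab in c("E", "E/M", "M", "non-E")) {
        inset <- if (lab == "non-E") labs != "E" else labs == lab
        expect_equal(cluster_components(sn, lab, l), flood_fill_sizes(inset, l))
      }
    }
  }
})

test_that("cluster sizes partition the label counts", {
  lat <- build_lattice(8, 8, "periodic")
  set.seed(3)
  labs <- sample(c("E", "E/M", "M"), 64, TRUE)
  sn <- make_labelled_snapshot(labs, lat)
  for (lab in c("E", "E/M", "M")) {
    expect_equal(sum(cluster_components(sn, lab)), sum(labs == lab))
  }
  expect_equal(sum(cluster_components(sn, "non-E")), sum(labs != "E"))
})

test_that("unlike-neighbour fraction matches its definition and expectation", {
  lat <- build_lattice(8, 8, "periodic")
  sn <- make_labelled_snapshot(rep("E", 64), lat)
  expect_equal(unlike_neighbour_fraction(sn), 0)
  # two equal-probability labels: each pair is unlike with probability 1/2
  vals <- sapply(1:20, function(seed) {
    set.seed(seed)
    unlike_neighbour_fraction(make_labelled_snapshot(
      sample(c("E", "M"), 64, TRUE), lat))
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 0.5), 3 * se + 1e-12)
  # checkerboard-like alternating columns score the maximum
  labs <- ifelse((seq_len(64) - 1) %% 2 == 0, "E", "M")
  expect_gt(unlike_neighbour_fraction(make_labelled_snapshot(labs, lat)), 0.6)
})

test_that("mean NICD and its relative variant behave", {
  lat <- build_lattice(4, 4, "periodic")
  sn <- make_labelled_snapshot(rep("E", 16), lat)
  sn$I <- rep(42, 16)
  expect_equal(mean_nicd(sn), 42)
  expect_equal(mean_nicd(sn, reference = sn), 1)
  bad <- sn
  bad$I <- NULL
  expect_error(mean_nicd(sn, reference = bad), "reference")
})

test_that("pattern summary assembles consistent pieces", {
  lat <- build_lattice(6, 6, "periodic")
  set.seed(8)
  sn <- make_labelled_snapshot(sample(c("E", "E/M", "M"), 36, TRUE), lat)
  ps <- pattern_summary(sn)
  expect_equal(sum(ps$fractions), 1)
  expect_equal(sum(ps$cluster_sizes[["non-E"]]), sum(sn$emt_label != "E"))
  if (length(ps$cluster_sizes[["non-E"]])) {
    expect_equal(ps$max_cluster_non_e, max(ps$cluster_sizes[["non-E"]]))
  }
})
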