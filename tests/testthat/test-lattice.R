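test_that("periodic lattices have uniform degree six", {
  lat <- build_lattice(10, 12, "periodic")
  expect_true(all(rowSums(lat$nbrs > 0) == 6))
  lat50 <- build_lattice(50, 50, "periodic")
  expect_equal(lat50$n_cells, 2500)
  expect_true(all(rowSums(lat50$nbrs > 0) == 6))
})

test_that("open 3x3 corners match the hand-enumerated odd-r stencil", {
  lat <- build_lattice(3, 3, "open")
  deg <- rowSums(lat$nbrs > 0)
  # corners: (0,0)=2, (0,2)=3, (2,0)=2, (2,2)=3; centre (1,1)=6
  expect_equal(deg[1], 2)
  expect_equal(deg[3], 3)
  expect_equal(deg[7], 2)
  expect_equal(deg[9], 3)
  expect_equal(deg[5], 6)
  # explicit neighbour sets for two corners (1-based indices)
  nb <- lattice_neighbours(lat)
  expect_equal(nb[[1]], c(2L, 4L))          # (0,0): east, south-west
  expect_equal(nb[[3]], c(2L, 5L, 6L))      # (0,2)
})

test_that("the neighbour relation is symmetric", {
  for (lat in list(build_lattice(6, 7, "periodic"), build_lattice(5, 4, "open"))) {
    for (i in seq_len(lat$n_cells)) {
      for (j in lat$nbrs[i, ]) {
        if (j > 0) expect_true(i %in% lat$nbrs[j, ])
      }
    }
  }
})

test_that("invalid lattice configurations are rejected", {
  expect_error(build_lattice(1, 5), "at least")
  expect_error(build_lattice(5, 5, "periodic"), "even number of rows")
  expect_silent(build_lattice(5, 5, "open"))
})

test_that("random initial states are reproducible and within range", {
  p <- default_parameters(gD = 20, gJ = 70)
  lat <- build_lattice(6, 6, "periodic")
  a <- random_initial_states(lat, p, seed = 4)
  b <- random_initial_states(lat, p, seed = 4)
  expect_identical(a, b)
  rng <- default_state_ranges(p)
  for (k in seq_len(nrow(rng))) {
    expect_true(all(a[, k] >= rng[k, 1] & a[, k] <= rng[k, 2]))
  }
  z <- random_initial_states(lat, p, seed = 1, ranges = cbind(rep(0, 11), rep(0, 11)))
  expect_true(all(z == 0))
})

test_that("neighbour aggregation follows its definition", {
  p <- default_parameters()
  lat <- build_lattice(6, 6, "periodic")
  st <- matrix(rep(cell_state(N = 700, D = 120, J = 45), each = 36), 36, 11,
               dimnames = list(NULL, species_names()))
  e_sum <- neighbour_environment(lat, st, aggregation = "sum")
  e_mean <- neighbour_environment(lat, st, aggregation = "mean")
  expect_true(all(e_mean[, "D_ext"] == 120))
  expect_true(all(e_sum[, "D_ext"] == 6 * 120))
  expect_true(all(e_sum[, "N_ext"] == 6 * 700))
  e2 <- neighbour_environment(lat, st, sJ_ext = 4000, I_ext = 70)
  expect_true(all(e2[, "sJ_ext"] == 4000))
  expect_true(all(e2[, "I_ext"] == 70))
})
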