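test_that("a uniform tissue at its self-consistent state stays uniform and stationary", {
  p <- default_parameters(gD = 20, gJ = 70)
  lat <- build_lattice(6, 6, "periodic")
  # relax a uniform epithelial tissue to its collective fixed point
  st0 <- matrix(rep(neutral_fixed_point(neutral_params()) *
                      c(1, 0.01, 0.1, 0, 1, 0.1, 0.1, 1, 0.1, 0.1, 0),
                    each = lat$n_cells), lat$n_cells, 11,
                dimnames = list(NULL, species_names()))
  relax <- simulate_tissue(lat, st0, p, t_end = 1500, snapshot_times = 1500)
  s1 <- snapshot_states(relax[[1]])
  # uniformity is preserved
  expect_lt(max(apply(s1, 2, function(x) diff(range(x)))), 1e-6)
  # the common cell state solves the one-cell problem under the aggregated env
  env <- neighbour_environment(lat, s1, aggregation = "sum")
  expect_lt(steady_state_residual(s1[1, ], env[1, ], p), 1e-3)
  # and the tissue is stationary from here on
  more <- simulate_tissue(lat, s1, p, t_end = 50, snapshot_times = 50)
  s2 <- snapshot_states(more[[1]])
  expect_lt(max(abs(s2 - s1) / pmax(abs(s1), 1)), 1e-6)
})

test_that("synchronous update is invariant under cell relabelling", {
  p <- default_parameters(gD = 20, gJ = 70)
  lat <- build_lattice(4, 4, "periodic")
  st0 <- random_initial_states(lat, p, seed = 9)
  run <- simulate_tissue(lat, st0, p, t_end = 20, snapshot_times = 20)
  ref <- snapshot_states(run[[1]])
  set.seed(1)
  perm <- sample(lat$n_cells)
  lat_p <- lat
  inv <- order(perm)
  # relabel: cell i of the new lattice is cell perm[i] of the old one
  lat_p$nbrs <- matrix(inv[lat$nbrs[perm, ]], lat$n_cells, 6)
  run_p <- simulate_tissue(lat_p, st0[perm, ], p, t_end = 20, snapshot_times = 20)
  got <- snapshot_states(run_p[[1]])[inv, ]
  expect_identical(unname(got), unname(ref))
})

test_that("tissue simulation is deterministic and labels snapshots consistently", {
  p <- default_parameters(gD = 20, gJ = 70)
  th <- default_thresholds(p)
  lat <- build_lattice(4, 4, "periodic")
  st0 <- random_initial_states(lat, p, seed = 2)
  a <- simulate_tissue(lat, st0, p, t_end = 30, snapshot_times = c(10, 30))
  b <- simulate_tissue(lat, st0, p, t_end = 30, snapshot_times = c(10, 30))
  expect_identical(snapshot_states(a[[2]]), snapshot_states(b[[2]]))
  sn <- a[[2]]
  expect_equal(sn$emt_label, unname(classify_emt(snapshot_states(sn), th)))
  expect_equal(sn$sr_label, unname(classify_sr(snapshot_states(sn), th)))
})

test_that("snapshots round-trip through CSV with their metadata", {
  p <- default_parameters(gD = 20, gJ = 70)
  lat <- build_lattice(4, 4, "periodic")
  st0 <- random_initial_states(lat, p, seed = 3)
  run <- simulate_tissue(lat, st0, p, t_end = 10, snapshot_times = 10)
  f <- tempfile(fileext = ".csv")
  write_snapshot(run[[1]], f, I_ext = 70)
  back <- read_snapshot(f)
  expect_equal(snapshot_states(back), snapshot_states(run[[1]]),
               tolerance = 1e-12)
  expect_equal(attr(back, "lattice")$rows, 4)
  expect_equal(attr(back, "meta")$I_ext, "70")
  # a continued run can be seeded from the reloaded snapshot
  cont <- simulate_tissue(lat, snapshot_states(back), p, t_end = 5)
  expect_equal(nrow(cont[[1]]), lat$n_cells)
})

test_that("tissue input validation catches shape and time errors", {
  p <- default_parameters()
  lat <- build_lattice(4, 4, "periodic")
  st0 <- random_initial_states(lat, p, seed = 1)
  expect_error(simulate_tissue(lat, st0[-1, ], p, t_end = 10), "one row per")
  expect_error(simulate_tissue(lat, st0, p, t_end = 10, snapshot_times = 20),
               "within")
})
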