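test_that("a single-value sweep reproduces direct stable-state enumeration", {
  p <- default_parameters()
  env <- cell_environment(N_ext = 5000)
  sw <- sweep_parameter("J_ext", 600, env, p, n_starts = 24, seed = 1)
  direct <- find_stable_states(cell_environment(N_ext = 5000, J_ext = 600), p,
                               n_starts = 24, seed = 1)
  expect_equal(nrow(sw), nrow(direct))
  expect_equal(sort(sw$miR200), sort(direct$miR200), tolerance = 1e-9)
  expect_error(sweep_parameter("J_ext", c(10, 5), env, p), "sorted")
  expect_error(sweep_parameter("bogus", 1, env, p))
})

test_that("nullclines of the unregulated model cross at g/gamma", {
  p <- neutral_params()
  nc <- nullclines_nd(cell_environment(), p, n_grid = 15, t_relax = 300)
  expect_equal(nrow(nc$intersections), 1)
  expect_equal(nc$intersections$N, p$notch$gN / p$notch$gammaN,
               tolerance = 0.02)
  expect_equal(nc$intersections$D, p$notch$gD / p$notch$gammaD,
               tolerance = 0.02)
  expect_true(nc$intersections$stable[1])
})

test_that("nullcline fixed points at the reference setting include both stable states", {
  p <- default_parameters()
  env <- cell_environment(N_ext = 5000, J_ext = 600)
  nc <- nullclines_nd(env, p, n_grid = 25)
  stable <- nc$intersections[nc$intersections$stable, ]
  expect_gte(nrow(stable), 2)
  expect_gte(nrow(nc$intersections), 3)  # plus at least one saddle
  ss <- find_stable_states(env, p, n_starts = 24, seed = 1)
  for (i in seq_len(nrow(ss))) {
    d <- apply(stable[, species_names()], 1, function(x) {
      max(abs(x - unlist(ss[i, species_names()])) /
            pmax(abs(unlist(ss[i, species_names()])), 1))
    })
    expect_lt(min(d), 0.01)
  }
  # stable intersections are fixed points of the full system
  res <- steady_state_residual(as.matrix(stable[, species_names()]), env, p)
  expect_true(all(res < 1e-3))
})

test_that("the phase diagram is consistent with direct enumeration and seeding", {
  p <- default_parameters()
  th <- default_thresholds(p)
  env <- cell_environment(N_ext = 5000)
  # grid points chosen away from fold bifurcations, where the attractor
  # set is robust to the choice of random starts
  pd <- phase_diagram(c(0, 1500), c(0, 2600), env, p, n_starts = 24, seed = 1,
                      thresholds = th)
  expect_equal(nrow(pd), 4)
  # origin: purely epithelial labels
  origin <- pd$labels[pd$D_ext == 0 & pd$J_ext == 0]
  expect_true(grepl("^E,", origin) || grepl("\\|E,", origin))
  expect_false(grepl("M", origin))
  # oracle self-consistency at one grid point
  direct <- find_stable_states(cell_environment(N_ext = 5000, J_ext = 2600), p,
                               n_starts = 24, seed = 1)
  m <- as.matrix(direct[, species_names()])
  lab <- paste(sort(unique(paste(classify_emt(m, th), classify_sr(m, th),
                                 sep = ","))), collapse = "|")
  expect_equal(pd$labels[pd$D_ext == 0 & pd$J_ext == 2600], lab)
  # reseeding does not change the label sets
  pd2 <- phase_diagram(c(0, 1500), c(0, 2600), env, p, n_starts = 24, seed = 7,
                       thresholds = th)
  expect_equal(pd$labels, pd2$labels)
})
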