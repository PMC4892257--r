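test_that("R reference and compiled right-hand sides agree", {
  p <- default_parameters()
  cp <- notchemt:::params_to_cpp(p)
  for (seed in 1:5) {
    st <- random_state_matrix(8, p, seed)
    set.seed(seed + 100)
    env <- cbind(N_ext = runif(8, 0, 8000), D_ext = runif(8, 0, 4000),
                 J_ext = runif(8, 0, 4000), sD_ext = runif(8, 0, 2000),
                 sJ_ext = runif(8, 0, 2000), I_ext = runif(8, 0, 100))
    dR <- cell_derivatives(st, env, p)
    dC <- notchemt:::cpp_rhs(st, env, cp)
    expect_equal(unname(dR), unname(dC), tolerance = 1e-12)
  }
  # and with Fringe enabled
  pf <- default_parameters(fringe = list(enabled = TRUE))
  st <- random_state_matrix(4, pf, 1)
  st[, "F"] <- c(0, 100, 300, 1000)
  env <- notchemt:::as_env_matrix(cell_environment(N_ext = 5000, J_ext = 600))
  expect_equal(unname(cell_derivatives(st, env, pf)),
               unname(notchemt:::cpp_rhs(st, env, notchemt:::params_to_cpp(pf))),
               tolerance = 1e-12)
})

test_that("unregulated linear circuit has its birth-death fixed point", {
  p <- neutral_params()
  fp <- neutral_fixed_point(p)
  d <- cell_derivatives(fp, cell_environment(), p)
  expect_true(all(abs(d) < 1e-9))
})

test_that("without receptor there is no NICD production", {
  p <- default_parameters()
  st <- cell_state(N = 0, D = 500, J = 200, I = 40, miR34 = 1e4,
                   mS = 100, S = 5e4, miR200 = 2e4, mZ = 10, Z = 1e3)
  env <- cell_environment(N_ext = 5000, D_ext = 2000, J_ext = 2000,
                          sD_ext = 1000, sJ_ext = 1000)
  d <- cell_derivatives(st, env, p)
  expect_equal(unname(d["I"]), -p$notch$gammaI * 40)
})

test_that("empty species can only be produced (boundary non-negativity)", {
  p <- default_parameters()
  for (seed in 1:10) {
    st <- random_state_matrix(1, p, seed)
    k <- (seed %% 11) + 1
    st[1, k] <- 0
    set.seed(seed)
    env <- cell_environment(N_ext = runif(1, 0, 8000),
                            D_ext = runif(1, 0, 4000),
                            J_ext = runif(1, 0, 4000),
                            I_ext = runif(1, 0, 100))
    d <- cell_derivatives(st[1, ], env, p)
    expect_gte(d[k], 0)
  }
})

test_that("invalid states and environments are rejected", {
  p <- default_parameters()
  st <- cell_state(N = 100)
  expect_error(cell_derivatives(replace(st, 1, -5), cell_environment(), p))
  expect_error(cell_derivatives(replace(st, 3, NaN), cell_environment(), p))
  expect_error(cell_environment(N_ext = -1))
})

test_that("steady-state residual is scale-free and small at fixed points", {
  p <- neutral_params()
  fp <- neutral_fixed_point(p)
  expect_lt(steady_state_residual(fp, cell_environment(), p), 1e-9)
  expect_gt(steady_state_residual(0.5 * fp, cell_environment(), p), 0.1)
})
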