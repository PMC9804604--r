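midpoint_config <- function(...) {
  dynamics_config(alpha_range = c(0.975, 0.975),
                  beta_intra_range = c(1, 1),
                  beta_inter_range = c(0.23, 0.23),
                  gamma_range = c(0.2, 0.2),
                  ...)
}

test_that("parameter draws respect intervals, fixed handling time, sparsity", {
  m <- rbind(c(2, 0, 1), c(0, 3, 0))
  net <- make_net(m)
  cfg <- dynamics_config(seed = 4)
  draw <- sample_parameters(net, cfg, seed = 11)

  expect_identical(draw$h, 0.1)
  # mutualistic strengths are zero exactly where no visit was observed
  expect_identical(unname(draw$Gamma_P > 0), m > 0)
  expect_identical(unname(draw$Gamma_A > 0), t(m) > 0)
  expect_true(all(diag(draw$B_P) >= 0.99 & diag(draw$B_P) <= 1.01))
  off <- draw$B_A[row(draw$B_A) != col(draw$B_A)]
  expect_true(all(off >= 0.22 & off <= 0.24))
  # intraspecific competition dominates interspecific, bound-wise
  expect_true(min(diag(draw$B_P)) > max(off))
})

test_that("growth rates are uniform on [0.85, 1.1]", {
  net <- make_net(matrix(c(1, 1, 1, 1), 2, 2))
  alphas <- unlist(lapply(1:2500, function(s) {
    sample_parameters(net, dynamics_config(), seed = s)$alpha_P
  }))
  expect_gte(min(alphas), 0.85)
  expect_lte(max(alphas), 1.1)
  # uniform-distribution oracle: mean 0.975, MC error ~ 0.072/sqrt(n)
  expect_equal(mean(alphas), 0.975, tolerance = 5 * 0.0722 / sqrt(5000) / 0.975)
})

test_that("the RHS matches hand-evaluated special cases", {
  # single plant at its logistic equilibrium alpha/beta_ii
  lone <- make_net(matrix(1, 1, 1))
  draw <- sample_parameters(lone, midpoint_config(), seed = 1)
  draw$alpha_P <- 1; draw$B_P <- matrix(1, 1, 1); draw$Gamma_P <- matrix(0, 1, 1)
  expect_equal(dynamics_rhs(c(1, 0), draw)[1], 0)

  # extinction is absorbing: every term carries S_i
  state <- c(0, 0.7)
  expect_equal(dynamics_rhs(state, sample_parameters(lone, midpoint_config(),
                                                     seed = 2))[1], 0)

  # 1 plant - 1 pollinator at interval midpoints, S = (1, 1):
  # dS/dt = alpha*S - beta*S^2 + S * gamma*S' / (1 + h*gamma*S')
  pair <- sample_parameters(lone, midpoint_config(), seed = 3)
  want <- 0.975 * 1 - 1 * 1 + 1 * 0.2 / (1 + 0.1 * 0.2)
  got <- dynamics_rhs(c(1, 1), pair)
  expect_equal(got[1], want, tolerance = 1e-12)
  expect_equal(got[2], want, tolerance = 1e-12)

  expect_error(dynamics_rhs(c(1, 1, 1), pair), "state length")
})

test_that("integration reaches known fixed points", {
  lone <- make_net(matrix(1, 1, 1))
  cfg <- midpoint_config()

  # isolated plant: logistic fixed point alpha/beta_ii = 1
  draw <- sample_parameters(lone, cfg, seed = 1)
  draw$alpha_P <- 1; draw$B_P <- matrix(1, 1, 1)
  draw$Gamma_P <- matrix(0, 1, 1); draw$Gamma_A <- matrix(0, 1, 1)
  draw$alpha_A <- -0.1                 # decaying pollinator
  draw$S0_P <- 0.5; draw$S0_A <- 0.5
  traj <- integrate_dynamics(draw, cfg)
  expect_equal(traj$final_P, 1, tolerance = 1e-6)
  expect_true(traj$extinct_A)          # exponential decay below threshold
  expect_false(traj$extinct_P)

  # coupled pair at midpoints: equilibrium matches an independent
  # algebraic root-finder on the planar fixed-point equations
  pair <- sample_parameters(lone, cfg, seed = 5)
  pair$S0_P <- 0.8; pair$S0_A <- 0.6
  traj2 <- integrate_dynamics(pair, cfg)
  f <- function(s) {
    c(0.975 - s[1] + 0.2 * s[2] / (1 + 0.02 * s[2]),
      0.975 - s[2] + 0.2 * s[1] / (1 + 0.02 * s[1]))
  }
  root <- newton2d(f, c(1, 1))
  expect_equal(c(traj2$final_P, traj2$final_A), root, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(traj2$settled)
})

test_that("without mutualism and interspecific competition every species is logistic", {
  set.seed(31)
  net <- make_net(random_count_matrix(5, 5))
  cfg <- dynamics_config(gamma_range = c(0, 0), beta_inter_range = c(0, 0),
                         seed = 9)
  draw <- sample_parameters(net, cfg, seed = 42)
  draw$S0_P[] <- pmax(draw$S0_P, 0.05)   # keep clear of the absorbing state
  draw$S0_A[] <- pmax(draw$S0_A, 0.05)
  traj <- integrate_dynamics(draw, cfg)
  want <- c(draw$alpha_P / diag(draw$B_P), draw$alpha_A / diag(draw$B_A))
  got <- c(traj$final_P, traj$final_A)
  expect_lt(max(abs(got - want) / want), 1e-6)
})

test_that("species started at zero stay extinct in every run", {
  net <- make_net(rbind(c(2, 1), c(0, 3)))
  cfg <- midpoint_config(n_runs = 5, seed = 2)
  for (r in 1:5) {
    draw <- sample_parameters(net, cfg, seed = r)
    draw$S0_P[1] <- 0
    traj <- integrate_dynamics(draw, cfg)
    expect_identical(traj$final_P[1], 0)
  }
})

test_that("mutualism raises pollinator persistence and abundance", {
  m <- matrix(5, 5, 5)                  # fully connected 5 x 5
  net <- make_net(m)
  cfg_hi <- dynamics_config(gamma_range = c(0.19, 0.21), n_runs = 200, seed = 8)
  cfg_lo <- dynamics_config(gamma_range = c(0.0, 0.02), n_runs = 200, seed = 8)
  hi <- run_persistence(net, cfg_hi)
  lo <- run_persistence(net, cfg_lo)
  expect_gte(hi$network$persistence_pollinators,
             lo$network$persistence_pollinators)
  # the benefit is strictly visible in equilibrium abundance
  d_hi <- sample_parameters(net, cfg_hi, seed = 77)
  d_lo <- d_hi
  d_lo$Gamma_P[] <- 0.01 * (m > 0); d_lo$Gamma_A[] <- 0.01 * (t(m) > 0)
  a_hi <- sum(integrate_dynamics(d_hi, cfg_hi)$final_A)
  a_lo <- sum(integrate_dynamics(d_lo, cfg_lo)$final_A)
  expect_gt(a_hi, a_lo)
})

test_that("persistence runs are deterministic and internally consistent", {
  set.seed(12)
  net <- make_net(random_count_matrix(4, 6), site = "S9", period = "2013-01")
  cfg <- dynamics_config(n_runs = 10, seed = 21)
  r1 <- run_persistence(net, cfg)
  r2 <- run_persistence(net, cfg)
  expect_identical(r1$species, r2$species)
  expect_identical(r1$network, r2$network)

  sp <- r1$species
  expect_true(all(sp$persistence >= 0 & sp$persistence <= 1))
  expect_equal(r1$network$persistence_all, mean(sp$persistence))
  expect_equal(r1$network$persistence_plants,
               mean(sp$persistence[sp$guild == "plant"]))
  expect_equal(r1$network$persistence_pollinators,
               mean(sp$persistence[sp$guild == "pollinator"]))

  # single favourable run: a lone plant always persists
  lone <- make_net(matrix(1, 1, 1))
  cfg1 <- dynamics_config(n_runs = 1, gamma_range = c(0.2, 0.2), seed = 3)
  r <- run_persistence(lone, cfg1)
  expect_equal(r$species$persistence, c(1, 1))
  expect_equal(r$network$persistence_all, 1)
})

test_that("a stored configuration file reproduces dynamics_config()", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("alpha_range: [0.9, 1.0]", "n_runs: 25", "seed: 7",
               "handling_time: 0.2"), f)
  cfg <- read_dynamics_config(f)
  expect_equal(cfg$alpha_range, c(0.9, 1.0))
  expect_equal(cfg$n_runs, 25L)
  expect_identical(cfg$handling_time, 0.2)
  # overrides win over file values; unknown fields are rejected
  expect_equal(read_dynamics_config(f, n_runs = 5)$n_runs, 5L)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"alpha_rnge": [0.9, 1.0]}', bad)
  expect_error(read_dynamics_config(bad), "unknown config field")
})
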