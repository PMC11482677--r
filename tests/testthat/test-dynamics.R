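gain_from_derivs <- function(net, p, N, u) {
  # mutualistic expectation extracted from the density derivative at N = 1
  d <- growth_and_selection(N, u, net, p)
  d$dN / N - p$b + as.vector(p$alpha %*% pmax(N, 0))
}

test_that("quadrature reproduces the closed-form Gaussian expectation at H = 0", {
  net <- pair_net()
  set.seed(4)
  for (i in 1:20) {
    u <- runif(2, -0.5, 0.5)
    s <- runif(2, 0.003, 0.03)
    g0 <- runif(1, 0.5, 5)
    p <- sample_params(net, gamma0 = g0, sigma = s, H = 0, alpha = diag(2))
    gain <- gain_from_derivs(net, p, c(1, 1), u)
    expect_equal(gain[1],
                 pair_interaction_strength(u[1], u[2], s[1], s[2], g0, 0.35, 1),
                 tolerance = 1e-9)
  }
})

test_that("kernel limits behave as expected", {
  # matched traits, vanishing variance, degree 1 -> gamma0
  expect_equal(pair_interaction_strength(0, 0, 1e-9, 1e-9, 1.7, 0.35, 1), 1.7)
  # wide trait separation -> vanishing interaction
  expect_lt(pair_interaction_strength(0, 3, 0.02, 0.02, 1.7, 0.35, 1), 1e-10)
})

test_that("obligate mutualists decay without mutualism", {
  net <- tri_net()
  p <- sample_params(net, gamma0 = 0, seed = 1)
  set.seed(2)
  d <- growth_and_selection(runif(6, 0.5, 2), runif(6, -0.5, 0.5), net, p)
  expect_true(all(d$dN <= 0))
})

test_that("matched traits produce no selection gradient", {
  net <- tri_net()
  p <- sample_params(net, gamma0 = 2, seed = 1)
  d <- growth_and_selection(rep(1, 6), rep(0.3, 6), net, p)
  expect_equal(d$du, rep(0, 6), tolerance = 1e-14)
})

test_that("two-species equilibrium matches the type-II fixed point", {
  net <- pair_net()
  p <- pair_params(gamma0 = 1.5)
  traj <- simulate_community(net, p, N0 = c(1, 1), u0 = c(0, 0), t_end = 1000)
  Nend <- traj$N[traj$time == 1000]
  expect_equal(Nend, rep(4 * (1.5 - 1) / 1.5, 2), tolerance = 0.01)
})

test_that("zero heritability freezes mean traits along a trajectory", {
  net <- tri_net()
  p <- sample_params(net, gamma0 = 2, h2 = 0, seed = 1)
  set.seed(3)
  u0 <- runif(6, -0.5, 0.5)
  traj <- simulate_community(net, p, N0 = rep(1, 6), u0 = u0, t_end = 100)
  final_u <- traj$u[traj$time == 100]
  expect_equal(final_u, u0, tolerance = 1e-10)
})

test_that("degree trade-off leaves summed gain invariant under partner replication", {
  # one plant with k identical animal partners receives the same per-capita
  # mutualistic input as with a single such partner (exact at H = 0, where
  # no saturation term re-introduces a degree dependence)
  u_all <- 0.1
  gains <- vapply(c(1, 3, 6), function(k) {
    net <- star_net(k)
    S <- k + 1
    p <- sample_params(net, gamma0 = 2, sigma = 0.02, H = 0, alpha = diag(S))
    gain_from_derivs(net, p, rep(1, S), rep(u_all, S))[1]
  }, numeric(1))
  expect_equal(gains[2], gains[1], tolerance = 1e-12)
  expect_equal(gains[3], gains[1], tolerance = 1e-12)
})

test_that("densities stay non-negative and forcing with zero strength is inert", {
  net <- kernel_fixture()
  S <- n_species(net)
  p <- sample_params(net, gamma0 = 0.8, sigma = "low", seed = 6)
  set.seed(7)
  N0 <- runif(S, 0, 0.005)
  u0 <- runif(S, -0.5, 0.5)
  base <- simulate_community(net, p, N0, u0, t_end = 200)
  expect_true(all(base$N >= 0))
  forced <- simulate_community(net, p, N0, u0, t_end = 200,
                               forcing = forcing_spec(1L, 0, 100))
  expect_equal(forced$N, base$N, tolerance = 1e-12)
})

test_that("quasi-equilibrium traits respect the no-gradient and adaptation limits", {
  net <- tri_net()
  p <- sample_params(net, seed = 1)
  # identical initial traits (zero draw range): no selection, traits returned
  u <- quasi_equilibrium_traits(net, p, seed = 1, u_range = 0)
  expect_equal(u, rep(0, 6), tolerance = 1e-10)

  # mismatched pair converges under selection (h2 = 0.4)
  netp <- pair_net()
  pp <- sample_params(netp, gamma0 = 4, sigma = 0.02, alpha = diag(2))
  traj <- simulate_community(netp, pp, N0 = c(1, 1), u0 = c(-0.2, 0.2),
                             t_end = 500)
  gap <- abs(traj$u[traj$time == 500][1] - traj$u[traj$time == 500][2])
  expect_lt(gap, 0.4)
})

test_that("mean-field approximation tracks the full quadrature at small variance", {
  net <- kernel_fixture()
  S <- n_species(net)
  p <- sample_params(net, gamma0 = 2, sigma = "low", seed = 9)
  pmf <- p
  pmf$mean_field <- TRUE
  set.seed(10)
  N <- runif(S, 0.5, 2)
  u <- runif(S, -0.3, 0.3)
  d1 <- growth_and_selection(N, u, net, p)
  d2 <- growth_and_selection(N, u, net, pmf)
  expect_equal(d2$dN, d1$dN, tolerance = 1e-3)
})

test_that("model configurations round-trip through JSON", {
  net <- tri_net()
  p <- sample_params(net, gamma0 = 1.3, sigma = "high", seed = 12)
  f <- forcing_spec(2L, 0.5, 500)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_config(p, path, forcing = f)
  back <- read_model_config(path)
  expect_equal(back$params$alpha, unname(p$alpha), tolerance = 1e-12)
  expect_equal(back$params$gamma0, p$gamma0)
  expect_equal(back$params$sigma, p$sigma)
  expect_equal(back$forcing$species, f$species)
  expect_equal(back$forcing$mode, "multiplicative")
  # restored params drive the dynamics identically
  d1 <- growth_and_selection(rep(1, 6), rep(0.1, 6), net, p)
  d2 <- growth_and_selection(rep(1, 6), rep(0.1, 6), net, back$params)
  expect_equal(d2$dN, d1$dN, tolerance = 1e-12)
})

test_that("asymmetric gamma kernel is weaker than the Gaussian at matched traits", {
  net <- pair_net()
  pg <- sample_params(net, gamma0 = 1.2, sigma = 0.02, alpha = diag(2))
  pa <- sample_params(net, gamma0 = 1.2, sigma = 0.02, alpha = diag(2),
                      kernel = "asymmetric_gamma")
  gg <- gain_from_derivs(net, pg, c(1, 1), c(0, 0))
  ga <- gain_from_derivs(net, pa, c(1, 1), c(0, 0))
  expect_lt(ga[1], gg[1])
  expect_gt(ga[1], 0)
})
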