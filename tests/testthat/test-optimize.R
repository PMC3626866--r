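test_that("the modified capacity bound substitutes quantiles for SSU", {
  expect_equal(capacity_bound(3, 8, 1, 0, 0), 3)
  expect_equal(capacity_bound(3, 8, 1, 1, 0), 8)
  expect_equal(capacity_bound(3, 8, 1, 0, 1), 1)
  expect_error(capacity_bound(3, 8, 1, 1, 1), "both")
})

test_that("intervention sets enforce exclusivity and canonical order", {
  iv <- intervention_set(c("B", "A"), "C")
  expect_identical(iv$up, c("A", "B"))
  expect_error(intervention_set("A", "A"), "both")
  expect_identical(format(intervention_set("B", character(0))),
                   "up:{B} down:{}")
})

test_that("with no interventions allowed CCOpt reduces to wild-type FBA", {
  fx <- tl3()
  r <- ccopt_solve(fx$model, fx$ref, fx$caps,
                   optimization_settings(eps = 0.5, L = 0))
  expect_equal(r$status, "optimal")
  expect_length(r$interventions$up, 0)
  expect_length(r$interventions$down, 0)
  expect_equal(r$v_target, 5)  # bottleneck bound
})

test_that("CCOpt relieves the planted bottleneck at the quantile level", {
  fx <- tl3()
  s <- optimization_settings(eps = 0.5, L = 1, alpha = 0.01)
  r <- ccopt_solve(fx$model, fx$ref, fx$caps, s)
  expect_identical(r$interventions$up, "R2")
  expect_equal(r$v_target, 30)   # median up-capacity 6*5 hits the chain cap
  expect_equal(r$objective, 30 - 0.01, tolerance = 1e-9)
  r0 <- ccopt_solve(fx$model, fx$ref, fx$caps,
                    optimization_settings(eps = 0, L = 1, alpha = 0.01))
  expect_equal(r0$v_target, 10)  # worst-case up-capacity 2*5
  # solution satisfies mass balance and the penalized-objective identity
  expect_lt(max(abs(fx$model$S %*% r$fluxes)), 1e-6)
  expect_equal(r$objective,
               r$v_target - r$alpha * (length(r$interventions$up) +
                                       length(r$interventions$down)),
               tolerance = 1e-9)
})

test_that("DetOpt is the zero-confidence special case of CCOpt", {
  fixtures <- list(tl3(), make_branched_fixture(2),
                   make_random_fixture(3), make_random_fixture(8))
  for (fx in fixtures) {
    for (L in 0:2) {
      s <- optimization_settings(eps = 0.3, L = L)
      det <- detopt_solve(fx$model, fx$ref, fx$caps, s)
      s$eps <- 0
      cc0 <- ccopt_solve(fx$model, fx$ref, fx$caps, s)
      expect_equal(det$objective, cc0$objective, tolerance = 1e-9)
    }
  }
})

test_that("an up-regulation whose worst case sits below SSU is never chosen", {
  fx <- tl3()
  # worst case 2 * vmax = 10 with SSU lifted above it: the up-capacity can
  # only lower the bound at eps = 0, so DetOpt must leave R2 alone
  fx$ref$SSU["R2"] <- 12
  det <- detopt_solve(fx$model, fx$ref, fx$caps,
                      optimization_settings(L = 1, alpha = 0.01))
  expect_length(det$interventions$up, 0)
  expect_equal(det$v_target, 12)
})

test_that("optimal target flux is monotone in L and in eps", {
  fixtures <- list(tl3(), make_branched_fixture(2), make_random_fixture(5))
  for (fx in fixtures) {
    prev <- -Inf
    for (L in 0:4) {
      r <- ccopt_solve(fx$model, fx$ref, fx$caps,
                       optimization_settings(eps = 0.25, L = L, alpha = 0))
      expect_gte(r$v_target, prev - 1e-9)
      prev <- r$v_target
    }
    prev <- -Inf
    for (eps in seq(0, 0.5, 0.1)) {
      r <- ccopt_solve(fx$model, fx$ref, fx$caps,
                       optimization_settings(eps = eps, L = 2, alpha = 0))
      expect_gte(r$v_target, prev - 1e-9)
      prev <- r$v_target
    }
  }
})

test_that("the MILP matches exhaustive enumeration on random fixtures", {
  for (seed in 1:8) {
    fx <- make_random_fixture(seed)
    for (eps in c(0, 0.25)) for (L in 1:2) {
      s <- optimization_settings(eps = eps, L = L)
      cc <- ccopt_solve(fx$model, fx$ref, fx$caps, s)
      bf <- brute_force_optimum(fx, eps, L, s)
      expect_equal(cc$objective, bf$objective, tolerance = 1e-6,
                   label = sprintf("seed %d eps %.2f L %d", seed, eps, L))
    }
  }
})

test_that("an unattainable biomass requirement returns infeasible status", {
  fx <- tl3()
  m <- fx$model
  m$biomass_id <- "R3"
  ref <- fx$ref
  ref$vbiomass_max <- 30
  ref$SSU["R1"] <- 0.1   # uptake cannot support 1% of 30
  r <- ccopt_solve(m, ref, fx$caps,
                   optimization_settings(eps = 0.5, L = 1,
                                         biomass_fraction = 0.5))
  expect_identical(r$status, "infeasible")
})

test_that("a missing capacity distribution for an eligible reaction errors", {
  fx <- tl3()
  expect_error(
    ccopt_solve(fx$model, fx$ref, fx$caps,
                optimization_settings(eps = 0.5, L = 1,
                                      eligible_reactions = c("R1", "R2"))),
    "lack capacity")
})

test_that("MCOpt with point-mass capacities collapses to one solution", {
  fx <- tl3()
  pt_up <- kinetic_capacity("R2", 5, fold_change_distribution("up", 6, 1e-13))
  pt_dn <- kinetic_capacity("R2", 5, fold_change_distribution("down", 0.5, 1e-13))
  caps <- structure(list(up = list(R2 = pt_up), down = list(R2 = pt_dn)),
                    class = "capacity_set")
  run <- mcopt_run(fx$model, fx$ref, caps,
                   optimization_settings(L = 1, alpha = 0.01),
                   n_samples = 20, seed = 5)
  expect_length(run$frequencies, 1)
  expect_equal(unname(run$frequencies), 1)
  expect_equal(unique(round(run$v_target, 9)), 30)
})

test_that("MCOpt on the bottleneck chain always picks the bottleneck", {
  fx <- tl3()
  run <- mcopt_run(fx$model, fx$ref, fx$caps,
                   optimization_settings(L = 1, alpha = 0.01),
                   n_samples = 200, seed = 11)
  expect_equal(unname(run$frequencies["up:{R2} down:{}"]), 1)
  expect_equal(sum(run$frequencies), 1, tolerance = 1e-12)
  # reproducible under the master seed
  run2 <- mcopt_run(fx$model, fx$ref, fx$caps,
                    optimization_settings(L = 1, alpha = 0.01),
                    n_samples = 200, seed = 11)
  expect_identical(run$v_target, run2$v_target)
})
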