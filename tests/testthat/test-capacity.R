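test_that("fold-change defaults encode the up/down regulation model", {
  up <- fold_change_distribution("up")
  expect_equal(up$mu, 6)
  expect_equal(up$delta, 8)
  expect_equal(up$sigma, 8 / 6)
  expect_equal(c(up$lower, up$upper), c(2, 10))
  dn <- fold_change_distribution("down")
  expect_equal(dn$mu, 0.5)
  expect_equal(c(dn$lower, dn$upper), c(0, 1))
  # worst case of an up-regulation must stay above the unmodified level
  expect_error(fold_change_distribution("up", mu = 2, delta = 8), "above 1")
  expect_error(fold_change_distribution("down", mu = 0.2, delta = 1), "below 0")
})

test_that("kinetic capacities scale the fold-change distribution by vmax", {
  up <- kinetic_capacity("R", 100, fold_change_distribution("up"))
  expect_equal(up$location, 600)
  expect_equal(c(up$lower, up$upper), c(200, 1000))
  dn <- kinetic_capacity("R", 100, fold_change_distribution("down"))
  expect_equal(dn$location, 50)
  expect_equal(c(dn$lower, dn$upper), c(0, 100))
  expect_error(kinetic_capacity("R", 0, up), "positive")
  # degenerate spread collapses to a point mass at vmax * mu
  pt <- kinetic_capacity("R", 10, fold_change_distribution("up", 6, 1e-14))
  expect_equal(quantile(pt, c(0, 0.5, 1)), rep(60, 3))
})

test_that("parametric quantiles match numeric CDF inversion", {
  d <- capacity_parametric("R", "up", location = 6, scale = 8 / 6,
                           lower = 2, upper = 10)
  expect_equal(quantile(d, 0.5), 6)   # symmetric support around the location
  expect_equal(quantile(d, 0), 2)
  expect_equal(quantile(d, 1), 10)
  probs <- c(0.01, 0.1, 0.25, 0.75, 0.9, 0.99)
  oracle <- numeric_truncnorm_quantile(probs, 6, 8 / 6, 2, 10)
  expect_equal(quantile(d, probs), oracle, tolerance = 1e-6)
  expect_error(quantile(d, -0.1), "\\[0, 1\\]")
  expect_error(quantile(d, 1.1), "\\[0, 1\\]")
})

test_that("empirical quantiles interpolate order statistics with pinned ends", {
  d <- capacity_empirical("R", "up", c(2, 4, 6, 8, 10), min_sample = 5)
  expect_equal(quantile(d, 0), 2)
  expect_equal(quantile(d, 1), 10)
  expect_equal(quantile(d, 0.5), 6)
  expect_equal(quantile(d, 0.125), 3)  # halfway between the first two
  expect_error(capacity_empirical("R", "up", 1:10), "at least 100")
  expect_error(capacity_empirical("R", "up", c(-1, rep(1, 200))), "negative")
})

test_that("quantile is nondecreasing and spans the support", {
  probs <- seq(0, 1, 0.01)
  d1 <- capacity_parametric("R", "up", 600, 400 / 3, 200, 1000)
  q1 <- quantile(d1, probs)
  expect_true(all(diff(q1) >= 0))
  expect_equal(range(q1), c(200, 1000))
  set.seed(5)
  d2 <- capacity_empirical("R", "down", runif(500, 0, 50), min_sample = 100)
  q2 <- quantile(d2, probs)
  expect_true(all(diff(q2) >= 0))
  expect_equal(range(q2), range(d2$values))
})

test_that("capacity construction commutes with flux rescaling", {
  fc <- fold_change_distribution("up")
  probs <- seq(0, 1, 0.05)
  a <- quantile(kinetic_capacity("R", 7, fc), probs)
  b <- quantile(kinetic_capacity("R", 21, fc), probs)
  expect_equal(b, 3 * a, tolerance = 1e-10)
})

test_that("sampling is seeded, reproducible and moment-faithful", {
  d <- kinetic_capacity("R", 5, fold_change_distribution("up"))
  expect_identical(sample_capacity(d, 100, seed = 11),
                   sample_capacity(d, 100, seed = 11))
  pt <- kinetic_capacity("R", 5, fold_change_distribution("up", 6, 1e-14))
  expect_equal(sample_capacity(pt, 10, seed = 1), rep(30, 10))
  x <- sample_capacity(d, 1e5, seed = 3)
  mu <- truncnorm_mean(30, 5 * 8 / 6, 10, 50)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mu), 3 * se)
  # empirical CDF of draws vs analytic CDF, uniform deviation below 0.01
  grid <- seq(10, 50, length.out = 200)
  pa <- pnorm((10 - 30) / (20 / 3)); pb <- pnorm((50 - 30) / (20 / 3))
  analytic <- (pnorm((grid - 30) / (20 / 3)) - pa) / (pb - pa)
  expect_lt(max(abs(ecdf(x)(grid) - analytic)), 0.01)
  # empirical representation resamples its own values
  de <- capacity_empirical("R", "up", c(2, 4, 6, 8, 10), min_sample = 5)
  expect_true(all(sample_capacity(de, 50, seed = 2) %in% de$values))
})

test_that("reference-state estimation recovers chain and branch geometry", {
  fx <- tl3()
  model <- fx$model
  vmax <- setNames(c(10, 10, 10), model$reactions)
  # a measured uptake pins every flux in a chain
  ref <- estimate_reference_state(model, vmax, measured = c(R1 = 10))
  expect_equal(unname(ref$SSU), c(10, 10, 10))
  expect_equal(unname(ref$SSL), c(10, 10, 10))
  # without measurements the range is [0, bottleneck]
  ref0 <- estimate_reference_state(model, vmax)
  expect_equal(unname(ref0$SSL), c(0, 0, 0))
  expect_equal(unname(ref0$SSU), c(10, 10, 10))
  expect_true(all(ref0$SSL <= ref0$SSU))
  # inconsistent measurement is reported, not silently dropped
  expect_error(estimate_reference_state(model, vmax, measured = c(R1 = 99)),
               "LP|incompatible")
})

test_that("reference-state bounds agree with polytope vertex enumeration", {
  # one uptake feeding two competing exports with unequal caps
  S <- matrix(0, 1, 3, dimnames = list("A", c("Up", "B1", "B2")))
  S["A", ] <- c(1, -1, -1)
  model <- metabolic_model(S, target_id = "B1")
  vmax <- c(Up = 10, B1 = 6, B2 = 8)
  ref <- estimate_reference_state(model, vmax, measured = c(Up = 10))
  verts <- enumerate_polytope_vertices(S, lb = rep(0, 3), ub = unname(vmax[colnames(S)]),
                                       fixed = list(Up = 10))
  expect_equal(unname(ref$SSU), unname(apply(verts, 2, max)), tolerance = 1e-8)
  expect_equal(unname(ref$SSL), unname(apply(verts, 2, min)), tolerance = 1e-8)
})

test_that("biomass maximum is the wild-type theoretical optimum", {
  S <- matrix(0, 1, 3, dimnames = list("A", c("Up", "Bio", "Exp")))
  S["A", ] <- c(1, -1, -1)
  model <- metabolic_model(S, target_id = "Exp", biomass_id = "Bio")
  vmax <- c(Up = 10, Bio = 6, Exp = 8)
  # measurement caps the observed state but not the theoretical maximum
  ref <- estimate_reference_state(model, vmax, measured = c(Bio = 1))
  expect_equal(ref$vbiomass_max, 6)
})

test_that("vmax completion propagates known caps and flags the rest", {
  fx <- tl3()
  out <- complete_vmax(fx$model, c(R1 = 10))
  expect_equal(unname(out$vmax), c(10, 10, 10))
  expect_identical(unname(out$provenance),
                   c("given", "completed", "completed"))
  # branched: each missing cap is the tightest LP bound through the knowns
  S <- matrix(0, 1, 3, dimnames = list("A", c("Up", "B1", "B2")))
  S["A", ] <- c(1, -1, -1)
  model <- metabolic_model(S, target_id = "B1")
  out2 <- complete_vmax(model, c(Up = 10, B1 = 4))
  expect_equal(unname(out2$vmax["B2"]), 10)
})

test_that("vmax completion reports unreachable fluxes as unbounded", {
  # X produces B which R4 exports; nothing bounds that branch
  S <- matrix(0, 2, 4, dimnames = list(c("A", "B"), c("R1", "R2", "X", "R4")))
  S["A", "R1"] <- 1; S["A", "R2"] <- -1
  S["B", "X"] <- 1; S["B", "R4"] <- -1
  model <- metabolic_model(S, target_id = "R2")
  expect_error(complete_vmax(model, c(R1 = 10)), "unbounded.*X|X.*unbounded")
})
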