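chain_model <- function() {
  S <- matrix(c(1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(c("A", "B"), c("R1", "R2", "R3")))
  metabolic_model(S, target_id = "R3")
}

test_that("a linear chain has exactly one elementary mode", {
  ems <- enumerate_ems(chain_model())
  expect_equal(ncol(ems$modes), 1)
  expect_equal(unname(ems$modes[, 1]), c(1, 1, 1))
})

test_that("a branch point yields one mode per pathway", {
  S <- matrix(0, 1, 3, dimnames = list("A", c("R1", "R2", "R3")))
  S["A", ] <- c(1, -1, -1)
  m <- metabolic_model(S, target_id = "R2")
  ems <- enumerate_ems(m)
  expect_equal(ncol(ems$modes), 2)
  expect_setequal(lapply(ems$supports, sort),
                  list(c("R1", "R2"), c("R1", "R3")))
})

test_that("futile split-pair cycles are excluded", {
  m <- split_reversible(chain_model() |> (\(x) {
    x$reversible[2] <- TRUE; x
  })())
  ems <- enumerate_ems(m)
  for (s in ems$supports)
    expect_false(setequal(s, c("R2", "R2_b")))
  expect_equal(ncol(ems$modes), 1)
  expect_equal(unname(ems$modes[c("R1", "R2", "R3"), 1]), c(1, 1, 1))
})

test_that("enumerated modes satisfy the defining properties", {
  set.seed(7)
  fixtures <- c(lapply(1:6, make_random_fixture),
                list(make_branched_fixture(2), make_branched_fixture(3)))
  for (fx in fixtures) {
    m <- fx$model
    if (length(m$reactions) > 10) next
    ems <- enumerate_ems(m)
    K <- ncol(ems$modes)
    for (k in seq_len(K)) {
      e <- ems$modes[, k]
      expect_lt(max(abs(m$S %*% e)), 1e-9)
      expect_true(all(e >= 0))
      expect_equal(max(e), 1)
    }
    # support minimality across the set
    if (K > 1) {
      for (i in seq_len(K)) for (j in seq_len(K)) {
        if (i == j) next
        expect_false(all(ems$supports[[i]] %in% ems$supports[[j]]) &&
                     length(ems$supports[[i]]) < length(ems$supports[[j]]))
      }
    }
  }
})

test_that("mode sets equal brute-force support-minimal enumeration", {
  skip_if_not_installed("MASS")
  models <- list(chain_model(),
                 make_branched_fixture(2)$model,
                 split_reversible(chain_model() |> (\(x) {
                   x$reversible[2] <- TRUE; x
                 })()))
  for (m in models) {
    ems <- enumerate_ems(m)
    oracle <- brute_force_ems(m)
    expect_equal(ncol(ems$modes), length(oracle$supports))
    expect_setequal(lapply(ems$supports, sort),
                    lapply(oracle$supports, sort))
  }
})

test_that("the reference EMC polytope answers flux queries", {
  m <- chain_model()
  ems <- enumerate_ems(m)
  ref <- reference_state(setNames(rep(30, 3), m$reactions),
                         setNames(rep(0, 3), m$reactions),
                         measured = c(R1 = 10))
  poly <- reference_emc_polytope(ems, ref)
  # one mode, one measurement: lambda pinned to 10
  expect_equal(ecf_adjusted_max_flux(ems, poly, "R2", 1, "R2"), 10)

  # two competing branches, measured uptake only: 1-D feasible segment
  S <- matrix(0, 1, 3, dimnames = list("A", c("Up", "B1", "B2")))
  S["A", ] <- c(1, -1, -1)
  m2 <- metabolic_model(S, target_id = "B1")
  ems2 <- enumerate_ems(m2)
  ref2 <- reference_state(c(Up = 10, B1 = 6, B2 = 8), c(Up = 0, B1 = 0, B2 = 0),
                          measured = c(Up = 10))
  poly2 <- reference_emc_polytope(ems2, ref2)
  # analytically: v_B1 in [2, 6] once Up = 10, B2 <= 8
  expect_equal(ecf_adjusted_max_flux(ems2, poly2, "B1", 1, "B1"), 6)
  expect_equal(ecf_adjusted_max_flux(ems2, poly2, "B2", 1, "B2"), 8)

  # measurements violating the bounds are an infeasibility error
  ref_bad <- reference_state(setNames(rep(30, 3), m$reactions),
                             setNames(rep(0, 3), m$reactions))
  ref_bad$measured <- c(R1 = 50)   # above SSU, bypassing constructor check
  expect_error(reference_emc_polytope(ems, ref_bad), "inconsistent")
})

test_that("the power-law adjustment rescales affected modes only", {
  m <- chain_model()
  ems <- enumerate_ems(m)
  ref <- reference_state(setNames(rep(30, 3), m$reactions),
                         setNames(rep(0, 3), m$reactions),
                         measured = c(R1 = 10))
  poly <- reference_emc_polytope(ems, ref)
  # single-mode chain: maximal flux scales linearly with the fold-change
  for (a in c(0.5, 1, 2, 3))
    expect_equal(ecf_adjusted_max_flux(ems, poly, "R2", a, "R2"), 10 * a)
  # exponent h enters as a power
  expect_equal(ecf_adjusted_max_flux(ems, poly, "R2", 2, "R2", h = 2), 40)
  expect_error(ecf_adjusted_max_flux(ems, poly, "R2", 2, "R2", h = 0),
               "positive")
  expect_error(ecf_adjusted_max_flux(ems, poly, "R2", -1, "R2"), "positive")

  # two-branch fixture: doubling one branch's enzyme doubles only the mode
  # through it, and the unmodified reference constraints still cap lambda
  S <- matrix(0, 1, 3, dimnames = list("A", c("Up", "B1", "B2")))
  S["A", ] <- c(1, -1, -1)
  m2 <- metabolic_model(S, target_id = "B1")
  ems2 <- enumerate_ems(m2)
  ref2 <- reference_state(c(Up = 10, B1 = 6, B2 = 8), c(Up = 0, B1 = 0, B2 = 0),
                          measured = c(Up = 10))
  poly2 <- reference_emc_polytope(ems2, ref2)
  # hand LP: max 2 * lambda_B1 with lambda_B1 <= 6, lambda_B1 + lambda_B2 = 10
  expect_equal(ecf_adjusted_max_flux(ems2, poly2, "B1", 2, "B1"), 12)
  # monotone in the fold-change when querying the modified reaction
  vals <- sapply(c(0.5, 1, 1.5, 2, 4),
                 function(a) ecf_adjusted_max_flux(ems2, poly2, "B1", a, "B1"))
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("ECF capacity distributions compose sampling with the flux map", {
  m <- chain_model()
  ems <- enumerate_ems(m)
  ref <- reference_state(setNames(rep(30, 3), m$reactions),
                         setNames(rep(0, 3), m$reactions),
                         measured = c(R1 = 10))
  poly <- reference_emc_polytope(ems, ref)
  # point mass at 1 concentrates on the unmodified maximal flux
  pt <- fold_change_distribution("down", mu = 1, delta = 1e-13)
  cap_pt <- ecf_capacity_distribution(ems, poly, "R2", pt, n = 100, seed = 9)
  expect_equal(unique(round(cap_pt$values, 9)), 10)
  # single-mode chain: capacity sample = reference flux x fold-change sample
  fc <- fold_change_distribution("up")
  cap <- ecf_capacity_distribution(ems, poly, "R2", fc, n = 150, seed = 4)
  draws <- sample_fold_change(fc, 150, seed = 4)
  expect_equal(sort(cap$values), sort(10 * draws), tolerance = 1e-9)
  # reproducible under the same seed
  cap2 <- ecf_capacity_distribution(ems, poly, "R2", fc, n = 150, seed = 4)
  expect_identical(cap$values, cap2$values)
})
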