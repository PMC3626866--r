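# Synthetic test networks with planted capacity bottlenecks, and an
# enumeration oracle for the MILP. The fixtures are algebraic test objects,
# not biology: their value is that the optimal intervention set and flux are
# computable by exhaustive search, independently of the branch-and-bound.

new_fixture <- function(model, ref, caps, seed = NULL) {
  structure(list(model = model, ref = ref, caps = caps, seed = seed),
            class = "strainopt_fixture")
}

#' @export
print.strainopt_fixture <- function(x, ...) {
  cat("strainopt_fixture: ")
  print(x$model)
  invisible(x)
}

#' Linear-chain fixture with one planted bottleneck
#'
#' Builds an uptake -> conversions -> export chain of `k` irreversible
#' reactions `R1..Rk` over `k - 1` internal metabolites. Every reaction has
#' an unmodified upper bound of 30 except the bottleneck, whose bound (and
#' `v_max`) is 5, making it the unique binding constraint of the wild type.
#' Up/down capacity distributions (default fold-change parameters scaled by
#' `v_max = SSU`) are attached to the interior reactions. The export `Rk` is
#' the target. The construction is deterministic given its arguments; `seed`
#' is echoed into the fixture for provenance but draws nothing.
#'
#' `make_linear_fixture(3)` is the three-reaction chain used throughout the
#' package's tests: bounds (30, 5, 30), capacities on `R2` only.
#'
#' @param k chain length, at least 3.
#' @param bottleneck_position index of the bottleneck reaction, an interior
#'   position (`2 .. k-1`).
#' @param seed echoed into the fixture.
#' @return a fixture: list with `model`, `ref`, `caps`, `seed`.
#' @export
make_linear_fixture <- function(k = 3, bottleneck_position = 2, seed = 1) {
  if (k < 3) stop("k must be at least 3")
  if (bottleneck_position < 2 || bottleneck_position > k - 1)
    stop("bottleneck_position must be interior (2 .. k-1)")
  rxns <- paste0("R", seq_len(k))
  mets <- paste0("M", seq_len(k - 1))
  S <- matrix(0, k - 1, k, dimnames = list(mets, rxns))
  for (i in seq_len(k - 1)) S[i, i] <- 1       # Ri produces Mi
  for (i in seq_len(k - 1)) S[i, i + 1] <- -1  # R(i+1) consumes Mi
  SSU <- stats::setNames(rep(30, k), rxns)
  SSU[bottleneck_position] <- 5
  model <- metabolic_model(S, mets, rxns, rep(FALSE, k), target_id = rxns[k],
                           vmax = SSU)
  ref <- reference_state(SSU, stats::setNames(rep(0, k), rxns))
  interior <- rxns[2:(k - 1)]
  caps <- kinetic_capacity_set(SSU[interior])
  new_fixture(model, ref, caps, seed)
}

#' Branched fixture with a serial two-step target branch
#'
#' One uptake feeds `branches` competing pathways to distinct exports. The
#' target branch runs through two reactions in series (`T1`: hub -> B, `T2`:
#' B -> P), both bounded at 5 and both carrying capacity distributions, so a
#' single intervention provably cannot raise the target flux — up-regulating
#' either serial reaction merely shifts the limiting capacity to the other.
#' The remaining `branches - 1` pathways are single wide reactions draining
#' the hub. Deterministic given its arguments; `seed` is echoed only.
#'
#' @param branches number of competing pathways, at least 2.
#' @param seed echoed into the fixture.
#' @return a fixture: list with `model`, `ref`, `caps`, `seed`.
#' @export
make_branched_fixture <- function(branches = 2, seed = 1) {
  if (branches < 2) stop("branches must be at least 2")
  alt <- if (branches > 1) paste0("Alt", seq_len(branches - 1)) else character(0)
  rxns <- c("Up", "T1", "T2", "Exp", alt)
  mets <- c("A", "B", "P")
  S <- matrix(0, 3, length(rxns), dimnames = list(mets, rxns))
  S["A", "Up"] <- 1
  S["A", "T1"] <- -1; S["B", "T1"] <- 1
  S["B", "T2"] <- -1; S["P", "T2"] <- 1
  S["P", "Exp"] <- -1
  for (a in alt) S["A", a] <- -1
  SSU <- stats::setNames(rep(30, length(rxns)), rxns)
  SSU[c("T1", "T2")] <- 5
  model <- metabolic_model(S, mets, rxns, rep(FALSE, length(rxns)),
                           target_id = "Exp", vmax = SSU)
  ref <- reference_state(SSU, stats::setNames(rep(0, length(rxns)), rxns))
  caps <- kinetic_capacity_set(SSU[c("T1", "T2")])
  new_fixture(model, ref, caps, seed)
}

#' Random small fixture for property testing
#'
#' Draws a random chain (length 3 to 5) with integer bounds, optionally one
#' reversible interior reaction (split on construction, exercising the
#' split-pair exclusivity constraints), up to two extra drain branches
#' competing for the uptake, optionally a positive lower bound on the
#' uptake, and optionally a biomass designation on a drain branch. Capacity
#' distributions (default fold-change parameters, `v_max = SSU`) are
#' attached to a random subset of at most six reactions. Fully determined by
#' `seed`.
#'
#' @param seed integer seed.
#' @return a fixture: list with `model`, `ref`, `caps`, `seed`.
#' @export
make_random_fixture <- function(seed = 1) {
  set.seed(seed)
  k <- sample(3:5, 1)
  rxns <- paste0("R", seq_len(k))
  mets <- paste0("M", seq_len(k - 1))
  S <- matrix(0, k - 1, k, dimnames = list(mets, rxns))
  for (i in seq_len(k - 1)) { S[i, i] <- 1; S[i, i + 1] <- -1 }
  rev <- rep(FALSE, k)
  if (k >= 4 && stats::runif(1) < 0.4) rev[sample(2:(k - 1), 1)] <- TRUE
  SSU <- stats::setNames(sample(4:40, k, replace = TRUE), rxns)

  n_drains <- sample(0:2, 1)
  drains <- character(0)
  if (n_drains > 0) {
    for (d in seq_len(n_drains)) {
      id <- paste0("D", d)
      src <- sample(seq_len(k - 1), 1)
      col <- numeric(k - 1); col[src] <- -1
      S <- cbind(S, col)
      colnames(S)[ncol(S)] <- id
      drains <- c(drains, id)
    }
    rxns <- colnames(S)
    rev <- c(rev, rep(FALSE, n_drains))
    SSU[drains] <- sample(2:20, n_drains, replace = TRUE)
  }
  biomass <- if (length(drains) && stats::runif(1) < 0.3) drains[1] else NULL
  model <- metabolic_model(S, mets, rxns, rev, target_id = paste0("R", k),
                           biomass_id = biomass, vmax = SSU)
  model <- split_reversible(model)
  all_rxns <- model$reactions
  SSU_full <- stats::setNames(numeric(length(all_rxns)), all_rxns)
  SSU_full[names(SSU)] <- SSU
  bwd <- setdiff(all_rxns, names(SSU))
  SSU_full[bwd] <- SSU[names(model$split_pairs)[match(bwd, model$split_pairs)]]
  SSL <- stats::setNames(rep(0, length(all_rxns)), all_rxns)
  if (stats::runif(1) < 0.5)
    SSL["R1"] <- round(stats::runif(1, 0, min(2, SSU_full["R1"])), 2)
  vbmax <- if (!is.null(biomass)) unname(SSU_full[biomass]) else NULL
  ref <- reference_state(SSU_full, SSL, vbiomass_max = vbmax)
  n_cap <- min(length(all_rxns), sample(2:6, 1))
  cap_rxns <- sort(sample(all_rxns, n_cap))
  caps <- kinetic_capacity_set(SSU_full[cap_rxns])
  new_fixture(model, ref, caps, seed)
}

#' Exhaustive-search optimum for small fixtures
#'
#' Independent oracle for the chance-constrained MILP: enumerates every
#' valid intervention set of size at most `L` over the eligible reactions
#' (respecting up/down exclusivity and the split-pair constraints), fixes
#' the flux bounds through [capacity_bound()] with capacity quantiles at
#' `eps`, solves the resulting FBA LP for each set, and returns the best
#' penalized objective. Shares no code with the branch-and-bound beyond the
#' LP backend.
#'
#' @param fixture a fixture (list with `model`, `ref`, `caps`).
#' @param eps confidence parameter.
#' @param L maximum interventions (at most 3).
#' @param settings optional [optimization_settings()]; `eps` and `L`
#'   arguments override its fields.
#' @return list with `interventions`, `v_target`, `objective`.
#' @export
brute_force_optimum <- function(fixture, eps, L,
                                settings = optimization_settings()) {
  settings$eps <- eps
  settings$L <- as.integer(L)
  model <- fixture$model; ref <- fixture$ref; caps <- fixture$caps
  elig <- resolve_eligibility(model, caps, settings)
  cand <- rbind(
    if (length(elig$up)) data.frame(rxn = elig$up, dir = "up"),
    if (length(elig$down)) data.frame(rxn = elig$down, dir = "down"))
  n_cand <- if (is.null(cand)) 0L else nrow(cand)
  if (length(unique(cand$rxn)) > 12 || L > 3)
    stop("oracle guard: at most 12 eligible reactions and L <= 3")
  q <- eligible_quantiles(caps, elig, eps)
  alpha <- resolve_alpha(model, ref, settings)
  rxns <- model$reactions
  SSU <- unname(ref$SSU[rxns]); SSL <- unname(ref$SSL[rxns])
  obj <- as.numeric(rxns == model$target_id)
  A_ge <- NULL; b_ge <- NULL
  if (!is.null(model$biomass_id) && !is.null(ref$vbiomass_max) &&
      settings$biomass_fraction > 0 && ref$vbiomass_max > 0) {
    A_ge <- matrix(as.numeric(rxns == model$biomass_id), 1)
    b_ge <- settings$biomass_fraction * ref$vbiomass_max
  }

  valid_set <- function(idx) {
    if (!length(idx)) return(TRUE)
    sub <- cand[idx, , drop = FALSE]
    if (anyDuplicated(sub$rxn)) return(FALSE)      # up xor down per reaction
    for (f in names(model$split_pairs)) {
      b <- model$split_pairs[[f]]
      for (d in c("up", "down")) {
        pick <- sub$rxn[sub$dir == d]
        if (f %in% pick && b %in% pick) return(FALSE)
      }
    }
    TRUE
  }

  best <- list(objective = -Inf, interventions = NULL, v_target = NA_real_)
  subsets <- list(integer(0))
  if (n_cand > 0)
    for (size in seq_len(min(L, n_cand)))
      subsets <- c(subsets,
                   utils::combn(n_cand, size, simplify = FALSE))
  for (idx in subsets) {
    if (!valid_set(idx)) next
    sub <- cand[idx, , drop = FALSE]
    ub <- SSU; lb <- SSL
    for (r in seq_len(nrow(sub))) {
      j <- match(sub$rxn[r], rxns)
      if (sub$dir[r] == "up") {
        ub[j] <- capacity_bound(SSU[j], q$qu[[sub$rxn[r]]], 0, 1, 0)
      } else {
        qd <- min(q$qd[[sub$rxn[r]]], SSU[j])
        ub[j] <- capacity_bound(SSU[j], 0, qd, 0, 1)
        lb[j] <- 0
      }
    }
    ans <- fba_lp(model$S, obj, upper = ub, lower = lb, maximize = TRUE,
                  A_ge = A_ge, b_ge = b_ge)
    if (ans$status != "optimal") next
    val <- ans$objective - alpha * length(idx)
    if (val > best$objective + 1e-12) {
      best <- list(objective = val,
                   interventions = intervention_set(
                     sub$rxn[sub$dir == "up"], sub$rxn[sub$dir == "down"]),
                   v_target = ans$objective)
    }
  }
  if (is.null(best$interventions))
    stop("oracle found no feasible intervention set (wild type infeasible)")
  best
}

#' Serialize a fixture to a directory
#'
#' Writes `model.json` (canonical schema), `refstate.tsv`
#' (`reaction_id`, `SSL`, `SSU`) and `capacities.tsv` (`reaction_id`,
#' `direction`, `kind`, parameter columns) so a failing case can be replayed
#' from files.
#'
#' @param fixture a fixture.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(fixture$model, file.path(dir, "model.json"))
  write_reference_state(fixture$ref, file.path(dir, "refstate.tsv"))
  write_capacity_set(fixture$caps, file.path(dir, "capacities.tsv"))
  invisible(dir)
}
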