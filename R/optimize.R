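# CCOpt / DetOpt / MCOpt: mixed-integer strain optimization.
#
# The chance constraint  Prob(v_j <= Cap_j) >= 1 - eps  on a random capacity
# is converted to its deterministic equivalent through the eps-quantile of
# the capacity distribution, leaving a MILP in the flux vector v and the
# binary up/down-regulation decisions y. The MILP is solved by depth-first
# branch-and-bound over the binaries, with LP relaxations solved by the
# package's simplex backend.

#' Optimization settings
#'
#' @param eps confidence parameter in `[0, 1]`: each capacity constraint must
#'   hold with probability at least `1 - eps`. `eps = 0` is the deterministic
#'   worst case.
#' @param L maximum number of interventions (up- plus down-regulations).
#' @param alpha per-intervention penalty subtracted from the objective, flux
#'   units. Default (`NULL`) resolves at solve time to `1e-4` times the
#'   wild-type target optimum (or 1 if that optimum is 0); it must stay small
#'   enough that `alpha * L` is below the smallest flux improvement of
#'   interest.
#' @param biomass_fraction minimal biomass flux as a fraction of the
#'   wild-type theoretical maximum (default 0.01); ignored when the model has
#'   no biomass reaction.
#' @param eligible_reactions optional character vector restricting which
#'   reactions may carry intervention variables; default: every reaction with
#'   a supplied capacity distribution.
#' @param allow_down_target,allow_down_biomass whether the target / biomass
#'   reactions may be down-regulated (default `FALSE`).
#' @return an object of class `optimization_settings`.
#' @export
optimization_settings <- function(eps = 0.1, L = 1, alpha = NULL,
                                  biomass_fraction = 0.01,
                                  eligible_reactions = NULL,
                                  allow_down_target = FALSE,
                                  allow_down_biomass = FALSE) {
  if (eps < 0 || eps > 1) stop("eps must lie in [0, 1]")
  if (L < 0 || L != round(L)) stop("L must be a nonnegative integer")
  if (!is.null(alpha) && alpha < 0) stop("alpha must be nonnegative")
  if (biomass_fraction < 0 || biomass_fraction > 1)
    stop("biomass_fraction must lie in [0, 1]")
  structure(list(eps = eps, L = as.integer(L), alpha = alpha,
                 biomass_fraction = biomass_fraction,
                 eligible_reactions = eligible_reactions,
                 allow_down_target = allow_down_target,
                 allow_down_biomass = allow_down_biomass),
            class = "optimization_settings")
}

#' An intervention set
#'
#' The binary decisions of a strain design: reactions to up-regulate and
#' reactions to down-regulate. The two sets must be disjoint.
#'
#' @param up,down character vectors of reaction ids.
#' @return an object of class `intervention_set`.
#' @export
intervention_set <- function(up = character(0), down = character(0)) {
  up <- sort(unique(as.character(up)))
  down <- sort(unique(as.character(down)))
  if (length(intersect(up, down)))
    stop("a reaction cannot be both up- and down-regulated: ",
         paste(intersect(up, down), collapse = ", "))
  structure(list(up = up, down = down), class = "intervention_set")
}

#' @export
format.intervention_set <- function(x, ...) {
  paste0("up:{", paste(x$up, collapse = ","), "} down:{",
         paste(x$down, collapse = ","), "}")
}

#' @export
print.intervention_set <- function(x, ...) {
  cat("intervention_set ", format(x), "\n", sep = "")
  invisible(x)
}

intervention_key <- function(x) format(x)

n_interventions <- function(x) length(x$up) + length(x$down)

#' Modified flux-capacity upper bound
#'
#' The deterministic-equivalent upper bound on a reaction flux given its
#' intervention state: the unmodified bound `SSU_j`, replaced by the up- or
#' down-capacity quantile when the corresponding binary is set. At most one
#' of `y_u`, `y_d` may be 1.
#'
#' @param SSU_j unmodified upper bound, flux units.
#' @param q_u,q_d eps-quantiles of the up/down capacity distributions.
#' @param y_u,y_d binary intervention indicators.
#' @return the effective upper bound, flux units.
#' @export
capacity_bound <- function(SSU_j, q_u, q_d, y_u, y_d) {
  if (y_u + y_d > 1) stop("a reaction cannot be both up- and down-regulated")
  SSU_j + y_u * (q_u - SSU_j) + y_d * (q_d - SSU_j)
}

# Resolve eligibility: which reactions carry y^u / y^d variables.
resolve_eligibility <- function(model, caps, settings) {
  up <- names(caps$up)
  down <- names(caps$down)
  if (!is.null(settings$eligible_reactions)) {
    missing_caps <- setdiff(settings$eligible_reactions, union(up, down))
    if (length(missing_caps))
      stop("eligible reaction(s) lack capacity distributions: ",
           paste(missing_caps, collapse = ", "))
    up <- intersect(up, settings$eligible_reactions)
    down <- intersect(down, settings$eligible_reactions)
  }
  bad <- setdiff(union(up, down), model$reactions)
  if (length(bad))
    stop("capacity distributions refer to unknown reaction(s): ",
         paste(bad, collapse = ", "))
  if (!settings$allow_down_target && !is.null(model$target_id))
    down <- setdiff(down, model$target_id)
  if (!settings$allow_down_biomass && !is.null(model$biomass_id))
    down <- setdiff(down, model$biomass_id)
  list(up = sort(up), down = sort(down))
}

# Assemble the MILP matrices once; branching only changes y bounds.
build_milp <- function(model, ref, settings, qu, qd, alpha) {
  rxns <- model$reactions
  M <- length(rxns)
  Eu <- names(qu); Ed <- names(qd)
  nu <- length(Eu); nd <- length(Ed)
  nv <- M + nu + nd
  iu <- if (nu) stats::setNames(M + seq_len(nu), Eu) else integer(0)
  id <- if (nd) stats::setNames(M + nu + seq_len(nd), Ed) else integer(0)

  SSU <- unname(ref$SSU[rxns]); SSL <- unname(ref$SSL[rxns])
  # down-quantiles capped at SSU: a down-regulation must not raise the bound
  qd_eff <- pmin(unname(qd), SSU[match(Ed, rxns)])

  obj <- numeric(nv)
  obj[match(model$target_id, rxns)] <- 1
  obj[c(iu, id)] <- -alpha

  A_eq <- cbind(model$S, matrix(0, nrow(model$S), nu + nd))

  # capacity rows: v_j - (q_u - SSU_j) y_u - (q_d - SSU_j) y_d <= SSU_j
  A_cap <- matrix(0, M, nv)
  A_cap[cbind(seq_len(M), seq_len(M))] <- 1
  for (k in seq_along(Eu)) {
    j <- match(Eu[k], rxns)
    A_cap[j, iu[k]] <- -(unname(qu)[k] - SSU[j])
  }
  for (k in seq_along(Ed)) {
    j <- match(Ed[k], rxns)
    A_cap[j, id[k]] <- -(qd_eff[k] - SSU[j])
  }
  b_cap <- SSU

  # lower rows: v_j + SSL_j y_d >= SSL_j (plain v_j >= SSL_j if not down-eligible)
  lb_rows <- which(SSL > 1e-12)
  A_lb <- matrix(0, length(lb_rows), nv)
  b_lb <- SSL[lb_rows]
  for (r in seq_along(lb_rows)) {
    j <- lb_rows[r]
    A_lb[r, j] <- 1
    if (rxns[j] %in% Ed) A_lb[r, id[[rxns[j]]]] <- SSL[j]
  }

  A_ge <- A_lb; b_ge <- b_lb
  if (!is.null(model$biomass_id) && !is.null(ref$vbiomass_max) &&
      settings$biomass_fraction > 0 && ref$vbiomass_max > 0) {
    row <- numeric(nv); row[match(model$biomass_id, rxns)] <- 1
    A_ge <- rbind(A_ge, row)
    b_ge <- c(b_ge, settings$biomass_fraction * ref$vbiomass_max)
  }

  A_le <- A_cap; b_le <- b_cap
  if (nu + nd > 0) {
    card <- numeric(nv); card[c(iu, id)] <- 1
    A_le <- rbind(A_le, card); b_le <- c(b_le, settings$L)
    for (r in intersect(Eu, Ed)) {      # exclusivity per reaction
      row <- numeric(nv); row[iu[[r]]] <- 1; row[id[[r]]] <- 1
      A_le <- rbind(A_le, row); b_le <- c(b_le, 1)
    }
    for (f in names(model$split_pairs)) { # split-pair exclusivity
      b <- model$split_pairs[[f]]
      if (f %in% Eu && b %in% Eu) {
        row <- numeric(nv); row[iu[[f]]] <- 1; row[iu[[b]]] <- 1
        A_le <- rbind(A_le, row); b_le <- c(b_le, 1)
      }
      if (f %in% Ed && b %in% Ed) {
        row <- numeric(nv); row[id[[f]]] <- 1; row[id[[b]]] <- 1
        A_le <- rbind(A_le, row); b_le <- c(b_le, 1)
      }
    }
  }

  list(obj = obj, A_eq = A_eq, b_eq = rep(0, nrow(A_eq)),
       A_le = A_le, b_le = b_le, A_ge = A_ge, b_ge = b_ge,
       nv = nv, M = M, iu = iu, id = id, rxns = rxns,
       qu = qu, qd_eff = stats::setNames(qd_eff, Ed), SSU = SSU, SSL = SSL)
}

milp_relaxation <- function(prob, ylb, yub) {
  yi <- c(prob$iu, prob$id)
  A_le <- prob$A_le; b_le <- prob$b_le
  A_ge <- prob$A_ge; b_ge <- prob$b_ge
  if (length(yi)) {
    ub_rows <- matrix(0, length(yi), prob$nv)
    ub_rows[cbind(seq_along(yi), yi)] <- 1
    A_le <- rbind(A_le, ub_rows); b_le <- c(b_le, yub)
    fixed1 <- which(ylb > 0)
    if (length(fixed1)) {
      lb_rows <- matrix(0, length(fixed1), prob$nv)
      lb_rows[cbind(seq_along(fixed1), yi[fixed1])] <- 1
      A_ge <- rbind(A_ge, lb_rows); b_ge <- c(b_ge, ylb[fixed1])
    }
  }
  lp_solve(prob$obj, A_eq = prob$A_eq, b_eq = prob$b_eq,
           A_le = A_le, b_le = b_le, A_ge = A_ge, b_ge = b_ge,
           maximize = TRUE)
}

.INT_TOL <- 1e-6

solve_milp <- function(prob, node_cap = 50000L) {
  yi <- c(prob$iu, prob$id)
  ny <- length(yi)
  best <- list(objective = -Inf, x = NULL)
  nodes <- 0L
  recurse <- function(ylb, yub) {
    nodes <<- nodes + 1L
    if (nodes > node_cap) stop("branch-and-bound node cap exceeded")
    rel <- milp_relaxation(prob, ylb, yub)
    if (rel$status != "optimal") return(invisible(NULL))
    if (rel$objective <= best$objective + 1e-9) return(invisible(NULL))
    yv <- if (ny) rel$x[yi] else numeric(0)
    frac <- if (ny) pmin(yv - floor(yv), ceiling(yv) - yv) else numeric(0)
    cand <- which(frac > .INT_TOL)
    if (!length(cand)) {
      best <<- list(objective = rel$objective, x = rel$x)
      return(invisible(NULL))
    }
    i <- cand[which.max(frac[cand])]
    up1 <- ylb; up1[i] <- 1
    recurse(up1, yub)                       # y_i = 1 branch first
    dn0 <- yub; dn0[i] <- 0
    recurse(ylb, dn0)
    invisible(NULL)
  }
  recurse(rep(0, ny), rep(1, ny))
  if (is.null(best$x)) return(list(status = "infeasible"))
  list(status = "optimal", objective = best$objective, x = best$x)
}

wildtype_optimum <- function(model, ref, settings) {
  rxns <- model$reactions
  obj <- as.numeric(rxns == model$target_id)
  A_ge <- NULL; b_ge <- NULL
  if (!is.null(model$biomass_id) && !is.null(ref$vbiomass_max) &&
      settings$biomass_fraction > 0 && ref$vbiomass_max > 0) {
    A_ge <- matrix(as.numeric(rxns == model$biomass_id), 1)
    b_ge <- settings$biomass_fraction * ref$vbiomass_max
  }
  fba_lp(model$S, obj, upper = unname(ref$SSU[rxns]),
         lower = unname(ref$SSL[rxns]), maximize = TRUE,
         A_ge = A_ge, b_ge = b_ge)
}

resolve_alpha <- function(model, ref, settings) {
  if (!is.null(settings$alpha)) return(settings$alpha)
  wt <- wildtype_optimum(model, ref, settings)
  base <- if (wt$status == "optimal" && wt$objective > 0) wt$objective else 1
  1e-4 * base
}

# quantiles (or sampled values) for the eligible reactions, named vectors
eligible_quantiles <- function(caps, elig, eps) {
  qu <- vapply(elig$up, function(r) quantile(caps$up[[r]], eps), 0)
  qd <- vapply(elig$down, function(r) quantile(caps$down[[r]], eps), 0)
  list(qu = qu, qd = qd)
}

finish_result <- function(model, ref, settings, prob, milp, alpha, eps) {
  if (milp$status != "optimal") {
    return(structure(list(interventions = NULL, v_target = NA_real_,
                          fluxes = NULL, objective = NA_real_,
                          status = "infeasible", settings = settings,
                          eps = eps, alpha = alpha),
                     class = "optimization_result"))
  }
  x <- milp$x
  yu <- round(x[prob$iu]); yd <- round(x[prob$id])
  iv <- intervention_set(names(prob$iu)[yu > 0.5], names(prob$id)[yd > 0.5])
  if (n_interventions(iv) > settings$L)
    stop("internal error: intervention count exceeds L after rounding")
  v <- stats::setNames(x[seq_len(prob$M)], prob$rxns)
  # verify the rounded binaries against all active bounds
  ub_check <- prob$SSU
  for (r in iv$up) ub_check[match(r, prob$rxns)] <- prob$qu[[r]]
  for (r in iv$down) ub_check[match(r, prob$rxns)] <- prob$qd_eff[[r]]
  lb_check <- prob$SSL
  lb_check[match(iv$down, prob$rxns)] <- 0
  if (any(v > ub_check + 1e-6) || any(v < lb_check - 1e-6))
    stop("internal error: solution violates bounds after binary rounding")
  v_target <- unname(v[model$target_id])
  structure(list(interventions = iv, v_target = v_target, fluxes = v,
                 objective = v_target - alpha * n_interventions(iv),
                 status = "optimal", settings = settings, eps = eps,
                 alpha = alpha),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("optimization_result [", x$status, "]\n", sep = "")
  if (x$status == "optimal") {
    cat("  interventions: ", format(x$interventions), "\n",
        "  v_target = ", format(x$v_target), ", objective = ",
        format(x$objective), "\n", sep = "")
  }
  invisible(x)
}

#' Chance-constrained strain optimization (CCOpt)
#'
#' Selects up to `L` reaction up-/down-regulations maximizing the target flux
#' minus a small per-intervention penalty, subject to steady-state mass
#' balance, a minimal-biomass viability constraint, and flux-capacity upper
#' bounds that must hold with probability at least `1 - eps`. Each chance
#' constraint is replaced by its deterministic equivalent through the
#' `eps`-quantile of the reaction's capacity distribution; the resulting MILP
#' is solved to global optimality by branch-and-bound. Down-regulation
#' quantiles exceeding the unmodified bound `SSU_j` are capped at `SSU_j`
#' (a down-regulation never raises a capacity).
#'
#' @param model a split [metabolic_model()] with a target reaction.
#' @param ref a [reference_state()] consistent with the model.
#' @param caps a capacity set (named lists `up` and `down` of
#'   [capacity_distribution][capacity_parametric] objects), e.g. from
#'   [kinetic_capacity_set()].
#' @param settings an [optimization_settings()].
#' @return an object of class `optimization_result`: fields `interventions`,
#'   `v_target`, `fluxes`, `objective`, `status`, plus the settings echo.
#' @export
ccopt_solve <- function(model, ref, caps, settings = optimization_settings()) {
  if (any(model$reversible))
    stop("model must be split into irreversible reactions first")
  if (is.null(model$target_id)) stop("model has no target reaction")
  if (!all(model$reactions %in% names(ref$SSU)))
    stop("reference state does not cover all model reactions")
  elig <- resolve_eligibility(model, caps, settings)
  q <- eligible_quantiles(caps, elig, settings$eps)
  alpha <- resolve_alpha(model, ref, settings)
  prob <- build_milp(model, ref, settings, q$qu, q$qd, alpha)
  milp <- solve_milp(prob)
  finish_result(model, ref, settings, prob, milp, alpha, settings$eps)
}

#' Deterministic worst-case strain optimization (DetOpt)
#'
#' The `eps = 0` special case of [ccopt_solve()]: every flux must stay below
#' the *smallest* value its capacity distribution can take, i.e. the
#' capacity quantile at probability 0 (the support minimum for parametric
#' distributions, the sample minimum for empirical ones).
#'
#' @inheritParams ccopt_solve
#' @return an `optimization_result`.
#' @export
detopt_solve <- function(model, ref, caps, settings = optimization_settings()) {
  settings$eps <- 0
  ccopt_solve(model, ref, caps, settings)
}

#' Monte-Carlo strain optimization (MCOpt)
#'
#' Emulates the chance-constrained problem by sampling: for each iteration a
#' capacity value is drawn independently for every eligible reaction and
#' direction, the deterministic MILP is solved with the drawn capacities in
#' place of the quantiles, and the chosen intervention set and optimal target
#' flux are recorded. One master seed spawns one RNG substream per sample;
#' within a sample, draws are ordered by reaction id (up before down), so
#' results do not depend on iteration order.
#'
#' @inheritParams ccopt_solve
#' @param n_samples number of sampling + optimization iterations.
#' @param seed master integer seed.
#' @return list with `results` (per-sample list of `sample` — the drawn
#'   capacities — and `result`), `frequencies` (named fractions per canonical
#'   intervention set, infeasible samples under `"<infeasible>"`, summing
#'   to 1), and `v_target` (vector of per-sample optima, `NA` when
#'   infeasible).
#' @export
mcopt_run <- function(model, ref, caps, settings = optimization_settings(),
                      n_samples = 100, seed = 1) {
  if (n_samples < 1) stop("n_samples must be at least 1")
  elig <- resolve_eligibility(model, caps, settings)
  alpha <- resolve_alpha(model, ref, settings)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_samples)
  rxn_order <- sort(union(elig$up, elig$down))
  results <- vector("list", n_samples)
  keys <- character(n_samples)
  v_targets <- rep(NA_real_, n_samples)
  for (s in seq_len(n_samples)) {
    set.seed(sub_seeds[s])
    Xu <- stats::setNames(numeric(0), character(0))
    Xd <- stats::setNames(numeric(0), character(0))
    for (r in rxn_order) {
      if (r %in% elig$up) Xu[r] <- sample_capacity(caps$up[[r]], 1)
      if (r %in% elig$down) Xd[r] <- sample_capacity(caps$down[[r]], 1)
    }
    prob <- build_milp(model, ref, settings, Xu, Xd, alpha)
    res <- finish_result(model, ref, settings, prob, solve_milp(prob),
                         alpha, NA_real_)
    results[[s]] <- list(sample = list(up = Xu, down = Xd), result = res)
    keys[s] <- if (res$status == "optimal") intervention_key(res$interventions)
               else "<infeasible>"
    if (res$status == "optimal") v_targets[s] <- res$v_target
  }
  freq <- table(keys) / n_samples
  list(results = results,
       frequencies = sort(stats::setNames(as.numeric(freq), names(freq)),
                          decreasing = TRUE),
       v_target = v_targets)
}
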