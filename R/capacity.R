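#' Enzyme fold-change distribution
#'
#' Models the uncertain outcome of a gene expression modification as a
#' normal fold-change distribution truncated to `[mu - delta/2, mu + delta/2]`
#' with `sigma = delta/6`. Defaults follow over-expression data from
#' mammalian cells: up-regulation `mu = 6`, `delta = 8` (so the worst case
#' `mu - delta/2 = 2` still exceeds 1, i.e. an up-regulated enzyme never ends
#' up below its unmodified level); down-regulation `mu = 0.5`, `delta = 1`
#' (support `[0, 1]`).
#'
#' @param direction `"up"` or `"down"`.
#' @param mu mean fold-change (dimensionless).
#' @param delta spread, defined as six standard deviations.
#' @return an object of class `fold_change_distribution` with fields `mu`,
#'   `sigma`, `delta`, `lower`, `upper`.
#' @export
fold_change_distribution <- function(direction = c("up", "down"),
                                     mu = NULL, delta = NULL) {
  direction <- match.arg(direction)
  if (is.null(mu)) mu <- if (direction == "up") 6 else 0.5
  if (is.null(delta)) delta <- if (direction == "up") 8 else 1
  if (delta <= 0) stop("delta must be positive")
  lower <- mu - delta / 2
  upper <- mu + delta / 2
  if (direction == "up" && lower <= 1)
    stop("up-regulation fold-change support must stay above 1 (mu - delta/2 > 1); ",
         "got mu = ", mu, ", delta = ", delta)
  if (lower < 0)
    stop("fold-change support extends below 0 (mu = ", mu, ", delta = ", delta, ")")
  structure(list(direction = direction, mu = mu, delta = delta,
                 sigma = delta / 6, lower = lower, upper = upper),
            class = "fold_change_distribution")
}

#' Flux-capacity distributions
#'
#' A `capacity_distribution` is the random upper flux bound of a reaction
#' after an up- or down-regulation. Two representations exist: parametric
#' (a normal truncated to a bounded support, all in flux units) and empirical
#' (a finite sample of capacity values, as produced by enzyme-control-flux
#' analysis). Both support the same [quantile()] and [sample_capacity()]
#' contract.
#'
#' @param reaction_id reaction the capacity belongs to.
#' @param direction `"up"` or `"down"`.
#' @param location,scale,lower,upper truncated-normal parameters, flux units.
#' @return an object of class `capacity_distribution`.
#' @export
capacity_parametric <- function(reaction_id, direction, location, scale,
                                lower, upper) {
  if (lower < 0) stop("capacity support must be nonnegative")
  if (upper < lower) stop("capacity support is empty (upper < lower)")
  if (scale < 0) stop("scale must be nonnegative")
  structure(list(reaction_id = reaction_id, direction = direction,
                 kind = "truncnorm", location = location, scale = scale,
                 lower = lower, upper = upper),
            class = "capacity_distribution")
}

#' @rdname capacity_parametric
#' @param values numeric sample of capacity values, flux units.
#' @param min_sample minimum sample size accepted (floor before the
#'   distribution may drive an optimization).
#' @export
capacity_empirical <- function(reaction_id, direction, values,
                               min_sample = 100) {
  values <- as.numeric(values)
  if (any(values < 0)) stop("capacity sample contains negative values")
  if (length(values) < min_sample)
    stop("empirical capacity sample has ", length(values),
         " values; at least ", min_sample, " required")
  structure(list(reaction_id = reaction_id, direction = direction,
                 kind = "empirical", values = sort(values)),
            class = "capacity_distribution")
}

#' @export
print.capacity_distribution <- function(x, ...) {
  if (x$kind == "truncnorm") {
    cat("capacity_distribution (truncated normal): ", x$reaction_id, " [",
        x$direction, "]\n  location ", x$location, ", scale ", x$scale,
        ", support [", x$lower, ", ", x$upper, "]\n", sep = "")
  } else {
    cat("capacity_distribution (empirical, n=", length(x$values), "): ",
        x$reaction_id, " [", x$direction, "], range [", min(x$values), ", ",
        max(x$values), "]\n", sep = "")
  }
  invisible(x)
}

#' Kinetic-route capacity distribution
#'
#' When a kinetic model supplies a maximal velocity `v_max` for a reaction, a
#' fold-change in enzyme level translates linearly into a fold-change of the
#' flux capacity: the capacity is `v_max` times the fold-change distribution.
#'
#' @param reaction_id reaction identifier.
#' @param vmax maximal velocity of the reaction (flux units), positive.
#' @param fc a [fold_change_distribution()].
#' @return a parametric [capacity_distribution][capacity_parametric].
#' @export
kinetic_capacity <- function(reaction_id, vmax, fc) {
  if (!is.finite(vmax) || vmax <= 0)
    stop("vmax must be positive; got ", vmax, " for ", reaction_id)
  capacity_parametric(reaction_id, fc$direction,
                      location = vmax * fc$mu, scale = vmax * fc$sigma,
                      lower = vmax * fc$lower, upper = vmax * fc$upper)
}

# truncated-normal inverse CDF; p may be a vector
truncnorm_quantile <- function(p, location, scale, lower, upper) {
  if (scale < 1e-12 || upper - lower < 1e-12) {
    # degenerate spread: point mass at the location clamped into the support
    return(rep(min(max(location, lower), upper), length(p)))
  }
  pa <- stats::pnorm((lower - location) / scale)
  pb <- stats::pnorm((upper - location) / scale)
  q <- location + scale * stats::qnorm(pa + p * (pb - pa))
  q <- pmin(pmax(q, lower), upper)
  q[p <= 0] <- lower   # exact support endpoints
  q[p >= 1] <- upper
  q
}

#' Quantile of a capacity distribution
#'
#' The inverse cumulative distribution function, used to convert chance
#' constraints into their deterministic equivalents. For the parametric
#' representation this is the truncated-normal inverse CDF; for the
#' empirical representation, linear interpolation of the empirical CDF over
#' order statistics with the endpoints pinned (`probs = 0` returns the sample
#' minimum, `probs = 1` the maximum), so the worst case at `probs = 0` is
#' always finite and well defined.
#'
#' @param x a [capacity_distribution][capacity_parametric].
#' @param probs probabilities in `[0, 1]`.
#' @param ... unused.
#' @return quantiles in flux units, nondecreasing in `probs`.
#' @export
quantile.capacity_distribution <- function(x, probs, ...) {
  probs <- as.numeric(probs)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("probs must lie in [0, 1]")
  if (x$kind == "truncnorm") {
    truncnorm_quantile(probs, x$location, x$scale, x$lower, x$upper)
  } else {
    v <- x$values  # stored sorted
    n <- length(v)
    if (n == 1) return(rep(v, length(probs)))
    # piecewise-linear inverse of the empirical CDF on the order statistics
    stats::approx(x = seq(0, 1, length.out = n), y = v, xout = probs,
                  rule = 2)$y
  }
}

#' Draw capacities from a distribution
#'
#' Parametric distributions are sampled by the inverse-CDF transform of
#' seeded uniforms; empirical distributions by with-replacement resampling.
#' Draws are reproducible for a given `seed`.
#'
#' @param dist a [capacity_distribution][capacity_parametric].
#' @param n number of draws.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (callers managing their own streams).
#' @return numeric vector of `n` capacity values.
#' @export
sample_capacity <- function(dist, n, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  if (dist$kind == "truncnorm") {
    truncnorm_quantile(u, dist$location, dist$scale, dist$lower, dist$upper)
  } else {
    dist$values[ceiling(u * length(dist$values))]
  }
}

#' Sample a fold-change distribution
#'
#' Inverse-CDF draws from the truncated-normal fold-change model.
#'
#' @param fc a [fold_change_distribution()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of dimensionless fold-changes.
#' @export
sample_fold_change <- function(fc, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truncnorm_quantile(stats::runif(n), fc$mu, fc$sigma, fc$lower, fc$upper)
}

#' Reference-state flux bounds
#'
#' Container for the unmodified (wild-type) state: per-reaction steady-state
#' upper and lower bounds `SSU`/`SSL`, the measured exchange fluxes they were
#' derived from, and the wild-type maximal biomass flux when a biomass
#' reaction is designated.
#'
#' @param SSU,SSL named numeric vectors of upper/lower bounds, flux units.
#' @param measured named numeric vector of measured fluxes (may be empty).
#' @param vbiomass_max wild-type maximal biomass flux, or `NULL`.
#' @return an object of class `reference_state`.
#' @export
reference_state <- function(SSU, SSL, measured = numeric(0),
                            vbiomass_max = NULL) {
  if (!identical(names(SSU), names(SSL)))
    stop("SSU and SSL must be named identically")
  if (any(SSL < -1e-9) || any(SSU - SSL < -1e-9))
    stop("bounds must satisfy 0 <= SSL <= SSU elementwise")
  SSL <- pmax(SSL, 0)
  SSU <- pmax(SSU, SSL)
  if (length(measured)) {
    bad <- names(measured)[measured < SSL[names(measured)] - 1e-6 |
                           measured > SSU[names(measured)] + 1e-6]
    if (length(bad))
      stop("measured flux outside [SSL, SSU] for: ", paste(bad, collapse = ", "))
  }
  structure(list(SSU = SSU, SSL = SSL, measured = measured,
                 vbiomass_max = vbiomass_max),
            class = "reference_state")
}

#' Estimate the reference state by flux variability analysis
#'
#' For every reaction `j`, `SSU_j` and `SSL_j` are the LP maximum and minimum
#' of `v_j` over the constraint set `{S v = 0, 0 <= v <= vmax,
#' v_k = measured_k for measured reactions}` (with an optional relative
#' tolerance on the measured equalities, since real exchange measurements can
#' be inconsistent with exact mass balance). The wild-type maximal biomass
#' flux is computed over the same set with the measurement constraints
#' removed: it is the theoretical maximum of the unmodified network, which
#' the viability constraint of the optimizers refers to.
#'
#' @param model a split (irreversible) [metabolic_model()].
#' @param vmax named numeric vector of maximal velocities covering all
#'   reactions.
#' @param measured named numeric vector of measured fluxes.
#' @param measurement_tol relative tolerance on measured equalities
#'   (default 0, exact equality).
#' @return a [reference_state()].
#' @export
estimate_reference_state <- function(model, vmax, measured = numeric(0),
                                     measurement_tol = 0) {
  if (any(model$reversible))
    stop("model must be split into irreversible reactions first")
  rxns <- model$reactions
  if (!all(rxns %in% names(vmax)))
    stop("vmax missing for reaction(s): ",
         paste(setdiff(rxns, names(vmax)), collapse = ", "))
  if (length(measured) && !all(names(measured) %in% rxns))
    stop("measured flux names are not model reactions: ",
         paste(setdiff(names(measured), rxns), collapse = ", "))
  M <- length(rxns)
  ub <- unname(vmax[rxns])
  lb <- rep(0, M)
  if (length(measured)) {
    idx <- match(names(measured), rxns)
    tol <- measurement_tol * abs(measured)
    lb[idx] <- pmax(lb[idx], measured - tol)
    ub[idx] <- pmin(ub[idx], measured + tol)
    if (any(lb[idx] > ub[idx] + 1e-12))
      stop("measured values incompatible with vmax for: ",
           paste(names(measured)[lb[idx] > ub[idx] + 1e-12], collapse = ", "))
  }
  SSU <- SSL <- stats::setNames(numeric(M), rxns)
  for (j in seq_len(M)) {
    obj <- numeric(M); obj[j] <- 1
    hi <- fba_lp(model$S, obj, upper = ub, lower = lb, maximize = TRUE)
    lo <- fba_lp(model$S, obj, upper = ub, lower = lb, maximize = FALSE)
    if (hi$status != "optimal" || lo$status != "optimal")
      stop("reference-state LP ", hi$status, " for reaction '", rxns[j],
           "'; check measured fluxes ",
           if (length(measured)) paste(names(measured), collapse = ", ") else "(none)")
    SSU[j] <- zap_small(hi$objective)
    SSL[j] <- zap_small(lo$objective)
  }
  SSL <- pmin(SSL, SSU)
  vbmax <- NULL
  if (!is.null(model$biomass_id)) {
    obj <- as.numeric(rxns == model$biomass_id)
    wt <- fba_lp(model$S, obj, upper = unname(vmax[rxns]), maximize = TRUE)
    if (wt$status != "optimal")
      stop("wild-type biomass LP ", wt$status)
    vbmax <- zap_small(wt$objective)
  }
  reference_state(SSU, SSL, measured, vbmax)
}

zap_small <- function(x, tol = 1e-9) ifelse(abs(x) < tol, 0, x)

#' Complete a partial set of maximal velocities
#'
#' Kinetic models often report `v_max` for only a subset of reactions. For
#' each reaction lacking one, its `v_max` is set to the LP maximum of its
#' flux subject to steady state and the known `v_max` bounds, i.e. the
#' largest flux the known kinetic caps allow through it. Known entries pass
#' through unchanged; provenance of each entry is recorded.
#'
#' @param model a split [metabolic_model()].
#' @param known named numeric vector of known maximal velocities (nonempty).
#' @return list with `vmax` (named numeric, all reactions) and `provenance`
#'   (named character, `"given"` or `"completed"`).
#' @export
complete_vmax <- function(model, known) {
  if (any(model$reversible))
    stop("model must be split into irreversible reactions first")
  if (!length(known)) stop("at least one known vmax is required")
  rxns <- model$reactions
  bad <- setdiff(names(known), rxns)
  if (length(bad)) stop("unknown reaction(s) in known vmax: ",
                        paste(bad, collapse = ", "))
  if (any(known <= 0)) stop("vmax values must be positive")
  M <- length(rxns)
  ub <- rep(Inf, M)
  ub[match(names(known), rxns)] <- known
  vmax <- stats::setNames(numeric(M), rxns)
  prov <- stats::setNames(rep("completed", M), rxns)
  vmax[names(known)] <- known
  prov[names(known)] <- "given"
  for (j in which(!rxns %in% names(known))) {
    obj <- numeric(M); obj[j] <- 1
    ans <- fba_lp(model$S, obj, upper = ub, maximize = TRUE)
    if (ans$status == "unbounded")
      stop("flux of reaction '", rxns[j],
           "' is unbounded: the known vmax set does not constrain it")
    if (ans$status != "optimal")
      stop("vmax-completion LP ", ans$status, " for reaction '", rxns[j], "'")
    vmax[j] <- zap_small(ans$objective)
  }
  list(vmax = vmax, provenance = prov)
}

#' Build kinetic capacity distributions for a model
#'
#' Convenience wrapper: attaches up- and down-regulation capacity
#' distributions (fold-change scaling of `v_max`) to a set of reactions.
#'
#' @param vmax named numeric vector of maximal velocities.
#' @param reactions reactions to cover (default: all names of `vmax`).
#' @param fc_up,fc_down fold-change distributions for the two directions.
#' @return a `capacity_set`: list with named lists `up` and `down` of
#'   [capacity_distribution][capacity_parametric] objects.
#' @export
kinetic_capacity_set <- function(vmax, reactions = names(vmax),
                                 fc_up = fold_change_distribution("up"),
                                 fc_down = fold_change_distribution("down")) {
  up <- lapply(reactions, function(r) kinetic_capacity(r, vmax[[r]], fc_up))
  dn <- lapply(reactions, function(r) kinetic_capacity(r, vmax[[r]], fc_down))
  structure(list(up = stats::setNames(up, reactions),
                 down = stats::setNames(dn, reactions)),
            class = "capacity_set")
}
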