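# Elementary flux modes and enzyme control flux (ECF).
#
# For stoichiometric models without kinetic vmax data, capacity distributions
# are estimated from elementary modes: sampled enzyme fold-changes are mapped
# through a power-law adjustment of the elementary-mode coefficients (EMCs)
# and the maximal achievable flux of the modified reaction becomes one
# capacity draw.

#' Enumerate elementary flux modes
#'
#' Computes all elementary modes of the irreversible flux cone
#' `{S v = 0, v >= 0}` by the double-description (tableau) method: starting
#' from the identity rays, each mass-balance row is processed in turn,
#' keeping rays in its null space and combining adjacent positive/negative
#' pairs. For a fully irreversible network the extreme rays of the cone are
#' exactly the support-minimal modes. Futile two-cycles supported exactly on
#' a forward/backward split pair are removed, modes are normalized to a
#' maximum entry of 1, deduplicated, and ordered lexicographically by
#' support.
#'
#' @param model a split (all-irreversible) [metabolic_model()].
#' @param max_modes resource cap on the number of rays carried at any point
#'   (default `1e6`); exceeding it raises an error.
#' @return an object of class `elementary_modes`: list with `modes`
#'   (reactions x K matrix) and `supports` (list of character vectors).
#' @export
enumerate_ems <- function(model, max_modes = 1e6) {
  if (any(model$reversible))
    stop("model must be split into irreversible reactions first")
  S <- model$S
  M <- ncol(S)
  R <- diag(M)  # rows = candidate rays
  for (i in seq_len(nrow(S))) {
    w <- as.numeric(R %*% S[i, ])
    w[abs(w) < 1e-9] <- 0
    zero <- which(w == 0)
    pos <- which(w > 0)
    neg <- which(w < 0)
    keep <- R[zero, , drop = FALSE]
    if (length(pos) && length(neg)) {
      zero_sets <- R == 0  # logical: which coordinates vanish per ray
      new_rays <- list()
      for (p in pos) for (q in neg) {
        # adjacency: no third ray vanishes everywhere both p and q vanish
        z <- zero_sets[p, ] & zero_sets[q, ]
        others <- setdiff(seq_len(nrow(R)), c(p, q))
        adjacent <- TRUE
        for (r in others) {
          if (all(zero_sets[r, ] | !z)) { adjacent <- FALSE; break }
        }
        if (adjacent) {
          ray <- w[p] * R[q, ] - w[q] * R[p, ]
          ray[abs(ray) < 1e-12] <- 0
          new_rays[[length(new_rays) + 1L]] <- ray / max(ray)
        }
      }
      if (length(new_rays))
        keep <- rbind(keep, do.call(rbind, new_rays))
    }
    if (nrow(keep) > max_modes)
      stop("elementary-mode count exceeded the cap of ", max_modes,
           " while processing metabolite '", model$metabolites[i], "'")
    if (!nrow(keep))
      return(new_elementary_modes(matrix(0, M, 0,
                                         dimnames = list(model$reactions, NULL)),
                                  model))
    R <- keep
  }
  modes <- t(R)
  rownames(modes) <- model$reactions
  # normalize, drop futile split-pair two-cycles, dedupe, order by support
  modes <- apply(modes, 2, function(e) e / max(e))
  if (is.null(dim(modes))) modes <- matrix(modes, M, 1,
                                           dimnames = list(model$reactions, NULL))
  if (length(model$split_pairs)) {
    futile <- apply(modes, 2, function(e) {
      s <- model$reactions[e > 1e-9]
      length(s) == 2 && s[1] %in% names(model$split_pairs) &&
        identical(unname(model$split_pairs[s[1]]), s[2])
    })
    modes <- modes[, !futile, drop = FALSE]
  }
  if (ncol(modes)) {
    key <- apply(modes, 2, function(e) paste(signif(e, 9), collapse = ","))
    modes <- modes[, !duplicated(key), drop = FALSE]
    supp_key <- apply(modes > 1e-9, 2,
                      function(s) paste(which(s), collapse = ","))
    modes <- modes[, order(supp_key), drop = FALSE]
  }
  new_elementary_modes(modes, model)
}

new_elementary_modes <- function(modes, model) {
  colnames(modes) <- if (ncol(modes)) paste0("EM", seq_len(ncol(modes))) else NULL
  structure(list(modes = modes,
                 supports = apply(modes, 2,
                                  function(e) rownames(modes)[e > 1e-9],
                                  simplify = FALSE)),
            class = "elementary_modes")
}

#' @export
print.elementary_modes <- function(x, ...) {
  cat("elementary_modes: ", ncol(x$modes), " modes over ", nrow(x$modes),
      " reactions\n", sep = "")
  invisible(x)
}

#' Feasible elementary-mode-coefficient polytope of the reference state
#'
#' The reconstruction `v = E lambda` of a steady-state flux from elementary
#' modes `E` is underdetermined; the reference data constrain the
#' coefficients to the polytope `{lambda >= 0, SSL <= E lambda <= SSU,
#' (E lambda)_k = measured_k}`. The polytope is kept as an opaque object
#' answering LP queries; an empty polytope (measurements inconsistent with
#' the bounds) raises an error.
#'
#' @param ems an [enumerate_ems()] result (nonempty).
#' @param ref a [reference_state()].
#' @return an object of class `emc_polytope`.
#' @export
reference_emc_polytope <- function(ems, ref) {
  E <- ems$modes
  if (!ncol(E)) stop("elementary mode set is empty")
  rxns <- rownames(E)
  SSU <- ref$SSU[rxns]; SSL <- ref$SSL[rxns]
  meas <- ref$measured[names(ref$measured) %in% rxns]
  A_le <- E[is.finite(SSU), , drop = FALSE]
  b_le <- SSU[is.finite(SSU)]
  pos_lb <- SSL > 1e-12 & !(rxns %in% names(meas))
  A_ge <- E[pos_lb, , drop = FALSE]
  b_ge <- SSL[pos_lb]
  A_eq <- E[match(names(meas), rxns), , drop = FALSE]
  b_eq <- unname(meas)
  poly <- structure(list(E = E, A_le = A_le, b_le = unname(b_le),
                         A_ge = A_ge, b_ge = unname(b_ge),
                         A_eq = A_eq, b_eq = b_eq),
                    class = "emc_polytope")
  probe <- emc_lp(poly, rep(0, ncol(E)), maximize = TRUE)
  if (probe$status != "optimal")
    stop("reference EMC polytope is empty: measured fluxes are inconsistent ",
         "with the steady-state bounds")
  poly
}

emc_lp <- function(poly, obj, maximize = TRUE) {
  lp_solve(obj,
           A_eq = if (nrow(poly$A_eq)) poly$A_eq else NULL,
           b_eq = if (nrow(poly$A_eq)) poly$b_eq else NULL,
           A_le = if (nrow(poly$A_le)) poly$A_le else NULL,
           b_le = if (nrow(poly$A_le)) poly$b_le else NULL,
           A_ge = if (nrow(poly$A_ge)) poly$A_ge else NULL,
           b_ge = if (nrow(poly$A_ge)) poly$b_ge else NULL,
           maximize = maximize)
}

#' Maximal flux after a power-law enzyme adjustment
#'
#' Enzyme-control-flux step: a fold-change `a` in the enzyme of
#' `modified_reaction` rescales the coefficient of every elementary mode
#' whose support contains that reaction by `a^h` (power-law model, exponent
#' `h`, default 1); modes not using the reaction are unchanged. The returned
#' value is the maximum of the reconstructed flux of `query_reaction` under
#' the adjusted coefficients, with the unadjusted coefficients ranging over
#' the reference polytope — an LP whose objective carries the scaling.
#'
#' @param ems an [enumerate_ems()] result.
#' @param polytope a [reference_emc_polytope()].
#' @param modified_reaction,query_reaction reaction ids.
#' @param fold_change positive dimensionless fold-change.
#' @param h power-law exponent (positive).
#' @return maximal flux of `query_reaction`, flux units.
#' @export
ecf_adjusted_max_flux <- function(ems, polytope, modified_reaction,
                                  fold_change, query_reaction, h = 1) {
  if (!is.finite(fold_change) || fold_change <= 0)
    stop("fold_change must be positive")
  if (h <= 0) stop("power-law exponent h must be positive")
  E <- polytope$E
  for (r in c(modified_reaction, query_reaction))
    if (!r %in% rownames(E)) stop("'", r, "' is not a reaction in the model")
  affected <- E[modified_reaction, ] > 1e-9
  scaling <- ifelse(affected, fold_change^h, 1)
  obj <- E[query_reaction, ] * scaling
  ans <- emc_lp(polytope, obj, maximize = TRUE)
  if (ans$status != "optimal")
    stop("ECF flux LP ", ans$status)
  ans$objective
}

#' Empirical capacity distribution from ECF analysis
#'
#' Draws `n` fold-changes from the fold-change distribution and maps each
#' through [ecf_adjusted_max_flux()] with the modified reaction queried
#' against itself; the resulting maximal-flux sample is the reaction's
#' capacity distribution for that direction.
#'
#' @param ems an [enumerate_ems()] result.
#' @param polytope a [reference_emc_polytope()].
#' @param reaction reaction id to modify.
#' @param fc a [fold_change_distribution()].
#' @param n sample size (at least 100).
#' @param seed integer seed for reproducibility.
#' @param h power-law exponent.
#' @return an empirical [capacity_distribution][capacity_empirical].
#' @export
ecf_capacity_distribution <- function(ems, polytope, reaction, fc,
                                      n = 1000, seed = 1, h = 1) {
  if (n < 100) stop("n must be at least 100 for a usable capacity sample")
  draws <- sample_fold_change(fc, n, seed = seed)
  vals <- vapply(draws, function(a)
    ecf_adjusted_max_flux(ems, polytope, reaction, a, reaction, h = h),
    0)
  capacity_empirical(reaction, fc$direction, vals, min_sample = min(n, 100))
}
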