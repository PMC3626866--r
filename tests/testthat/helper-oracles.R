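# Independent oracles used across the suite. These deliberately share no
# code with the implementation paths they check (beyond base R).

# The three-reaction chain used throughout: bounds (30, 5, 30), capacity
# distributions on R2 only, target R3.
tl3 <- function() make_linear_fixture(3)

# Brute-force elementary-mode enumeration for tiny models: a reaction subset
# is a mode support iff the null space of S restricted to those columns is
# one-dimensional with a strictly positive basis vector, and no proper
# subset qualifies. Futile forward/backward two-cycles are dropped like the
# implementation does.
brute_force_ems <- function(model) {
  S <- model$S
  M <- ncol(S)
  stopifnot(M <= 10)
  supports <- list()
  vectors <- list()
  for (mask in 1:(2^M - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(M) - 1)) > 0)
    Ssub <- S[, idx, drop = FALSE]
    ns <- MASS::Null(t(Ssub))
    if (is.null(dim(ns)) || ncol(ns) != 1) next
    v <- ns[, 1]
    if (all(v < -1e-9)) v <- -v
    if (any(v < 1e-9)) next  # not strictly positive on its support
    supports[[length(supports) + 1L]] <- model$reactions[idx]
    full <- numeric(M); full[idx] <- v / max(v)
    vectors[[length(vectors) + 1L]] <- full
  }
  # support minimality
  keep <- vapply(seq_along(supports), function(i) {
    !any(vapply(seq_along(supports), function(j)
      j != i && all(supports[[j]] %in% supports[[i]]), TRUE))
  }, TRUE)
  supports <- supports[keep]; vectors <- vectors[keep]
  if (length(model$split_pairs)) {
    futile <- vapply(supports, function(s)
      length(s) == 2 && s[1] %in% names(model$split_pairs) &&
        identical(unname(model$split_pairs[s[1]]), s[2]), TRUE)
    supports <- supports[!futile]; vectors <- vectors[!futile]
  }
  list(supports = supports, vectors = vectors)
}

# Truncated-normal quantile by bisection against a trapezoid-integrated pdf;
# independent of the closed-form path under test.
numeric_truncnorm_quantile <- function(p, location, scale, lower, upper,
                                       n_grid = 200001) {
  x <- seq(lower, upper, length.out = n_grid)
  dens <- exp(-0.5 * ((x - location) / scale)^2)
  cdf <- cumsum(c(0, (dens[-1] + dens[-n_grid]) / 2 * diff(x)))
  cdf <- cdf / cdf[n_grid]
  vapply(p, function(pp) {
    if (pp <= 0) return(lower)
    if (pp >= 1) return(upper)
    i <- findInterval(pp, cdf)
    x[i] + (pp - cdf[i]) / (cdf[i + 1] - cdf[i]) * (x[i + 1] - x[i])
  }, 0)
}

# Closed-form truncated-normal mean (for the sampling-moment check).
truncnorm_mean <- function(location, scale, lower, upper) {
  a <- (lower - location) / scale
  b <- (upper - location) / scale
  location + scale * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# Vertex enumeration of {v : S v = 0, lb <= v <= ub} for tiny models: take
# every subset of active bound constraints that pins the null-space degrees
# of freedom, solve, keep feasible points; per-reaction min/max over the
# vertex set equals the LP bounds.
enumerate_polytope_vertices <- function(S, lb, ub, fixed = list()) {
  M <- ncol(S)
  A <- S
  b <- rep(0, nrow(S))
  for (nm in names(fixed)) {
    row <- numeric(M); row[nm == colnames(S)] <- 1
    A <- rbind(A, row); b <- c(b, fixed[[nm]])
  }
  dof <- M - qr(A)$rank
  verts <- list()
  bnd_rows <- rbind(cbind(diag(M), lb), cbind(diag(M), ub))
  if (dof <= 0) {
    sol <- qr.solve(A, b)
    return(matrix(sol, 1, dimnames = list(NULL, colnames(S))))
  }
  for (pick in utils::combn(nrow(bnd_rows), dof, simplify = FALSE)) {
    Aa <- rbind(A, bnd_rows[pick, seq_len(M), drop = FALSE])
    bb <- c(b, bnd_rows[pick, M + 1])
    if (qr(Aa)$rank < M) next
    v <- tryCatch(qr.solve(Aa, bb), error = function(e) NULL)
    if (is.null(v)) next
    if (all(v >= lb - 1e-8) && all(v <= ub + 1e-8) &&
        all(abs(S %*% v) < 1e-8)) {
      ok <- TRUE
      for (nm in names(fixed)) if (abs(v[nm == colnames(S)] - fixed[[nm]]) > 1e-8) ok <- FALSE
      if (ok) verts[[length(verts) + 1L]] <- v
    }
  }
  do.call(rbind, verts)
}

# A small SBML Level 3 document for the import test (written by hand; the
# network is the three-reaction chain with a boundary glucose species).
sbml_chain_doc <- function() {
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="chain">
    <listOfSpecies>
      <species id="glc_ext" boundaryCondition="true" compartment="e"/>
      <species id="A" boundaryCondition="false" compartment="c"/>
      <species id="B" boundaryCondition="false" compartment="c"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R1" reversible="false">
        <listOfReactants><speciesReference species="glc_ext" stoichiometry="1"/></listOfReactants>
        <listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>
      </reaction>
      <reaction id="R2" reversible="true">
        <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
        <listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>
      </reaction>
      <reaction id="R3" reversible="false">
        <listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
}
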