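#' Simulation settings
#'
#' @param tol absolute convergence tolerance on the synchronous fixed-point
#'   iteration (default 1e-9).
#' @param maxit maximum number of synchronous sweeps (default 100; an acyclic
#'   network converges in at most its depth plus one).
#' @return a `cfl_settings` list.
#' @export
cfl_settings <- function(tol = 1e-9, maxit = 100L) {
  stopifnot(tol > 0, maxit >= 1)
  structure(list(tol = tol, maxit = as.integer(maxit)), class = "cfl_settings")
}

#' Normalized Hill transfer function
#'
#' `f(x) = a * H(x) / H(1)` with `H(x) = x^n / (p^n + x^n)`, so that
#' `f(0) = 0`, `f(1) = a` and `f` is strictly increasing, continuous and
#' differentiable on \[0,1\]. `p` is the midpoint of the unnormalized curve
#' (where `H` reaches 1/2), `n` its steepness, and `a` a gain that scales the
#' amount of signal a reaction transmits downstream.
#'
#' @param x upstream activation in \[0,1\] (vectorized).
#' @param a gain in \[0,1\].
#' @param p midpoint, positive.
#' @param n Hill coefficient, positive (default 4).
#' @return activity values in \[0, a\].
#' @export
hill_transfer <- function(x, a, p, n = 4) {
  if (any(x < -1e-12 | x > 1 + 1e-12))
    stop("hill_transfer: input activation outside [0,1]")
  x <- pmin(pmax(x, 0), 1)
  a * (x^n / (p^n + x^n)) * (p^n + 1)
}

#' Activity of a single gated reaction
#'
#' The effective input of an AND gate is the bilinear product of its reactant
#' activations, with each inhibitor entering as its complement `1 - x`; the
#' activity is the Hill transfer of that product. On \{0,1\} inputs with
#' `a = 1` this reproduces the Boolean AND / AND-NOT gate.
#'
#' @param reactants numeric vector of reactant activations (length 0--2).
#' @param inhibitors numeric vector of inhibitor activations (length 0--1).
#' @param a,p,n transfer-function parameters as in [hill_transfer()].
#' @return reaction activity `z` in \[0,1\].
#' @export
reaction_activity <- function(reactants, inhibitors = numeric(), a = 1, p = 0.5, n = 4) {
  if (length(reactants) + length(inhibitors) == 0)
    stop("reaction_activity: a reaction needs at least one input")
  u <- prod(reactants) * prod(1 - inhibitors)
  hill_transfer(u, a, p, n)
}

#' OR-combination of reaction activities (probabilistic sum)
#'
#' Activities of the reactions producing one species are combined recursively
#' by `u <- u + z - u*z`. The operation is commutative and associative, never
#' smaller than any input, and equals Boolean OR on \{0,1\}. An empty set
#' yields 0: a species with no producers and no clamp stays inactive.
#'
#' @param z numeric vector of reaction activities in \[0,1\].
#' @return combined activation in \[0,1\].
#' @export
or_combine <- function(z) {
  if (any(z < 0 | z > 1)) stop("or_combine: activities must lie in [0,1]")
  u <- 0
  for (zi in z) u <- u + zi - u * zi
  u
}

# internal: integer-coded reaction structure for the C++ core
.pack_pathway <- function(pathway) {
  nm <- pathway$species$name
  n_r <- n_reactions(pathway)
  react <- matrix(0L, 2L, n_r)
  inhib <- integer(n_r)
  prod <- integer(n_r)
  for (i in seq_len(n_r)) {
    r <- pathway$reactions[[i]]
    ri <- match(r$reactants, nm)
    if (length(ri)) react[seq_along(ri), i] <- ri
    if (length(r$inhibitors)) inhib[i] <- match(r$inhibitors, nm)
    prod[i] <- match(r$product, nm)
  }
  list(react = react, inhib = inhib, prod = prod, names = nm)
}

# internal: n_s x n_e clamp matrix (NA = free species)
.clamp_matrix <- function(pathway, design) {
  nm <- pathway$species$name
  cl <- matrix(NA_real_, length(nm), n_experiments(design))
  tr <- design$treatments
  unknown <- setdiff(colnames(tr), nm)
  if (length(unknown))
    stop("design treatments not in pathway: ", paste(unknown, collapse = ", "))
  cl[match(colnames(tr), nm), ] <- t(tr)
  rownames(cl) <- nm
  cl
}

#' Pseudo-steady-state simulation of a cFL model
#'
#' For every experiment, treatment species (all stimuli and inhibitor nodes of
#' the design) are clamped to their 0/1 treatment values, every other species
#' starts at 0, and the synchronous update `x_j <- OR_{i in T_j} z_i` with
#' `z_i = f(prod(R_i) * prod(1 - I_i))` is iterated to a fixed point. For an
#' acyclic pathway this equals a single topological-order pass; cyclic
#' pathways iterate until the maximum absolute change falls below `tol`.
#'
#' @param pathway a [cfl_pathway].
#' @param params a [cfl_params] table (default: nominal `a = 1, p = 0.5, n = 4`).
#' @param design a [cfl_design].
#' @param settings a [cfl_settings].
#' @return a `cfl_prediction`: list with `x` (species x experiments activation
#'   matrix) and `z` (reactions x experiments activity matrix).
#' @export
simulate_pathway <- function(pathway, params = cfl_params(pathway), design,
                             settings = cfl_settings()) {
  pk <- .pack_pathway(pathway)
  cl <- .clamp_matrix(pathway, design)
  res <- .simulate_cpp(pk$react, pk$inhib, pk$prod,
                       as.numeric(params$a), as.numeric(params$p),
                       as.numeric(params$n[1]), cl, settings$tol, settings$maxit)
  if (!all(res$converged)) {
    bad <- which(!res$converged)[1]
    moving <- .oscillating_species(pathway, params, cl[, bad], settings)
    stop(sprintf(paste0("simulation did not converge in experiment %d within %d ",
                        "iterations (oscillating species: %s)"),
                 bad, settings$maxit, paste(moving, collapse = ", ")))
  }
  x <- res$x; rownames(x) <- pk$names
  z <- res$z
  rownames(z) <- vapply(seq_len(n_reactions(pathway)),
                        function(i) paste0("r", i), "")
  structure(list(x = x, z = z, iterations = res$iterations),
            class = "cfl_prediction")
}

# identify the species still changing after maxit sweeps (cycle diagnosis)
.oscillating_species <- function(pathway, params, clamp_col, settings) {
  nm <- pathway$species$name
  x <- ifelse(is.na(clamp_col), 0, clamp_col)
  step <- function(x) {
    xn <- setNames(numeric(length(nm)), nm)
    for (i in seq_len(n_reactions(pathway))) {
      r <- pathway$reactions[[i]]
      z <- reaction_activity(x[r$reactants], x[r$inhibitors],
                             params$a[i], params$p[i], params$n[i])
      xn[r$product] <- xn[r$product] + z - xn[r$product] * z
    }
    xn[!is.na(clamp_col)] <- x[!is.na(clamp_col)]
    xn
  }
  names(x) <- nm
  for (it in seq_len(settings$maxit)) x <- step(x)
  x2 <- step(x)
  nm[abs(x2 - x) > settings$tol]
}

#' @export
print.cfl_prediction <- function(x, ...) {
  cat(sprintf("cfl_prediction: %d species x %d experiments (max %d sweeps)\n",
              nrow(x$x), ncol(x$x), max(x$iterations)))
  invisible(x)
}

#' Extract predicted values for the measured cells
#'
#' @param prediction a `cfl_prediction` from [simulate_pathway()].
#' @param measurements a [cfl_measurements]; defines which (species,
#'   experiment) cells to extract.
#' @return numeric matrix shaped like `measurements$values`.
#' @export
predicted_values <- function(prediction, measurements) {
  miss <- setdiff(measurements$signals, rownames(prediction$x))
  if (length(miss)) stop("measured species absent from prediction: ",
                         paste(miss, collapse = ", "))
  t(prediction$x[measurements$signals, , drop = FALSE])
}
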