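#' Fit configuration
#'
#' Bounds and solver settings for the parameter-estimation problem. With the
#' Hill coefficient fixed, the free parameters are the gain `a` in \[0,1\] and
#' the midpoint `p` in `p_bounds` of every parameter group. The default
#' midpoint bounds (0.1--0.4375) are the medium/large-scale preset selected by
#' bounds-grid search; `preset = "toy"` switches to the wider 0.3--0.7 box
#' used for small demonstration models.
#'
#' @param p_bounds length-2 numeric, lower and upper bound for `p`.
#' @param n fixed Hill coefficient (default 4).
#' @param eps smoothing constant of the smoothed-absolute loss (default 1e-8).
#' @param loss `"sabs"` (smoothed absolute deviation, default) or `"squared"`.
#' @param init `"nominal"` (a = 1, p = 0.5 clipped into bounds) or `"random"`
#'   (uniform in the bound box, drawn from the current RNG stream).
#' @param maxit maximum solver iterations (default 200).
#' @param ndeps finite-difference step for the numerical gradient (default 1e-6).
#' @param continuation solve first with Hill coefficient 1 (a nearly linear,
#'   much smoother landscape) and use that optimum as the starting point for
#'   the target `n`; markedly reduces trapping in shallow local minima
#'   (default TRUE).
#' @param polish after the main solve, re-solve once with each eliminated
#'   reaction (gain below 0.05) reinstated at full gain, keeping the better
#'   optimum. A characteristic local minimum of gated networks wrongly zeroes
#'   a vital reaction because reinstating it alone -- without adjusting the
#'   gains downstream -- raises the mismatch; the check lets the solver make
#'   that coordinated move (default TRUE).
#' @param preset `"medium"` (default bounds) or `"toy"` (p in \[0.3, 0.7\]).
#' @return a `cfl_config` list.
#' @export
cfl_config <- function(p_bounds = c(0.1, 0.4375), n = 4, eps = 1e-8,
                       loss = c("sabs", "squared"),
                       init = c("nominal", "random"),
                       maxit = 200L, ndeps = 1e-6, continuation = TRUE,
                       polish = TRUE, preset = c("medium", "toy")) {
  preset <- match.arg(preset)
  if (preset == "toy" && missing(p_bounds)) p_bounds <- c(0.3, 0.7)
  if (length(p_bounds) != 2 || p_bounds[1] <= 0 || p_bounds[1] >= p_bounds[2])
    stop("p_bounds must satisfy 0 < lower < upper")
  structure(list(p_bounds = p_bounds, n = n, eps = eps,
                 loss = match.arg(loss), init = match.arg(init),
                 maxit = as.integer(maxit), ndeps = ndeps,
                 continuation = isTRUE(continuation), polish = isTRUE(polish)),
            class = "cfl_config")
}

# theta packing: one (a, p) pair per parameter group, groups in ascending order
.group_ids <- function(pathway) sort(unique(vapply(pathway$reactions, `[[`, 1L, "group")))

.theta_to_params <- function(theta, pathway, config) {
  g <- .group_ids(pathway)
  ng <- length(g)
  grp <- vapply(pathway$reactions, `[[`, 1L, "group")
  ix <- match(grp, g)
  cfl_params(pathway, a = theta[ix], p = theta[ng + ix], n = config$n)
}

.params_to_theta <- function(params, pathway) {
  g <- .group_ids(pathway)
  ix <- match(g, params$group)
  c(params$a[ix], params$p[ix])
}

.theta_bounds <- function(pathway, config) {
  ng <- length(.group_ids(pathway))
  list(lower = c(rep(0, ng), rep(config$p_bounds[1], ng)),
       upper = c(rep(1, ng), rep(config$p_bounds[2], ng)))
}

.init_theta <- function(pathway, config) {
  b <- .theta_bounds(pathway, config)
  ng <- length(b$lower) / 2
  if (config$init == "random") {
    runif(2 * ng, b$lower, b$upper)
  } else {
    pmin(pmax(c(rep(1, ng), rep(0.5, ng)), b$lower), b$upper)
  }
}

.residuals <- function(prediction, measurements) {
  predicted_values(prediction, measurements) - measurements$values
}

#' Weighted measurement-prediction mismatch (the NLP objective)
#'
#' `sum_k sum_j alpha_j^k * rho(x_j^k - xhat_j^k)` over measured cells, with
#' `rho(r) = sqrt(r^2 + eps)` by default (a smoothed absolute deviation that
#' keeps the objective differentiable while agreeing in shape with the MAE
#' report), or `rho(r) = r^2` with `loss = "squared"`.
#'
#' @param params a [cfl_params] table.
#' @param pathway,design,measurements model and data.
#' @param config a [cfl_config] (provides `eps` and `loss`).
#' @param settings a [cfl_settings].
#' @return nonnegative scalar; 0 (up to `eps`) iff predictions match exactly.
#' @export
cfl_objective <- function(params, pathway, design, measurements,
                          config = cfl_config(), settings = cfl_settings()) {
  pred <- simulate_pathway(pathway, params, design, settings)
  r <- .residuals(pred, measurements)
  w <- measurements$weights
  mask <- !is.na(r)
  if (!any(mask)) stop("no measured cells")
  rho <- if (config$loss == "sabs") sqrt(r[mask]^2 + config$eps) else r[mask]^2
  sum(w[mask] * rho)
}

#' Mean absolute error over measured cells
#'
#' The goodness-of-fit report: mean of `|x_j^k - xhat_j^k|` over all measured
#' cells, in \[0,1\] (conventionally quoted as a percentage).
#'
#' @param prediction a `cfl_prediction` from [simulate_pathway()].
#' @param measurements a [cfl_measurements].
#' @return scalar in \[0,1\].
#' @export
cfl_mae <- function(prediction, measurements) {
  r <- .residuals(prediction, measurements)
  if (!any(!is.na(r))) stop("no measured cells")
  mean(abs(r), na.rm = TRUE)
}

#' MAE of the null solution (all gains zero)
#'
#' With every gain at 0 no signal propagates; the resulting fitness error is
#' the ceiling against which fits are judged.
#'
#' @inheritParams cfl_objective
#' @return scalar in \[0,1\].
#' @export
null_mae <- function(pathway, design, measurements, settings = cfl_settings()) {
  pred <- simulate_pathway(pathway, cfl_params(pathway, a = 0), design, settings)
  cfl_mae(pred, measurements)
}

#' Fit transfer-function parameters by bounded local optimization
#'
#' Minimizes [cfl_objective()] over the `(a, p)` box with `stats::optim`'s
#' L-BFGS-B (a projected quasi-Newton method; gradients by finite differences
#' through the simulation). The Hill coefficient stays fixed. A solver failure
#' is caught and reported in the solution's `status`, falling back to the
#' initial guess; the returned objective never exceeds the initial one.
#'
#' @inheritParams cfl_objective
#' @param init_params optional [cfl_params] starting point; otherwise the
#'   config's init policy is used.
#' @return a `cfl_solution`: fitted `params`, `objective`, `mae`,
#'   `prediction`, per-reaction `max_activity` (`max_k z_i^k`), the initial
#'   guess `init`, and solver `status`.
#' @export
cfl_optimize <- function(pathway, design, measurements, config = cfl_config(),
                         settings = cfl_settings(), init_params = NULL) {
  if (!n_measured_cells(measurements)) stop("no measured cells")
  b <- .theta_bounds(pathway, config)
  theta0 <- if (is.null(init_params)) .init_theta(pathway, config)
            else pmin(pmax(.params_to_theta(init_params, pathway), b$lower), b$upper)
  make_fn <- function(cfg) function(theta) {
    # finite-difference probes can step ndeps outside an active bound
    theta <- pmin(pmax(theta, b$lower), b$upper)
    cfl_objective(.theta_to_params(theta, pathway, cfg),
                  pathway, design, measurements, cfg, settings)
  }
  solve_box <- function(theta, cfg, fix = integer()) {
    fn <- make_fn(cfg)
    free <- setdiff(seq_along(theta), fix)
    fn_free <- function(th_free) { th <- theta; th[free] <- th_free; fn(th) }
    tryCatch({
      r <- optim(theta[free], fn_free, method = "L-BFGS-B",
                 lower = b$lower[free], upper = b$upper[free],
                 control = list(maxit = cfg$maxit,
                                ndeps = rep(cfg$ndeps, length(free))))
      par <- theta; par[free] <- r$par
      list(par = par, value = r$value, convergence = r$convergence,
           message = r$message)
    }, error = function(e) list(par = theta, value = fn(theta),
                                convergence = -1L,
                                message = conditionMessage(e)))
  }
  f0 <- make_fn(config)(theta0)
  start <- theta0
  if (config$continuation && config$n != 1) {
    cfg1 <- config; cfg1$n <- 1
    pre <- solve_box(theta0, cfg1)
    if (!identical(pre$convergence, -1L))
      start <- pmin(pmax(pre$par, b$lower), b$upper)
  }
  res <- solve_box(start, config)
  if (config$polish && !identical(res$convergence, -1L)) {
    # reinstatement check: for every eliminated reaction, re-solve with its
    # gain held at full strength so the remaining gains can adapt, then
    # release; keeps the better optimum
    ng <- length(res$par) / 2
    for (gi in which(res$par[seq_len(ng)] < 0.05)) {
      cand <- pmin(pmax(res$par, b$lower), b$upper); cand[gi] <- 1
      held <- solve_box(cand, config, fix = gi)
      if (identical(held$convergence, -1L)) next
      alt <- solve_box(held$par, config)
      if (!identical(alt$convergence, -1L) && alt$value < res$value - 1e-9)
        res <- alt
    }
  }
  status <- if (identical(res$convergence, -1L)) "failure"
            else if (res$convergence == 0) "converged" else "maxit"
  if (res$value > f0) { res$par <- theta0; res$value <- f0 }  # never worse than start
  res$par <- pmin(pmax(res$par, b$lower), b$upper)
  params <- .theta_to_params(res$par, pathway, config)
  pred <- simulate_pathway(pathway, params, design, settings)
  structure(list(params = params,
                 objective = res$value,
                 mae = cfl_mae(pred, measurements),
                 prediction = pred,
                 max_activity = apply(pred$z, 1, max),
                 init = .theta_to_params(theta0, pathway, config),
                 status = status,
                 message = res$message),
            class = "cfl_solution")
}

#' @export
print.cfl_solution <- function(x, ...) {
  cat(sprintf("cfl_solution: MAE = %.2f%% (objective %.4g, %s)\n",
              100 * x$mae, x$objective, x$status))
  invisible(x)
}

#' Select midpoint bounds by grid search
#'
#' Fits once per candidate `(p_lb, p_ub)` pair and reports MAE and wall time;
#' the pair minimizing MAE wins, ties going to the narrower box. The fit
#' quality is typically governed by the lower bound.
#'
#' @inheritParams cfl_objective
#' @param grid list of length-2 numeric vectors, or a 2-column matrix of
#'   `(p_lb, p_ub)` pairs.
#' @return list with `bounds` (the winning pair) and `report` (a data.frame
#'   with columns `p_lb`, `p_ub`, `mae`, `seconds`, `status`).
#' @export
select_bounds <- function(pathway, design, measurements, grid,
                          config = cfl_config(), settings = cfl_settings()) {
  if (is.matrix(grid)) grid <- asplit(grid, 1)
  if (!length(grid)) stop("empty bounds grid")
  rows <- lapply(grid, function(bp) {
    cfg <- config; cfg$p_bounds <- as.numeric(bp)
    t0 <- proc.time()[["elapsed"]]
    sol <- cfl_optimize(pathway, design, measurements, cfg, settings)
    data.frame(p_lb = bp[1], p_ub = bp[2], mae = sol$mae,
               seconds = proc.time()[["elapsed"]] - t0, status = sol$status)
  })
  report <- do.call(rbind, rows)
  if (all(report$status == "failure")) stop("all bound-grid fits failed")
  ok <- report[report$status != "failure", ]
  best_mae <- min(ok$mae)
  cand <- ok[ok$mae <= best_mae + 1e-12, ]
  cand <- cand[order(cand$p_ub - cand$p_lb), ]
  list(bounds = c(cand$p_lb[1], cand$p_ub[1]), report = report)
}

#' Multistart optimization: a family of near-optimal solutions
#'
#' Runs [cfl_optimize()] `n_runs` times from independent uniform-random
#' initial guesses inside the bound box. Because a local solver carries no
#' global-optimality guarantee, the family both hedges against poor local
#' minima and exposes alternative near-optimal pathways; the per-reaction
#' activity averaged over the family is the "average pathway".
#'
#' @inheritParams cfl_objective
#' @param n_runs number of restarts (>= 1).
#' @param seed integer seed; per-run streams are derived reproducibly.
#' @return a `cfl_family`: `solutions` (list), `mae` (vector), `best` (index
#'   of the lowest MAE), `avg_activity` (per-reaction mean over runs of
#'   `max_k z_i^k`), `low_gain_fraction` (share of runs with `a < 0.05` per
#'   reaction), and `seed`.
#' @export
cfl_multistart <- function(pathway, design, measurements, config = cfl_config(),
                           settings = cfl_settings(), n_runs = 50L, seed = 1L) {
  stopifnot(n_runs >= 1)
  cfg <- config; cfg$init <- "random"
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  solutions <- lapply(run_seeds, function(s) {
    set.seed(s)
    cfl_optimize(pathway, design, measurements, cfg, settings)
  })
  mae <- vapply(solutions, `[[`, 0, "mae")
  act <- vapply(solutions, `[[`, numeric(n_reactions(pathway)), "max_activity")
  act <- matrix(act, nrow = n_reactions(pathway))
  a_mat <- vapply(solutions, function(s) s$params$a, numeric(n_reactions(pathway)))
  a_mat <- matrix(a_mat, nrow = n_reactions(pathway))
  structure(list(solutions = solutions, mae = mae, best = which.min(mae),
                 avg_activity = rowMeans(act),
                 low_gain_fraction = rowMeans(a_mat < 0.05),
                 seed = seed),
            class = "cfl_family")
}

#' @export
print.cfl_family <- function(x, ...) {
  cat(sprintf("cfl_family: %d runs, best MAE = %.2f%% (spread %.2f%%)\n",
              length(x$mae), 100 * min(x$mae), 100 * diff(range(x$mae))))
  invisible(x)
}

#' Serialize a solution as CSV (one row per reaction)
#'
#' @param solution a `cfl_solution`.
#' @param pathway the fitted [cfl_pathway] (for reaction labels).
#' @param path output CSV path.
#' @export
write_solution <- function(solution, pathway, path) {
  df <- data.frame(id = solution$params$id,
                   reaction = vapply(pathway$reactions, .reaction_label, ""),
                   a = solution$params$a, p = solution$params$p,
                   n = solution$params$n,
                   max_activity = as.numeric(solution$max_activity))
  write.csv(df, path, row.names = FALSE)
  invisible(NULL)
}
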