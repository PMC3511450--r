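#' Cross-validate the fitting procedure against held-out data
#'
#' For every exclusion fraction, a random portion of the measured cells is
#' masked out of training; the model is fitted on the remainder and evaluated
#' both on the full dataset (total MAE) and on the excluded cells alone.
#' Small fractions probe redundancy in the design (held-out cells inferable
#' from the rest fit almost as well); large fractions leave the model
#' unconstrained and the total error climbs toward the null-solution ceiling.
#'
#' @inheritParams cfl_objective
#' @param fractions ascending numeric vector of exclusion fractions in \[0,1).
#' @param replicates random exclusions per fraction (default 5).
#' @param seed integer seed.
#' @param mode `"cell"` (default) excludes individual (species, experiment)
#'   measurements; `"condition"` excludes whole experiments.
#' @param n_restarts multistart restarts per training fit (default 3); as in
#'   pruning, a small family per fit keeps a stray local minimum from
#'   masquerading as a generalization failure.
#' @return a `cfl_crossval`: `summary` (data.frame `fraction`, `total_mae`,
#'   `excluded_mae` averaged over replicates), `replicates` (per-replicate
#'   rows), `null_mae`, `seed`.
#' @export
cross_validate <- function(pathway, design, measurements,
                           config = cfl_config(), settings = cfl_settings(),
                           fractions = c(0, 0.2, 0.4, 0.6, 0.8, 0.95),
                           replicates = 5L, seed = 1L,
                           mode = c("cell", "condition"), n_restarts = 3L) {
  mode <- match.arg(mode)
  stopifnot(replicates >= 1, !is.unsorted(fractions),
            all(fractions >= 0 & fractions < 1))
  cells <- which(!is.na(measurements$values))
  n_cells <- length(cells)
  if (!n_cells) stop("no measured cells")
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(fractions) * replicates),
                      nrow = length(fractions))
  rows <- list()
  for (fi in seq_along(fractions)) {
    phi <- fractions[fi]
    for (r in seq_len(replicates)) {
      set.seed(rep_seeds[fi, r])
      if (mode == "cell") {
        n_out <- floor(phi * n_cells)
        excl <- if (n_out) sample(cells, n_out) else integer()
      } else {
        n_out <- floor(phi * n_experiments(design))
        out_exp <- if (n_out) sample(n_experiments(design), n_out) else integer()
        excl <- intersect(cells, which(row(measurements$values) %in% out_exp))
      }
      if (length(excl) >= n_cells) stop("exclusion fraction leaves no training cells")
      train_vals <- measurements$values
      train_vals[excl] <- NA_real_
      train <- cfl_measurements(train_vals, measurements$weights)
      sol <- if (n_restarts > 1) {
        fam <- cfl_multistart(pathway, design, train, config, settings,
                              n_runs = n_restarts, seed = rep_seeds[fi, r])
        fam$solutions[[fam$best]]
      } else cfl_optimize(pathway, design, train, config, settings)
      pv <- predicted_values(sol$prediction, measurements)
      res <- abs(pv - measurements$values)
      total_mae <- mean(res[cells])
      excluded_mae <- if (length(excl)) mean(res[excl]) else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(fraction = phi, replicate = r, total_mae = total_mae,
                   excluded_mae = excluded_mae)
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$fraction), function(d)
    data.frame(fraction = d$fraction[1],
               total_mae = mean(d$total_mae),
               excluded_mae = if (all(is.na(d$excluded_mae))) NA_real_
                              else mean(d$excluded_mae, na.rm = TRUE))))
  rownames(summ) <- NULL
  structure(list(summary = summ, replicates = reps,
                 null_mae = null_mae(pathway, design, measurements, settings),
                 seed = seed),
            class = "cfl_crossval")
}

#' @export
print.cfl_crossval <- function(x, ...) {
  cat(sprintf("cfl_crossval (null MAE = %.2f%%):\n", 100 * x$null_mae))
  print(transform(x$summary, total_mae = round(total_mae, 4),
                  excluded_mae = round(excluded_mae, 4)))
  invisible(x)
}

#' Plot the cross-validation error curves
#'
#' Total MAE (solid) and excluded-data MAE (dashed) against the exclusion
#' fraction, with the null-solution ceiling as a dotted reference line.
#'
#' @param x a `cfl_crossval`.
#' @param ... passed to [plot()].
#' @export
plot.cfl_crossval <- function(x, ...) {
  s <- x$summary
  plot(s$fraction, s$total_mae, type = "b", col = "blue", ylim = c(0, max(
    x$null_mae, s$total_mae, s$excluded_mae, na.rm = TRUE)),
    xlab = "excluded fraction of dataset", ylab = "MAE", ...)
  lines(s$fraction, s$excluded_mae, type = "b", col = "red", lty = 2)
  abline(h = x$null_mae, lty = 3)
  legend("topleft", c("total", "excluded", "null ceiling"),
         col = c("blue", "red", "black"), lty = c(1, 2, 3), bty = "n")
  invisible(x)
}

#' Summary statistics of a multistart family of solutions
#'
#' MAE mean and standard deviation (population convention, i.e. divisor `n`),
#' the sd of the first `m` solutions as `m` grows (a guide to how many
#' restarts are enough), the per-reaction average activity, and the fraction
#' of runs in which each reaction's gain collapsed below 0.05.
#'
#' @param family a `cfl_family` from [cfl_multistart()] (size >= 2).
#' @return a `cfl_family_stats` list.
#' @export
family_statistics <- function(family) {
  n <- length(family$mae)
  if (n < 2) stop("family_statistics needs a family of at least 2 solutions")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  structure(list(
    n = n,
    mae_mean = mean(family$mae),
    mae_sd = pop_sd(family$mae),
    sd_by_prefix = data.frame(size = 2:n,
                              sd = vapply(2:n, function(m) pop_sd(family$mae[1:m]), 0)),
    avg_activity = family$avg_activity,
    low_gain_fraction = family$low_gain_fraction
  ), class = "cfl_family_stats")
}

#' @export
print.cfl_family_stats <- function(x, ...) {
  cat(sprintf("cfl_family_stats: n = %d, MAE %.2f%% +/- %.2f%% (population sd)\n",
              x$n, 100 * x$mae_mean, 100 * x$mae_sd))
  invisible(x)
}
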