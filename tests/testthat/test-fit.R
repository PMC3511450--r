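test_that("the objective is a weighted smoothed-absolute mismatch", {
  fx <- toy_fixture()
  truth <- fx$truth$params
  # perfect fit: bounded by n_cells * sqrt(eps)
  obj <- cfl_objective(truth, fx$pathway, fx$design, fx$measurements, fx$config)
  expect_lt(obj, 45 * sqrt(fx$config$eps) + 1e-12)

  # one cell off by 0.5 contributes ~0.5 (plus the eps floor of the other cells)
  v <- fx$measurements$values
  v[1, "JNK"] <- 0.5
  m2 <- cfl_measurements(v)
  expect_lt(abs(cfl_objective(truth, fx$pathway, fx$design, m2, fx$config) - 0.5),
            0.01)

  # doubling one node's weights doubles its residual contribution
  w <- matrix(1, nrow(v), ncol(v), dimnames = dimnames(v))
  w[, "JNK"] <- 2
  m3 <- cfl_measurements(v, w)
  base <- cfl_objective(truth, fx$pathway, fx$design, fx$measurements, fx$config)
  expect_equal(cfl_objective(truth, fx$pathway, fx$design, m3, fx$config) - base,
               2 * (cfl_objective(truth, fx$pathway, fx$design, m2, fx$config) - base),
               tolerance = 1e-2)
})

test_that("the objective is invariant to reaction reordering", {
  fx <- toy_fixture()
  perm <- c(3, 1, 2, 5, 4, 7, 6, 9, 10, 8)
  pw2 <- cfl_pathway(fx$pathway$species,
                     lapply(fx$pathway$reactions[perm], function(r)
                       list(reactants = r$reactants, inhibitors = r$inhibitors,
                            product = r$product)))
  p1 <- fx$truth$params
  p2 <- cfl_params(pw2, a = p1$a[perm], p = p1$p[perm])
  expect_equal(cfl_objective(p2, pw2, fx$design, fx$measurements, fx$config),
               cfl_objective(p1, fx$pathway, fx$design, fx$measurements, fx$config))
})

test_that("MAE is the arithmetic mean of absolute residuals", {
  pw <- cfl_pathway(data.frame(name = c("S", "M"), role = c("stimulus", "measured")),
                    list(list(reactants = "S", product = "M")))
  des <- cfl_design(matrix(c(0, 1, 1), 3, 1, dimnames = list(NULL, "S")))
  pred <- simulate_pathway(pw, cfl_params(pw, a = 0.6), des)
  # predictions are (0, 0.6, 0.6); residuals chosen to give {0, 0.2, 0.4}
  meas <- cfl_measurements(matrix(c(0, 0.8, 1.0), 3, 1,
                                  dimnames = list(NULL, "M")))
  expect_equal(cfl_mae(pred, meas), mean(c(0, 0.2, 0.4)))
  meas0 <- cfl_measurements(matrix(c(0, 0.6, 0.6), 3, 1,
                                   dimnames = list(NULL, "M")))
  expect_equal(cfl_mae(pred, meas0), 0)
  expect_error(cfl_mae(pred, cfl_measurements(matrix(NA_real_, 3, 1,
                                                     dimnames = list(NULL, "M")))),
               "no measured cells")
})

test_that("a single-reaction chain recovers its gain in closed form", {
  # stimulus clamped to 1 makes the prediction equal a, so data 0.8 -> a ~ 0.8
  pw <- cfl_pathway(data.frame(name = c("S", "M"), role = c("stimulus", "measured")),
                    list(list(reactants = "S", product = "M")))
  des <- cfl_design(matrix(1, 1, 1, dimnames = list(NULL, "S")))
  meas <- cfl_measurements(matrix(0.8, 1, 1, dimnames = list(NULL, "M")))
  sol <- cfl_optimize(pw, des, meas, cfl_config(preset = "toy"))
  expect_equal(sol$params$a[1], 0.8, tolerance = 1e-4)
})

test_that("data generated at the initial guess keeps the optimizer at the start", {
  fx <- toy_fixture()
  nominal <- cfl_params(fx$pathway)  # a=1, p=0.5 = the nominal initial guess
  meas <- generate_dataset(nominal, fx$pathway, fx$design)
  sol <- cfl_optimize(fx$pathway, fx$design, meas, fx$config)
  expect_lt(sol$mae, 1e-4)
  expect_equal(sol$params$a, rep(1, 10), tolerance = 1e-3)
})

test_that("fitting toy data eliminates exactly the three inactive reactions", {
  fx <- toy_fixture()
  sol <- cfl_optimize(fx$pathway, fx$design, fx$measurements, fx$config)
  expect_lt(sol$mae, 0.02)
  expect_true(all(sol$params$a[fx$truth$inactive] < 0.05))
  expect_true(all(sol$params$a[-fx$truth$inactive] >= 0.05))
  # optimized never worse than the initial guess
  init_pred <- simulate_pathway(fx$pathway,
                                cfl_params(fx$pathway, a = sol$init$a, p = sol$init$p),
                                fx$design)
  expect_lte(sol$mae, cfl_mae(init_pred, fx$measurements) + 1e-9)
})

test_that("bounds-grid selection reports MAE per pair and prefers the narrower tie", {
  fx <- toy_fixture()
  grid <- list(c(0.3, 0.7), c(0.1, 0.4375), c(0.1, 2.0))
  sel <- select_bounds(fx$pathway, fx$design, fx$measurements, grid, fx$config)
  expect_equal(nrow(sel$report), 3)
  expect_true(all(c("p_lb", "p_ub", "mae", "seconds") %in% names(sel$report)))
  best_mae <- min(sel$report$mae)
  w <- which(sel$report$mae <= best_mae + 1e-12)
  widths <- sel$report$p_ub[w] - sel$report$p_lb[w]
  expect_equal(sel$bounds[2] - sel$bounds[1], min(widths))
  # single-pair grid returns that pair
  one <- select_bounds(fx$pathway, fx$design, fx$measurements,
                       list(c(0.3, 0.7)), fx$config)
  expect_equal(one$bounds, c(0.3, 0.7))
  # widening only the upper bound leaves the fit quality essentially unchanged
  mae_nar <- sel$report$mae[1]
  mae_wide <- select_bounds(fx$pathway, fx$design, fx$measurements,
                            list(c(0.3, 2.0)), fx$config)$report$mae[1]
  expect_lt(abs(mae_wide - mae_nar), 0.02)
})

test_that("multistart families are reproducible and prefix-stable", {
  fx <- toy_fixture()
  fam1 <- cfl_multistart(fx$pathway, fx$design, fx$measurements, fx$config,
                         n_runs = 3, seed = 5)
  fam2 <- cfl_multistart(fx$pathway, fx$design, fx$measurements, fx$config,
                         n_runs = 3, seed = 5)
  expect_identical(fam1$mae, fam2$mae)
  expect_identical(fam1$solutions[[1]]$params, fam2$solutions[[1]]$params)
  # n_runs = 1 equals a single optimize from that run's derived seed
  fam3 <- cfl_multistart(fx$pathway, fx$design, fx$measurements, fx$config,
                         n_runs = 1, seed = 5)
  expect_equal(fam3$mae[1], fam1$mae[1])
  # best-member MAE is non-increasing in family size (prefix property)
  bigger <- cfl_multistart(fx$pathway, fx$design, fx$measurements, fx$config,
                           n_runs = 5, seed = 5)
  expect_equal(bigger$mae[1:3], fam1$mae)
  expect_true(all(diff(cummin(bigger$mae)) <= 0))
})

test_that("gains are recovered on identifiable tree-structured networks", {
  deltas <- c()
  for (seed in 1:20) {
    n_sp <- 10 + seed %% 6
    pw <- random_pathway(n_sp, n_sp - 2, n_stimuli = 2, and_fraction = 0,
                         n_measured = 3, seed = 100 + seed)
    # every leaf measured so all reactions sit on a path to data
    producers <- vapply(pw$reactions, `[[`, "", "product")
    inputs <- unique(unlist(lapply(pw$reactions, function(r) r$reactants)))
    leaves <- setdiff(producers, inputs)
    pw$species$role[pw$species$name %in% leaves] <- "measured"
    des <- combinatorial_design(c("S1", "S2"))
    truth <- cfl_params(pw, a = 1, p = 0.5)
    meas <- generate_dataset(truth, pw, des)
    set.seed(seed)
    cfg <- cfl_config(preset = "toy"); cfg$init <- "random"
    sol <- cfl_optimize(pw, des, meas, cfg)
    deltas <- c(deltas, abs(sol$params$a - truth$a))
  }
  expect_lt(median(deltas), 0.05)
})

test_that("a non-convergent model propagates a convergence error from the fit", {
  pw <- cfl_pathway(data.frame(name = c("S", "X", "Y", "M"),
                               role = c("stimulus", "latent", "latent", "measured")),
                    list(list(reactants = "S", inhibitors = "Y", product = "X"),
                         list(reactants = "X", product = "Y"),
                         list(reactants = "X", product = "M")))
  des <- cfl_design(matrix(1, 1, 1, dimnames = list(NULL, "S")))
  meas <- cfl_measurements(matrix(0.5, 1, 1, dimnames = list(NULL, "M")))
  expect_error(cfl_optimize(pw, des, meas, cfl_config(preset = "toy")),
               "did not converge")
})
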