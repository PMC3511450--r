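feedback_fixture <- function() {
  des <- combinatorial_design("A")
  pw <- read_sif(system.file("extdata", "feedback_pair.sif", package = "cflopt"))
  list(pathway = assign_roles(pw, des, "C"), design = des)
}

crosstalk_fixture <- function() {
  des <- combinatorial_design(c("A1", "A2"))
  pw <- read_sif(system.file("extdata", "crosstalk_pair.sif", package = "cflopt"))
  pw <- assign_roles(pw, des, c("C1", "C2"))
  # C1 responds only to A1, C2 only to A2
  vals <- cbind(C1 = des$treatments[, "A1"], C2 = des$treatments[, "A2"])
  list(pathway = pw, design = des, measurements = cfl_measurements(vals))
}

test_that("a feedback pair with identical responses collapses into one compartment", {
  fx <- feedback_fixture()
  res <- compartmentalize(fx$pathway, fx$design)
  grouped <- res$map$compartments[lengths(res$map$compartments) > 1]
  expect_length(grouped, 1)
  expect_setequal(grouped[[1]], c("B1", "B2"))
  # A -> Cmp and Cmp -> C survive; B1<->B2 wiring is intra-compartment
  expect_equal(n_reactions(res$pathway), 2)
  expect_length(res$map$intra, 2)
})

test_that("species with distinct stimulus dependencies stay separate", {
  pw <- cfl_pathway(data.frame(name = c("S1", "S2", "N1", "N2", "M"),
                               role = c("stimulus", "stimulus", "latent",
                                        "latent", "measured")),
                    list(list(reactants = "S1", product = "N1"),
                         list(reactants = "S2", product = "N2"),
                         list(reactants = "N1", product = "M"),
                         list(reactants = "N2", product = "M")))
  des <- combinatorial_design(c("S1", "S2"))
  res <- compartmentalize(pw, des)
  # two singleton compartments: each node is the sole target of one stimulus
  expect_equal(lengths(res$map$compartments),
               setNames(c(1L, 1L), c("Cmp1", "Cmp2")))
  expect_equal(n_reactions(res$pathway), 4)
})

test_that("measured-node predictions are invariant under compartmentalization", {
  for (seed in 1:10) {
    fx <- random_fixture(seed, n_species = 15 + 2 * (seed %% 6),
                         n_reactions = 22 + 3 * (seed %% 6))
    res <- compartmentalize(fx$pathway, fx$design)
    measured <- fx$pathway$species$name[fx$pathway$species$role == "measured"]
    before <- simulate_pathway(fx$pathway, cfl_params(fx$pathway), fx$design)
    after <- simulate_pathway(res$pathway, cfl_params(res$pathway), fx$design)
    expect_lt(max(abs(before$x[measured, ] - after$x[measured, ])), 1e-9)
  }
})

test_that("compartments partition exactly the eligible species", {
  fx <- random_fixture(4, n_species = 20, n_reactions = 30)
  res <- compartmentalize(fx$pathway, fx$design)
  eligible <- fx$pathway$species$name[fx$pathway$species$role == "latent"]
  expect_setequal(unlist(res$map$compartments), eligible)
  expect_equal(sum(lengths(res$map$compartments)), length(eligible))
  treat <- c(fx$design$stimuli, fx$design$inhibitors)
  expect_length(intersect(unlist(res$map$compartments), treat), 0)
})

test_that("over-aggressive grouping is detected on the crosstalk example", {
  fx <- crosstalk_fixture()
  res <- compartmentalize(fx$pathway, fx$design)
  grouped <- res$map$compartments[lengths(res$map$compartments) > 1]
  expect_setequal(grouped[[1]], c("B1", "B2"))
  cfg <- cfl_config(preset = "toy")
  red_pw <- assign_roles(res$pathway, fx$design, c("C1", "C2"))
  sol_red <- cfl_optimize(red_pw, fx$design, fx$measurements, cfg)
  sol_full <- cfl_optimize(fx$pathway, fx$design, fx$measurements, cfg)
  expect_lt(sol_full$mae, 0.02)            # unreduced model fits the data
  expect_gt(sol_red$mae, sol_full$mae + 0.05)  # reduced model cannot
  rep <- compartmentalization_report(fx$pathway, res$pathway, res$map,
                                     fitted_mae = sol_red$mae)
  expect_true(rep$overaggressive)
})

test_that("identity reduction reports zero deltas and no warning", {
  pw <- cfl_pathway(data.frame(name = c("S", "M"), role = c("stimulus", "measured")),
                    list(list(reactants = "S", product = "M")))
  des <- combinatorial_design("S")
  res <- compartmentalize(pw, des)
  rep <- compartmentalization_report(pw, res$pathway, res$map, fitted_mae = 0.001)
  expect_equal(rep$species_before, rep$species_after)
  expect_equal(rep$reactions_before, rep$reactions_after)
  expect_equal(rep$parameters_after, 2 * n_reactions(res$pathway))
  expect_false(rep$overaggressive)
})

test_that("map_back transfers activities and flags intra-compartment edges", {
  fx <- feedback_fixture()
  res <- compartmentalize(fx$pathway, fx$design)
  meas <- generate_dataset(cfl_params(fx$pathway), fx$pathway, fx$design,
                           signals = "C")
  red_pw <- assign_roles(res$pathway, fx$design, "C")
  sol <- cfl_optimize(red_pw, fx$design, meas, cfl_config(preset = "toy"))
  mb <- map_back(sol, res$map, fx$pathway)
  expect_equal(nrow(mb$annotation), n_reactions(fx$pathway))
  expect_equal(sum(!mb$annotation$interrogated), 2)   # B1<->B2
  # A->B1 and A->B2 inherit the same compartment-level activity
  a_rows <- grep("^\\[[0-9]+\\] A ->", mb$annotation$reaction)
  expect_length(a_rows, 2)
  expect_equal(mb$annotation$activity[a_rows[1]],
               mb$annotation$activity[a_rows[2]])

  # identity map: annotation equals the solution's own activities
  pw1 <- cfl_pathway(data.frame(name = c("S", "M"), role = c("stimulus", "measured")),
                     list(list(reactants = "S", product = "M")))
  des1 <- combinatorial_design("S")
  res1 <- compartmentalize(pw1, des1)
  meas1 <- generate_dataset(cfl_params(pw1, a = 0.7), pw1, des1)
  sol1 <- cfl_optimize(res1$pathway, des1, meas1, cfl_config(preset = "toy"))
  mb1 <- map_back(sol1, res1$map, pw1)
  expect_equal(mb1$annotation$activity, unname(sol1$max_activity))
})

test_that("pruning removes exactly the planted inactive reactions then stops", {
  fx <- toy_fixture()
  res <- prune_reactions(fx$pathway, fx$design, fx$measurements, fx$config,
                         mae_tolerance = 0.01, n_restarts = 3, seed = 2)
  removed <- res$trace$reaction[res$trace$accepted]
  expect_setequal(removed, fx$truth$inactive)
  expect_equal(n_reactions(res$pathway), 7)
  expect_false(res$exhausted)
  # the rejected step is recorded and its MAE exceeds baseline + tolerance
  last <- res$trace[nrow(res$trace), ]
  expect_false(last$accepted)
  expect_gt(last$mae_after, res$baseline_mae + 0.01)
  # accepted steps never exceeded the tolerance
  expect_true(all(res$trace$mae_after[res$trace$accepted] <=
                  res$baseline_mae + 0.01))
})

test_that("a duplicate parallel reaction is redundant and pruned first", {
  fx <- toy_fixture()
  rx <- lapply(fx$pathway$reactions, function(r)
    list(reactants = r$reactants, inhibitors = r$inhibitors, product = r$product))
  rx[[length(rx) + 1]] <- list(reactants = "TNFa", product = "JNK")  # duplicate
  pw2 <- cfl_pathway(fx$pathway$species, rx)
  res <- prune_reactions(pw2, fx$design, fx$measurements, fx$config,
                         mae_tolerance = 0.01, n_restarts = 3, seed = 2)
  removed <- res$trace$reaction[res$trace$accepted]
  expect_true(11 %in% removed || 7 %in% removed)  # one of the two copies goes
  expect_true(all(res$trace$mae_after[res$trace$accepted] <=
                  res$baseline_mae + 0.01))
})

test_that("infinite tolerance prunes down to the null solution", {
  fx <- toy_fixture()
  res <- prune_reactions(fx$pathway, fx$design, fx$measurements, fx$config,
                         mae_tolerance = Inf, n_restarts = 2, seed = 2)
  expect_true(res$exhausted)
  expect_equal(n_reactions(res$pathway), 0)
  expect_equal(res$final_mae,
               null_mae(fx$pathway, fx$design, fx$measurements))
})
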