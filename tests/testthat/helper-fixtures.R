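# shared fixtures and independent oracles for the test suite

toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pw <- build_toy_model()
      des <- build_toy_design()
      truth <- toy_ground_truth(pw)
      cache <<- list(pathway = pw, design = des, truth = truth,
                     measurements = generate_dataset(truth$params, pw, des),
                     config = cfl_config(preset = "toy"))
    }
    cache
  }
})

# independent Boolean evaluation: plain logical propagation to a fixed point,
# no shared code with the simulation engine
boolean_oracle <- function(pathway, design) {
  nm <- pathway$species$name
  out <- matrix(NA, length(nm), n_experiments(design), dimnames = list(nm, NULL))
  for (k in seq_len(n_experiments(design))) {
    val <- setNames(rep(FALSE, length(nm)), nm)
    clamped <- colnames(design$treatments)
    val[clamped] <- design$treatments[k, ] == 1
    for (sweep in seq_len(length(nm) + 1)) {
      new <- setNames(rep(FALSE, length(nm)), nm)
      for (r in pathway$reactions) {
        on <- all(val[r$reactants]) && !any(val[r$inhibitors])
        new[r$product] <- new[r$product] || on
      }
      new[clamped] <- val[clamped]
      if (identical(new, val)) break
      val <- new
    }
    out[, k] <- val
  }
  out
}

# independent cycle detection by Kahn's algorithm on the species graph
has_cycle <- function(pathway) {
  nm <- pathway$species$name
  edges <- unique(do.call(rbind, lapply(pathway$reactions, function(r)
    cbind(src = c(r$reactants, r$inhibitors), tgt = r$product))))
  indeg <- setNames(rep(0L, length(nm)), nm)
  for (t in edges[, "tgt"]) indeg[t] <- indeg[t] + 1L
  queue <- nm[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    out <- edges[edges[, "src"] == v, "tgt"]
    for (t in out) {
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) queue <- c(queue, t)
    }
    edges <- edges[edges[, "src"] != v, , drop = FALSE]
  }
  seen < length(nm)
}

# deterministic small random fixture: pathway + full-factorial stimulus design
random_fixture <- function(seed, n_species = 12, n_reactions = 16,
                           n_stimuli = 3, ...) {
  pw <- random_pathway(n_species, n_reactions, n_stimuli = n_stimuli,
                       seed = seed, ...)
  des <- combinatorial_design(paste0("S", seq_len(n_stimuli)))
  list(pathway = pw, design = des)
}

reaction_set <- function(pathway) {
  sort(vapply(pathway$reactions, function(r)
    paste(paste(r$reactants, collapse = "+"),
          paste(r$inhibitors, collapse = "+"), r$product, sep = "|"), ""))
}
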