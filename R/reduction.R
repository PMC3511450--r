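# new pathway keeping the reactions at positions keep (species untouched)
.subset_reactions <- function(pathway, keep) {
  rx <- lapply(pathway$reactions[keep], function(r)
    list(reactants = r$reactants, inhibitors = r$inhibitors,
         product = r$product, group = NULL))
  # re-link shared parameter groups among the survivors
  old_grp <- vapply(pathway$reactions[keep], `[[`, 1L, "group")
  pw <- cfl_pathway(pathway$species, rx)
  for (g in unique(old_grp)) {
    members <- which(old_grp == g)
    for (m in members) pw$reactions[[m]]$group <- members[1]
  }
  pw
}

.reaction_key <- function(reactants, inhibitors, product) {
  paste(paste(reactants, collapse = "+"), paste(inhibitors, collapse = "+"),
        product, sep = "|")
}

#' Compartmentalize a pathway into equivalent classes
#'
#' Groups non-measured, non-stimulus, non-inhibitor species whose simulated
#' responses under nominal parameters (`a = 1, p = 0.5, n = 4`) are identical
#' across every experiment of the design: the data cannot distinguish such
#' species, so their internal wiring is not interrogable. Each group becomes a
#' compartment node `C1, C2, ...`; reactions are rewritten onto compartments,
#' duplicates are merged (the survivor keeps the smallest original id) and
#' reactions whose product compartment is among their own input compartments
#' (intra-compartment wiring) are dropped. Under nominal parameters the
#' reduced pathway reproduces the measured-node predictions of the original.
#'
#' @param pathway a [cfl_pathway] with roles assigned (see [assign_roles()]).
#' @param design a [cfl_design].
#' @param settings a [cfl_settings].
#' @param tol absolute tolerance for response equality (default 1e-9).
#' @return list with `pathway` (the reduced [cfl_pathway]) and `map` (a
#'   `cfl_compartments` object: `compartments`, full species `mapping`,
#'   `ungrouped`, `reaction_map` data.frame, and `intra` original reaction ids).
#' @export
compartmentalize <- function(pathway, design, settings = cfl_settings(),
                             tol = 1e-9) {
  if (!any(pathway$species$role == "measured"))
    stop("no measured species: call assign_roles() before compartmentalizing")
  treat <- c(design$stimuli, design$inhibitors)
  eligible <- pathway$species$name[pathway$species$role == "latent" &
                                   !pathway$species$name %in% treat]
  pred <- simulate_pathway(pathway, cfl_params(pathway), design, settings)
  X <- pred$x

  # greedy grouping of identical response rows
  compartments <- list()
  mapping <- setNames(pathway$species$name, pathway$species$name)
  for (sp in eligible) {
    placed <- FALSE
    for (ci in seq_along(compartments)) {
      rep_sp <- compartments[[ci]][1]
      if (max(abs(X[sp, ] - X[rep_sp, ])) <= tol) {
        compartments[[ci]] <- c(compartments[[ci]], sp)
        placed <- TRUE; break
      }
    }
    if (!placed) compartments[[length(compartments) + 1L]] <- sp
  }
  cn <- vapply(seq_along(compartments), function(i) paste0("Cmp", i), "")
  while (any(cn %in% pathway$species$name)) cn <- paste0("x", cn)
  names(compartments) <- cn
  for (ci in seq_along(compartments))
    mapping[compartments[[ci]]] <- names(compartments)[ci]

  # rewrite reactions onto compartments
  keys <- character(); new_rx <- list(); rmap <- integer(); intra <- integer()
  for (r in pathway$reactions) {
    R <- sort(unique(unname(mapping[r$reactants])))
    I <- sort(unique(unname(mapping[r$inhibitors])))
    P <- unname(mapping[r$product])
    # dropped as non-interrogable: self-input after rewriting, or a gate whose
    # reactant and inhibitor collapse onto one compartment (its input
    # b*(1-b) is identically 0 at the Boolean corners of the nominal regime)
    if (P %in% c(R, I) || length(intersect(R, I))) {
      intra <- c(intra, r$id); rmap[r$id] <- NA_integer_; next
    }
    key <- .reaction_key(R, I, P)
    hit <- match(key, keys)
    if (is.na(hit)) {
      keys <- c(keys, key)
      new_rx[[length(new_rx) + 1L]] <-
        list(reactants = R, inhibitors = I, product = P, orig_id = r$id)
      hit <- length(new_rx)
    }
    rmap[r$id] <- hit
  }
  keep_sp <- pathway$species[!pathway$species$name %in% unlist(compartments), ]
  sp <- if (length(compartments))
    rbind(keep_sp, data.frame(name = names(compartments), role = "latent",
                              stringsAsFactors = FALSE))
  else keep_sp
  reduced <- cfl_pathway(sp, lapply(new_rx, function(r) r[1:3]))
  map <- structure(list(
    compartments = compartments,
    mapping = mapping,
    ungrouped = setdiff(pathway$species$name, eligible),
    reaction_map = data.frame(original_id = seq_along(rmap), reduced_id = rmap),
    intra = intra,
    reduced_orig_id = vapply(new_rx, `[[`, 1L, "orig_id")
  ), class = "cfl_compartments")
  list(pathway = reduced, map = map)
}

#' @export
print.cfl_compartments <- function(x, ...) {
  sizes <- lengths(x$compartments)
  cat(sprintf("cfl_compartments: %d compartments (sizes %s), %d intra-compartment reaction(s)\n",
              length(x$compartments),
              if (length(sizes)) paste(sizes, collapse = ",") else "-",
              length(x$intra)))
  for (cn in names(x$compartments))
    cat(sprintf("  %s = {%s}\n", cn, paste(x$compartments[[cn]], collapse = ", ")))
  invisible(x)
}

#' Map a fitted reduced-model solution back onto the original PKN
#'
#' Every original reaction that crosses a compartment boundary inherits the
#' fitted maximum activity of its compartment-level counterpart; reactions
#' inside a compartment were never part of the optimization and are flagged
#' not interrogated.
#'
#' @param solution a `cfl_solution` fitted on the reduced pathway.
#' @param map the `cfl_compartments` object from [compartmentalize()].
#' @param original the original [cfl_pathway].
#' @return list with `pathway` (the original) and `annotation`, a data.frame
#'   with one row per original reaction: `id`, `reaction`, `activity` (NA for
#'   intra-compartment edges), `interrogated`.
#' @export
map_back <- function(solution, map, original) {
  if (nrow(map$reaction_map) != n_reactions(original))
    stop("compartment map does not match the original pathway")
  act <- solution$max_activity[map$reaction_map$reduced_id]
  annotation <- data.frame(
    id = map$reaction_map$original_id,
    reaction = vapply(original$reactions, .reaction_label, ""),
    activity = as.numeric(act),
    interrogated = !is.na(map$reaction_map$reduced_id))
  list(pathway = original, annotation = annotation)
}

#' Report the effect of compartmentalization
#'
#' Species/reaction/parameter counts before and after reduction, compartment
#' sizes, and a warning flag when the post-fit MAE exceeds `mae_threshold` --
#' the signature of over-aggressive grouping, where species were merged whose
#' targets respond differently in the data. A reduced-model fit should then be
#' compared against an unreduced fit.
#'
#' @param original,reduced the pathways before and after [compartmentalize()].
#' @param map the `cfl_compartments` object.
#' @param fitted_mae MAE of a fit on the reduced pathway (optional).
#' @param mae_threshold warning threshold on `fitted_mae` (default 0.05).
#' @return a `cfl_reduction_report` list.
#' @export
compartmentalization_report <- function(original, reduced, map,
                                        fitted_mae = NULL, mae_threshold = 0.05) {
  rep <- list(
    species_before = n_species(original), species_after = n_species(reduced),
    reactions_before = n_reactions(original), reactions_after = n_reactions(reduced),
    parameters_before = free_parameter_count(original),
    parameters_after = free_parameter_count(reduced),
    compartment_sizes = unname(lengths(map$compartments)),
    intra_reactions = length(map$intra),
    fitted_mae = fitted_mae,
    overaggressive = !is.null(fitted_mae) && fitted_mae > mae_threshold)
  structure(rep, class = "cfl_reduction_report")
}

#' @export
print.cfl_reduction_report <- function(x, ...) {
  cat(sprintf("reduction: species %d -> %d, reactions %d -> %d, parameters %d -> %d\n",
              x$species_before, x$species_after, x$reactions_before,
              x$reactions_after, x$parameters_before, x$parameters_after))
  if (!is.null(x$fitted_mae))
    cat(sprintf("  post-fit MAE %.2f%%%s\n", 100 * x$fitted_mae,
                if (x$overaggressive)
                  " -- WARNING: exceeds threshold; compartmentalization may be over-aggressive"
                else ""))
  invisible(x)
}

#' Iteratively prune low-activity reactions
#'
#' Starting from a multistart baseline fit, repeatedly removes the reaction
#' with the smallest maximum activity `max_k z_i^k` (ties to the smallest
#' reaction id), refits, and stops when the refit MAE exceeds the baseline MAE
#' by more than `mae_tolerance`, restoring the last removed reaction.
#' Reactions removable without an MAE penalty are either conflicting with the
#' data or non-identifiable; what remains is vital for the fit.
#'
#' @inheritParams cfl_objective
#' @param mae_tolerance allowed absolute MAE increase over baseline (default
#'   0.01); `Inf` removes everything down to the null solution.
#' @param n_restarts multistart restarts per refit (default 5).
#' @param seed integer seed for the refits.
#' @return list with `pathway` (the pruned [cfl_pathway]), `trace` (a
#'   `cfl_prune_trace` data.frame: `step`, `reaction`, `label`, `activity`,
#'   `mae_after`, `accepted`), `baseline_mae`, `final_mae`, `exhausted`.
#' @export
prune_reactions <- function(pathway, design, measurements,
                            config = cfl_config(), settings = cfl_settings(),
                            mae_tolerance = 0.01, n_restarts = 5L, seed = 1L) {
  base_fam <- cfl_multistart(pathway, design, measurements, config, settings,
                             n_runs = n_restarts, seed = seed)
  best <- base_fam$solutions[[base_fam$best]]
  baseline_mae <- best$mae
  current <- pathway
  orig_id <- seq_len(n_reactions(pathway))
  trace <- data.frame(step = integer(), reaction = integer(), label = character(),
                      activity = numeric(), mae_after = numeric(),
                      accepted = logical())
  step <- 0L; exhausted <- FALSE; final_mae <- baseline_mae
  repeat {
    if (!n_reactions(current)) { exhausted <- TRUE; break }
    step <- step + 1L
    cand <- which.min(best$max_activity)   # first minimum = smallest id
    label <- sub("^\\[[0-9]+\\]", sprintf("[%d]", orig_id[cand]),
                 .reaction_label(current$reactions[[cand]]))
    activity <- best$max_activity[[cand]]
    reduced <- .subset_reactions(current, setdiff(seq_len(n_reactions(current)), cand))
    if (!n_reactions(reduced)) {
      mae_after <- null_mae(reduced, design, measurements, settings)
      new_best <- NULL
    } else {
      fam <- cfl_multistart(reduced, design, measurements, config, settings,
                            n_runs = n_restarts, seed = seed + step)
      new_best <- fam$solutions[[fam$best]]
      mae_after <- new_best$mae
    }
    accepted <- mae_after <= baseline_mae + mae_tolerance
    trace <- rbind(trace, data.frame(step = step, reaction = orig_id[cand],
                                     label = label, activity = activity,
                                     mae_after = mae_after, accepted = accepted))
    if (!accepted) break          # restore: keep `current` as the result
    orig_id <- orig_id[-cand]
    current <- reduced
    final_mae <- mae_after
    if (is.null(new_best)) { exhausted <- TRUE; break }
    best <- new_best
  }
  class(trace) <- c("cfl_prune_trace", "data.frame")
  list(pathway = current, trace = trace, baseline_mae = baseline_mae,
       final_mae = final_mae, exhausted = exhausted)
}

#' Write a compartment map or prune trace as CSV
#'
#' @param x a `cfl_compartments` or `cfl_prune_trace`.
#' @param path output CSV path.
#' @export
write_reduction <- function(x, path) {
  if (inherits(x, "cfl_compartments")) {
    df <- data.frame(species = names(x$mapping), compartment = unname(x$mapping))
    write.csv(df, path, row.names = FALSE)
  } else if (inherits(x, "cfl_prune_trace")) {
    write.csv(as.data.frame(x), path, row.names = FALSE)
  } else stop("unsupported object")
  invisible(NULL)
}
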