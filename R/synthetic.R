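#' The 10-node toy signaling model
#'
#' A fixed demonstration pathway: stimuli TGFa and TNFa, inhibitor nodes
#' MEK12i and PI3Ki, latent PI3K, and five measured signals (MEK12, ERK12,
#' AKT, JNK, P38), wired through 10 reactions -- 4 AND gates, 4 NOT inputs
#' and 4 OR gates -- for 20 free parameters with the Hill coefficient fixed.
#' The wiring is pinned in the shipped SIF fixture
#' (`system.file("extdata", "toy_pkn.sif", package = "cflopt")`), which is the
#' single source of truth.
#'
#' @return a [cfl_pathway] with roles assigned.
#' @export
build_toy_model <- function() {
  pw <- read_sif(system.file("extdata", "toy_pkn.sif", package = "cflopt"))
  assign_roles(pw,
               cfl_design(matrix(0, 1, 4,
                                 dimnames = list(NULL, c("TGFa", "TNFa", "MEK12i", "PI3Ki"))),
                          inhibitors = c("MEK12i", "PI3Ki")),
               c("MEK12", "ERK12", "AKT", "JNK", "P38"))
}

#' The 3 x 3 toy experiment design
#'
#' Combinatorial treatment with stimuli (TGFa, TNFa, no-treatment) crossed
#' with inhibitors (MEK12i, PI3Ki, no-inhibitor): 9 experiments; with the 5
#' measured signals, a complete dataset has 45 cells.
#'
#' @return a [cfl_design] with 9 experiments.
#' @export
build_toy_design <- function() {
  stim <- rbind(c(0, 0), c(1, 0), c(0, 1))
  inh <- rbind(c(0, 0), c(1, 0), c(0, 1))
  tr <- cbind(stim[rep(1:3, each = 3), ], inh[rep(1:3, times = 3), ])
  colnames(tr) <- c("TGFa", "TNFa", "MEK12i", "PI3Ki")
  cfl_design(tr, inhibitors = c("MEK12i", "PI3Ki"))
}

#' Ground-truth parameters for the toy model
#'
#' All gains at 1 and midpoints at 0.5 except for three reactions whose gain
#' is 0: PI3K & NOT MEK12i -> MEK12, PI3K -> JNK, and PI3K -> P38. Data
#' generated from this truth lets a fit demonstrate that it eliminates
#' exactly those reactions.
#'
#' @param pathway the toy pathway from [build_toy_model()].
#' @return list with `params` (a [cfl_params]) and `inactive` (the ids of the
#'   three zero-gain reactions).
#' @export
toy_ground_truth <- function(pathway = build_toy_model()) {
  lab <- vapply(pathway$reactions, .reaction_label, "")
  inactive <- c(grep("PI3K & !MEK12i -> MEK12", lab, fixed = TRUE),
                grep("PI3K -> JNK", lab, fixed = TRUE),
                grep("PI3K -> P38", lab, fixed = TRUE))
  stopifnot(length(inactive) == 3)
  a <- rep(1, n_reactions(pathway)); a[inactive] <- 0
  list(params = cfl_params(pathway, a = a, p = 0.5), inactive = sort(inactive))
}

#' Generate a synthetic measurement set from known parameters
#'
#' Simulates the pathway under the design, keeps the measured species, adds
#' truncated-Gaussian noise (clipped back into \[0,1\] so the activation
#' domain is preserved), and returns a reproducible [cfl_measurements].
#'
#' @param params ground-truth [cfl_params].
#' @param pathway a [cfl_pathway] with measured roles assigned (or pass
#'   `signals`).
#' @param design a [cfl_design].
#' @param sd Gaussian noise standard deviation (default 0 = noiseless).
#' @param seed integer seed (only consulted when `sd > 0`).
#' @param signals measured species names (default: species with role
#'   `"measured"`).
#' @param settings a [cfl_settings].
#' @return a [cfl_measurements].
#' @export
generate_dataset <- function(params, pathway, design, sd = 0, seed = 1L,
                             signals = NULL, settings = cfl_settings()) {
  stopifnot(sd >= 0)
  if (is.null(signals))
    signals <- pathway$species$name[pathway$species$role == "measured"]
  if (!length(signals)) stop("no measured species; pass `signals`")
  pred <- simulate_pathway(pathway, params, design, settings)
  v <- t(pred$x[signals, , drop = FALSE])
  if (sd > 0) {
    set.seed(seed)
    v <- v + matrix(rnorm(length(v), 0, sd), nrow(v))
    v <- pmin(pmax(v, 0), 1)
  }
  colnames(v) <- signals
  cfl_measurements(v)
}

#' Full-factorial treatment design
#'
#' All 2^k on/off combinations of the given treatment species (stimuli plus
#' optional inhibitor nodes).
#'
#' @param stimuli character vector of stimulus names.
#' @param inhibitors character vector of inhibitor-node names.
#' @return a [cfl_design] with `2^(length(stimuli) + length(inhibitors))`
#'   experiments.
#' @export
combinatorial_design <- function(stimuli, inhibitors = character()) {
  treat <- c(stimuli, inhibitors)
  tr <- as.matrix(expand.grid(rep(list(c(0, 1)), length(treat))))
  colnames(tr) <- treat
  cfl_design(tr, inhibitors = inhibitors)
}

#' Single-plus-pairwise stimulus design
#'
#' One experiment per single stimulus and one per unordered stimulus pair,
#' optionally crossed with a list of inhibitor conditions (the no-inhibitor
#' condition is included when `inhibitor_conditions` is supplied). With 15
#' stimuli this yields the 120-treatment layout of large perturbation
#' screens.
#'
#' @param stimuli character vector of stimulus names.
#' @param inhibitors character vector of inhibitor-node names (columns).
#' @param inhibitor_conditions optional list of inhibitor subsets to cross
#'   with the stimulus conditions; `NULL` (default) applies no inhibitors.
#' @return a [cfl_design].
#' @export
pairwise_stimulus_design <- function(stimuli, inhibitors = character(),
                                     inhibitor_conditions = NULL) {
  n <- length(stimuli)
  conds <- c(lapply(seq_len(n), function(i) stimuli[i]),
             if (n >= 2) apply(utils::combn(n, 2), 2, function(ix) stimuli[ix],
                               simplify = FALSE))
  if (is.null(inhibitor_conditions)) inhibitor_conditions <- list(character())
  rows <- list()
  for (ic in inhibitor_conditions) for (sc in conds) {
    tr <- setNames(numeric(length(stimuli) + length(inhibitors)),
                   c(stimuli, inhibitors))
    tr[sc] <- 1; tr[ic] <- 1
    rows[[length(rows) + 1L]] <- tr
  }
  cfl_design(do.call(rbind, rows), inhibitors = inhibitors)
}

#' Generate a random gated pathway
#'
#' Builds a connected, acyclic-by-construction logic network: species are
#' ordered, every non-stimulus species receives at least one activating
#' reaction from an earlier species (so everything is reachable from the
#' stimuli), and extra reactions are added at random. A fraction of reactions
#' get a second AND input, and a fraction of those second inputs enter as NOT
#' (inhibitory) edges. With `cycles = TRUE` one extra feedback reaction is
#' appended between the two last latent species.
#'
#' @param n_species total species count.
#' @param n_reactions reaction count (must be at least
#'   `n_species - n_stimuli`).
#' @param n_stimuli number of stimulus species (default 3).
#' @param n_measured number of measured species, taken from the end of the
#'   species order (default: ~30% of the non-stimulus species, at least 1).
#' @param and_fraction probability that a reaction gains a second input.
#' @param not_fraction probability that a second input is inhibitory.
#' @param seed integer seed.
#' @param cycles append one feedback reaction (default FALSE).
#' @return a [cfl_pathway] with roles assigned.
#' @export
random_pathway <- function(n_species, n_reactions, n_stimuli = 3L,
                           n_measured = NULL, and_fraction = 0.25,
                           not_fraction = 0.1, seed = 1L, cycles = FALSE) {
  n_latent <- n_species - n_stimuli
  if (n_latent < 1) stop("need at least one non-stimulus species")
  if (n_reactions < n_latent)
    stop(sprintf("infeasible: %d reactions cannot reach %d non-stimulus species",
                 n_reactions, n_latent))
  stopifnot(and_fraction >= 0, and_fraction <= 1,
            not_fraction >= 0, not_fraction <= 1)
  if (is.null(n_measured)) n_measured <- max(1L, round(0.3 * n_latent))
  if (n_measured > n_latent) stop("more measured species than non-stimuli")
  set.seed(seed)
  stim <- paste0("S", seq_len(n_stimuli))
  latent <- paste0("N", seq_len(n_latent))
  order_names <- c(stim, latent)

  second_input <- function(pos, avoid) {
    pool <- setdiff(order_names[seq_len(pos - 1)], avoid)
    if (!length(pool) || runif(1) > and_fraction) return(NULL)
    inp <- sample(pool, 1)
    list(name = inp, not = runif(1) <= not_fraction)
  }
  rx <- list()
  for (t in seq_len(n_latent)) {
    pos <- n_stimuli + t
    src <- order_names[sample.int(pos - 1, 1)]
    extra <- second_input(pos, src)
    rx[[t]] <- list(reactants = c(src, if (!is.null(extra) && !extra$not) extra$name),
                    inhibitors = if (!is.null(extra) && extra$not) extra$name,
                    product = order_names[pos])
  }
  while (length(rx) < n_reactions) {
    tpos <- n_stimuli + sample.int(n_latent, 1)
    src <- order_names[sample.int(tpos - 1, 1)]
    extra <- second_input(tpos, src)
    cand <- list(reactants = c(src, if (!is.null(extra) && !extra$not) extra$name),
                 inhibitors = if (!is.null(extra) && extra$not) extra$name,
                 product = order_names[tpos])
    key <- .reaction_key(sort(cand$reactants), sort(cand$inhibitors %||% character()),
                         cand$product)
    if (!key %in% vapply(rx, function(r)
      .reaction_key(sort(r$reactants), sort(r$inhibitors %||% character()),
                    r$product), "")) rx[[length(rx) + 1L]] <- cand
  }
  if (cycles) {
    if (n_latent < 2) stop("cycles need at least two non-stimulus species")
    back <- list(reactants = latent[n_latent], inhibitors = NULL,
                 product = latent[n_latent - 1])
    # ensure the forward path exists so the back edge closes a directed cycle
    rx[[length(rx) + 1L]] <- list(reactants = latent[n_latent - 1],
                                  inhibitors = NULL, product = latent[n_latent])
    rx[[length(rx) + 1L]] <- back
  }
  sp <- data.frame(name = order_names, role = "latent", stringsAsFactors = FALSE)
  sp$role[seq_len(n_stimuli)] <- "stimulus"
  sp$role[(n_species - n_measured + 1):n_species] <- "measured"
  cfl_pathway(sp, rx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
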