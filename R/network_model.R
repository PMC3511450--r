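#' Construct a pathway (prior knowledge network with logic-gate semantics)
#'
#' A pathway is a set of species and a set of gated reactions. Each reaction
#' has up to two reactants, at most one inhibitor (a NOT input), and exactly
#' one product; several reactions producing the same species form an OR gate.
#' Reactions that originally listed several products are split into one
#' reaction per product; the `group` field ties the split copies to a shared
#' transfer-function parameter set.
#'
#' @param species character vector of species names, or a data.frame with
#'   columns `name` and `role` (role one of `"stimulus"`, `"inhibitor"`,
#'   `"measured"`, `"latent"`).
#' @param reactions list of reactions, each a list with elements `reactants`
#'   (character, length 0--2), `inhibitors` (character, length 0--1) and
#'   `product` (single name). An optional `group` element links reactions that
#'   share parameters.
#' @return An object of class `cfl_pathway`.
#' @seealso [read_sif()], [validate_pathway()], [build_toy_model()]
#' @export
cfl_pathway <- function(species, reactions) {
  if (is.character(species)) {
    species <- data.frame(name = species, role = "latent",
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(species), all(c("name", "role") %in% names(species)))
  if (anyDuplicated(species$name))
    stop("duplicate species names: ",
         paste(unique(species$name[duplicated(species$name)]), collapse = ", "))
  bad_role <- setdiff(species$role, c("stimulus", "inhibitor", "measured", "latent"))
  if (length(bad_role)) stop("unknown species role: ", paste(bad_role, collapse = ", "))

  rx <- lapply(seq_along(reactions), function(i) {
    r <- reactions[[i]]
    list(id         = i,
         reactants  = sort(unique(as.character(r$reactants))),
         inhibitors = sort(unique(as.character(r$inhibitors))),
         product    = as.character(r$product),
         group      = if (is.null(r$group)) i else as.integer(r$group))
  })
  pw <- structure(list(species = species, reactions = rx),
                  class = "cfl_pathway")
  err <- .pathway_errors(pw)
  if (length(err)) stop(paste(err, collapse = "\n"))
  pw
}

# hard invariants (construction-time errors, as opposed to validate_pathway()
# which only reports)
.pathway_errors <- function(pw) {
  nm <- pw$species$name
  errs <- character()
  for (r in pw$reactions) {
    card <- length(r$reactants) + length(r$inhibitors)
    if (card < 1 || card > 2)
      errs <- c(errs, sprintf("reaction %d: |R|+|I| = %d, must be 1 or 2", r$id, card))
    if (length(r$product) != 1)
      errs <- c(errs, sprintf("reaction %d: exactly one product required", r$id))
    unknown <- setdiff(c(r$reactants, r$inhibitors, r$product), nm)
    if (length(unknown))
      errs <- c(errs, sprintf("reaction %d: unknown species %s", r$id,
                              paste(unknown, collapse = ", ")))
    if (length(intersect(r$reactants, r$inhibitors)))
      errs <- c(errs, sprintf("reaction %d: reactants and inhibitors overlap", r$id))
  }
  errs
}

#' @export
print.cfl_pathway <- function(x, ...) {
  cat(sprintf("cfl_pathway: %d species, %d reactions (%d parameter groups)\n",
              nrow(x$species), length(x$reactions),
              length(unique(vapply(x$reactions, `[[`, 1L, "group")))))
  tab <- table(factor(x$species$role,
                      c("stimulus", "inhibitor", "measured", "latent")))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  for (r in x$reactions) cat(" ", .reaction_label(r), "\n")
  invisible(x)
}

.reaction_label <- function(r) {
  inputs <- c(r$reactants, if (length(r$inhibitors)) paste0("!", r$inhibitors))
  sprintf("[%d] %s -> %s", r$id, paste(inputs, collapse = " & "), r$product)
}

#' Number of species / reactions / free parameters
#'
#' With the Hill coefficient held fixed, every parameter group contributes two
#' free parameters (gain `a` and midpoint `p`).
#'
#' @param pathway a [cfl_pathway] object.
#' @return integer count.
#' @export
n_species <- function(pathway) nrow(pathway$species)

#' @rdname n_species
#' @export
n_reactions <- function(pathway) length(pathway$reactions)

#' @rdname n_species
#' @export
free_parameter_count <- function(pathway) {
  2L * length(unique(vapply(pathway$reactions, `[[`, 1L, "group")))
}

#' Reactions producing a species (the OR-gate index set)
#'
#' @param pathway a [cfl_pathway].
#' @param j species name.
#' @return integer vector of reaction ids whose product is `j`.
#' @export
producing_reactions <- function(pathway, j) {
  if (!j %in% pathway$species$name) stop("unknown species: ", j)
  ids <- vapply(pathway$reactions, function(r) if (r$product == j) r$id else NA_integer_,
                integer(1))
  sort(unique(ids[!is.na(ids)]))
}

#' Read a prior knowledge network from a SIF file
#'
#' Plain 3-column SIF: `source relation target`, whitespace- or tab-separated,
#' relation `1` (activating) or `-1` (inhibiting); `#` starts a comment.
#' AND gates use reserved and-nodes (`and1`, `and2`, ...): each input species
#' has an edge into the and-node (sign -1 marks a NOT input) and the and-node
#' has one edge per product out. Every other edge is a single-input reaction;
#' multiple edges into one target form an OR gate.
#'
#' @param path file path.
#' @return a validated [cfl_pathway]; all roles are `"latent"` until
#'   [assign_roles()] is applied.
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  edges <- list()
  for (ln in keep) {
    tok <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(tok) != 3 || !tok[2] %in% c("1", "-1"))
      stop(sprintf("%s:%d: malformed SIF line (need 'source 1|-1 target'): %s",
                   path, ln, trimws(lines[ln])))
    edges[[length(edges) + 1L]] <-
      list(src = tok[1], sign = as.integer(tok[2]), tgt = tok[3])
  }
  .pathway_from_edges(edges, path)
}

.is_and_node <- function(x) grepl("^and[0-9]+$", x)

.pathway_from_edges <- function(edges, origin = "<edges>") {
  src <- vapply(edges, `[[`, "", "src")
  tgt <- vapply(edges, `[[`, "", "tgt")
  sgn <- vapply(edges, `[[`, 1L, "sign")
  and_nodes <- unique(c(src[.is_and_node(src)], tgt[.is_and_node(tgt)]))
  species <- setdiff(unique(c(src, tgt)), and_nodes)

  reactions <- list()
  for (an in and_nodes) {
    ins <- which(tgt == an)
    outs <- which(src == an)
    if (!length(ins) || !length(outs))
      stop(sprintf("%s: dangling and-node '%s' (needs >=1 input and >=1 output edge)",
                   origin, an))
    if (any(.is_and_node(src[ins])) || any(.is_and_node(tgt[outs])))
      stop(sprintf("%s: and-node '%s' chained to another and-node", origin, an))
    if (any(sgn[outs] != 1L))
      stop(sprintf("%s: and-node '%s' has an inhibiting output edge", origin, an))
    grp <- length(reactions) + 1L
    for (o in outs) {
      reactions[[length(reactions) + 1L]] <-
        list(reactants  = src[ins][sgn[ins] == 1L],
             inhibitors = src[ins][sgn[ins] == -1L],
             product    = tgt[o],
             group      = grp)
    }
  }
  plain <- which(!.is_and_node(src) & !.is_and_node(tgt))
  for (e in plain) {
    reactions[[length(reactions) + 1L]] <-
      list(reactants  = if (sgn[e] == 1L) src[e] else character(),
           inhibitors = if (sgn[e] == -1L) src[e] else character(),
           product    = tgt[e],
           group      = length(reactions) + 1L)
  }
  # renumber groups so they coincide with the id of their first member
  pw <- cfl_pathway(species, reactions)
  grp <- vapply(pw$reactions, `[[`, 1L, "group")
  first <- tapply(vapply(pw$reactions, `[[`, 1L, "id"), grp, min)
  for (i in seq_along(pw$reactions))
    pw$reactions[[i]]$group <- as.integer(first[[as.character(grp[i])]])
  pw
}

#' Write a pathway to a SIF file
#'
#' Inverse of [read_sif()] up to reaction ordering: single-input reactions
#' become plain edges; two-input reactions are emitted through the and-node
#' convention. Reactions sharing a parameter group share one and-node.
#'
#' @param pathway a [cfl_pathway].
#' @param path output file path.
#' @export
write_sif <- function(pathway, path) {
  out <- c("# SIF (source relation target); and<N> nodes encode AND gates")
  and_ct <- 0L
  grp <- vapply(pathway$reactions, `[[`, 1L, "group")
  done_grp <- integer()
  for (r in pathway$reactions) {
    members <- pathway$reactions[grp == r$group]
    multi <- length(r$reactants) + length(r$inhibitors) > 1 || length(members) > 1
    if (!multi) {
      sign <- if (length(r$inhibitors)) "-1" else "1"
      input <- c(r$reactants, r$inhibitors)
      out <- c(out, paste(input, sign, r$product))
    } else {
      if (r$group %in% done_grp) next
      done_grp <- c(done_grp, r$group)
      and_ct <- and_ct + 1L
      an <- paste0("and", and_ct)
      out <- c(out,
               if (length(r$reactants)) paste(r$reactants, "1", an),
               if (length(r$inhibitors)) paste(r$inhibitors, "-1", an),
               vapply(members, function(m) paste(an, "1", m$product), ""))
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write SIF file: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(out, con)
  invisible(NULL)
}

#' Assign species roles from an experiment design and measurement set
#'
#' A species is a stimulus or inhibitor node iff it appears in the design's
#' treatment vocabulary, and measured iff the measurement set (or the `signals`
#' character vector) has a data column for it; everything else is latent.
#'
#' @param pathway a [cfl_pathway].
#' @param design a [cfl_design].
#' @param measurements a [cfl_measurements] object, or a character vector of
#'   measured species names.
#' @return the pathway with updated roles.
#' @export
assign_roles <- function(pathway, design, measurements = NULL) {
  signals <- if (is.character(measurements)) measurements else measurements$signals
  unknown <- setdiff(c(design$stimuli, design$inhibitors, signals),
                     pathway$species$name)
  if (length(unknown))
    stop("names not in pathway: ", paste(unknown, collapse = ", "))
  role <- rep("latent", nrow(pathway$species))
  role[pathway$species$name %in% signals] <- "measured"
  role[pathway$species$name %in% design$stimuli] <- "stimulus"
  role[pathway$species$name %in% design$inhibitors] <- "inhibitor"
  pathway$species$role <- role
  pathway
}

#' Validate a pathway (report-only)
#'
#' Reports, without mutating the pathway: gate-cardinality violations,
#' species unreachable from any stimulus (when no roles are assigned,
#' in-degree-0 species are taken as the sources), self-loops (a reaction whose
#' product is one of its own inputs), non-stimulus species with in-degree 0,
#' and reactions with no reactants (pure NOT inputs).
#'
#' @param pathway a [cfl_pathway].
#' @return a `cfl_validation` list with elements `violations`, `unreachable`,
#'   `self_loops`, `no_input`, `pure_not`, and logical `ok`.
#' @export
validate_pathway <- function(pathway) {
  nm <- pathway$species$name
  violations <- .pathway_errors(pathway)
  self_loops <- character()
  producers <- character()
  for (r in pathway$reactions) {
    if (r$product %in% c(r$reactants, r$inhibitors))
      self_loops <- c(self_loops, .reaction_label(r))
    producers <- c(producers, r$product)
  }
  # treatment nodes (stimuli and inhibitor nodes) are exogenous sources;
  # reachability is edge-wise (a directed path, not gate satisfiability)
  sources <- pathway$species$name[pathway$species$role %in% c("stimulus", "inhibitor")]
  no_input <- setdiff(nm, producers)
  if (!length(sources)) sources <- no_input
  reach <- sources
  repeat {
    new <- vapply(pathway$reactions, function(r) {
      inputs <- c(r$reactants, r$inhibitors)
      if (length(inputs) && any(inputs %in% reach)) r$product else NA_character_
    }, character(1))
    new <- setdiff(new[!is.na(new)], reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  pure_not <- vapply(pathway$reactions,
                     function(r) length(r$reactants) == 0, logical(1))
  structure(list(
    violations  = violations,
    unreachable = setdiff(nm, reach),
    self_loops  = self_loops,
    no_input    = setdiff(no_input, sources),
    pure_not    = vapply(pathway$reactions[pure_not], .reaction_label, ""),
    ok          = length(violations) == 0
  ), class = "cfl_validation")
}

#' @export
print.cfl_validation <- function(x, ...) {
  cat("cfl_validation:", if (x$ok) "no violations" else "VIOLATIONS", "\n")
  for (f in c("violations", "unreachable", "self_loops", "no_input", "pure_not"))
    if (length(x[[f]])) cat(sprintf("  %s: %s\n", f, paste(x[[f]], collapse = "; ")))
  invisible(x)
}

#' Transfer-function parameters for every reaction
#'
#' One row per reaction: gain `a` in \[0,1\], midpoint `p`, Hill coefficient
#' `n` (shared, fixed). Reactions in the same parameter group carry identical
#' values.
#'
#' @param pathway a [cfl_pathway].
#' @param a,p numeric scalars or vectors of length `n_reactions(pathway)`.
#' @param n Hill coefficient (positive, shared by all reactions; default 4).
#' @return a `cfl_params` data.frame with columns `id`, `group`, `a`, `p`, `n`.
#' @export
cfl_params <- function(pathway, a = 1.0, p = 0.5, n = 4) {
  n_r <- n_reactions(pathway)
  a <- rep_len(a, n_r); p <- rep_len(p, n_r)
  if (any(a < 0 | a > 1)) stop("gain a must lie in [0,1]")
  if (any(p <= 0)) stop("midpoint p must be positive")
  if (n <= 0) stop("Hill coefficient n must be positive")
  grp <- vapply(pathway$reactions, `[[`, 1L, "group")
  # enforce shared parameters within a group (first member wins)
  for (g in unique(grp)) {
    a[grp == g] <- a[which(grp == g)[1]]
    p[grp == g] <- p[which(grp == g)[1]]
  }
  structure(data.frame(id = seq_len(n_r), group = grp, a = a, p = p,
                       n = rep_len(n, n_r)),
            class = c("cfl_params", "data.frame"))
}
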