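#' Construct an experiment design
#'
#' An experiment is a treatment combination: a set of stimuli and a set of
#' inhibitor nodes that are clamped active (value 1) while all other treatment
#' species are clamped inactive (value 0). Non-treatment species are free and
#' determined by the network.
#'
#' @param treatments 0/1 matrix or data.frame, one row per experiment, one
#'   column per treatment species (column names are species names).
#' @param inhibitors character vector naming which treatment columns are
#'   inhibitor nodes; the remaining columns are stimuli.
#' @return an object of class `cfl_design`.
#' @export
cfl_design <- function(treatments, inhibitors = character()) {
  tr <- as.matrix(treatments)
  if (is.null(colnames(tr)) || !nrow(tr))
    stop("treatments needs column names and at least one experiment")
  if (!all(tr %in% c(0, 1))) stop("treatment values must be 0/1")
  if (!all(inhibitors %in% colnames(tr)))
    stop("inhibitors must name treatment columns")
  storage.mode(tr) <- "double"
  rownames(tr) <- NULL
  structure(list(treatments = tr,
                 stimuli    = setdiff(colnames(tr), inhibitors),
                 inhibitors = inhibitors),
            class = "cfl_design")
}

#' @rdname cfl_design
#' @param design a `cfl_design`.
#' @export
n_experiments <- function(design) nrow(design$treatments)

#' @export
print.cfl_design <- function(x, ...) {
  cat(sprintf("cfl_design: %d experiments, stimuli {%s}, inhibitors {%s}\n",
              n_experiments(x), paste(x$stimuli, collapse = ", "),
              paste(x$inhibitors, collapse = ", ")))
  invisible(x)
}

#' Construct a measurement set
#'
#' Measured activation values in \[0,1\] for (species, experiment) pairs.
#' `NA` cells are unmeasured and excluded from all objectives. Weights default
#' to 1 everywhere (all nodes equally important).
#'
#' @param values numeric matrix, one row per experiment, one column per
#'   measured species (column names are species names); `NA` = missing.
#' @param weights nonnegative numeric scalar or matrix conformable to `values`.
#' @return an object of class `cfl_measurements`.
#' @export
cfl_measurements <- function(values, weights = 1) {
  v <- as.matrix(values)
  if (is.null(colnames(v))) stop("values needs species column names")
  storage.mode(v) <- "double"
  rownames(v) <- NULL
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("measurements outside [0,1]; run normalize_measurements() first")
  w <- if (length(weights) == 1) matrix(weights, nrow(v), ncol(v)) else as.matrix(weights)
  if (!all(dim(w) == dim(v))) stop("weights not conformable to values")
  if (any(w < 0)) stop("weights must be nonnegative")
  structure(list(values = v, weights = w, signals = colnames(v)),
            class = "cfl_measurements")
}

#' @rdname cfl_measurements
#' @param measurements a `cfl_measurements`.
#' @export
n_measured_cells <- function(measurements) sum(!is.na(measurements$values))

#' @export
print.cfl_measurements <- function(x, ...) {
  cat(sprintf("cfl_measurements: %d experiments x %d signals, %d measured cells\n",
              nrow(x$values), ncol(x$values), n_measured_cells(x)))
  invisible(x)
}

#' Rescale raw measurements into the [0,1] activation domain
#'
#' Signals whose maximum exceeds 1 are divided by that maximum; signals
#' already inside \[0,1\] (including all-zero signals) are left untouched, so
#' the operation is idempotent. Negative raw values are refused: background
#' subtraction and the like belong upstream of this package.
#'
#' @param measurements a [cfl_measurements] built with raw values, or a
#'   numeric matrix with signal column names.
#' @return a [cfl_measurements] with all values in \[0,1\].
#' @export
normalize_measurements <- function(measurements) {
  v <- if (inherits(measurements, "cfl_measurements")) measurements$values else as.matrix(measurements)
  w <- if (inherits(measurements, "cfl_measurements")) measurements$weights else 1
  if (any(v < 0, na.rm = TRUE))
    stop("negative raw values; preprocess (background-correct) before normalizing")
  for (jc in seq_len(ncol(v))) {
    mx <- suppressWarnings(max(v[, jc], na.rm = TRUE))
    if (is.finite(mx) && mx > 1) v[, jc] <- v[, jc] / mx
  }
  cfl_measurements(v, w)
}

.parse_midas_header <- function(header) {
  kind <- sub(":.*$", "", header)
  name <- sub("^[A-Z]+:", "", header)
  if (!all(kind %in% c("TR", "DA", "DV")))
    stop("MIDAS header columns must be TR:, DA: or DV: (got ",
         paste(unique(setdiff(kind, c("TR", "DA", "DV"))), collapse = ", "), ")")
  list(kind = kind, name = name)
}

#' Read a perturbation dataset in MIDAS-dialect CSV
#'
#' Columns: `TR:<name>` 0/1 treatments, optional `DA:<name>` acquisition-time
#' columns (ignored beyond row averaging -- the model is single-time-point),
#' `DV:<name>` measured values. Rows with identical treatment patterns (e.g.
#' several time points or replicates) are averaged into one experiment.
#' Treatment species that appear as an inhibitor input of some reaction in the
#' pathway are classified as inhibitor nodes, the rest as stimuli. Raw values
#' above 1 trigger per-signal max rescaling via [normalize_measurements()].
#'
#' @param path CSV file path.
#' @param pathway a [cfl_pathway] used to resolve species names.
#' @return list with elements `design` ([cfl_design]) and `measurements`
#'   ([cfl_measurements]).
#' @export
read_midas <- function(path, pathway) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("MIDAS file has no data rows: ", path)
  hd <- .parse_midas_header(names(df))
  tr_cols <- which(hd$kind == "TR"); dv_cols <- which(hd$kind == "DV")
  if (!length(tr_cols) || !length(dv_cols))
    stop("MIDAS file needs at least one TR: and one DV: column")
  tr_names <- hd$name[tr_cols]; dv_names <- hd$name[dv_cols]
  unknown <- setdiff(c(tr_names, dv_names), pathway$species$name)
  if (length(unknown))
    stop("MIDAS species not present in pathway: ", paste(unknown, collapse = ", "))

  tr <- as.matrix(df[, tr_cols, drop = FALSE]); colnames(tr) <- tr_names
  dv <- as.matrix(df[, dv_cols, drop = FALSE]); colnames(dv) <- dv_names
  key <- apply(tr, 1, paste, collapse = "/")
  if (anyDuplicated(key))
    message("read_midas: averaging ", sum(duplicated(key)),
            " replicate/time-point row(s) into their treatment conditions")
  ukey <- unique(key)
  idx <- match(ukey, key)
  tr_u <- tr[idx, , drop = FALSE]
  dv_u <- vapply(ukey, function(k) {
    colMeans(dv[key == k, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(dv)))
  dv_u <- if (is.matrix(dv_u)) t(dv_u) else matrix(dv_u, ncol = 1)
  dv_u[is.nan(dv_u)] <- NA_real_
  colnames(dv_u) <- dv_names

  inhib_inputs <- unique(unlist(lapply(pathway$reactions, `[[`, "inhibitors")))
  design <- cfl_design(tr_u, inhibitors = intersect(tr_names, inhib_inputs))
  meas <- if (any(dv_u > 1, na.rm = TRUE)) normalize_measurements(dv_u)
          else cfl_measurements(dv_u)
  list(design = design, measurements = meas)
}

#' Write a design + measurement set as MIDAS-dialect CSV
#'
#' Round-trip stable with [read_midas()] up to row order and float formatting.
#' When the measurement set is `NULL` or fully unmeasured, only treatment
#' columns are written.
#'
#' @param design a [cfl_design].
#' @param measurements a [cfl_measurements] or `NULL`.
#' @param path output CSV path.
#' @param time acquisition time written into the `DA:ALL` column (default 30).
#' @export
write_midas <- function(design, measurements, path, time = 30) {
  out <- as.data.frame(design$treatments)
  names(out) <- paste0("TR:", colnames(design$treatments))
  if (!is.null(measurements) && n_measured_cells(measurements) > 0) {
    if (nrow(measurements$values) != n_experiments(design))
      stop("measurements and design disagree on the number of experiments")
    out[["DA:ALL"]] <- time
    dv <- as.data.frame(measurements$values)
    names(dv) <- paste0("DV:", measurements$signals)
    out <- cbind(out, dv)
  }
  tryCatch(write.csv(out, path, row.names = FALSE, quote = FALSE, na = ""),
           error = function(e) stop("cannot write MIDAS file: ", conditionMessage(e)))
  invisible(NULL)
}
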