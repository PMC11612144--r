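#' Construct a peptide quantification table
#'
#' Rows are keyed by (peptide sequence, modification-form id); columns are
#' samples. Values may be raw or log2-scale intensities; the `log2` and
#' `centered` flags record the state so that normalisation is idempotent.
#'
#' @param values Numeric matrix, rows = peptide forms, columns = samples.
#'   Missing values allowed (`NA`).
#' @param peptide Character vector of peptide sequences, one per row.
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (`"enzyme"` or `"buffer"`) and `replicate`; one row per column of
#'   `values`.
#' @param form_id Optional modification-form ids (default `"na"`).
#' @param log2,centered State flags for `values`.
#' @return An object of class `qpisa_quant`.
#' @export
quant_table <- function(values, peptide, samples, form_id = NULL,
                        log2 = FALSE, centered = FALSE) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(peptide),
            ncol(values) == nrow(samples),
            all(c("sample_id", "condition", "replicate") %in% names(samples)))
  if (!all(samples$condition %in% c("enzyme", "buffer"))) {
    stop("sample conditions must be 'enzyme' or 'buffer'")
  }
  if (!all(c("enzyme", "buffer") %in% samples$condition)) {
    stop("need at least one sample per condition")
  }
  if (is.null(form_id)) form_id <- rep("na", length(peptide))
  colnames(values) <- samples$sample_id
  structure(list(values = values, peptide = as.character(peptide),
                 form_id = as.character(form_id), samples = samples,
                 log2 = log2, centered = centered),
            class = "qpisa_quant")
}

#' @export
print.qpisa_quant <- function(x, ...) {
  cat("qpisa quantification table:", nrow(x$values), "peptide forms x",
      ncol(x$values), "samples",
      sprintf("(%s, %s)\n",
              if (x$log2) "log2" else "raw",
              if (x$centered) "median-centered" else "uncentered"))
  invisible(x)
}

#' Log2-transform and median-centre a quantification table
#'
#' Raw intensities are log2-transformed, then every sample column is shifted
#' so its median over non-missing values is zero. Tables already flagged as
#' centred are returned unchanged, so the step is idempotent.
#'
#' @param qt A `qpisa_quant`.
#' @return The normalised table (`log2 = TRUE`, `centered = TRUE`).
#' @export
log2_median_center <- function(qt) {
  stopifnot(inherits(qt, "qpisa_quant"))
  if (qt$centered) return(qt)
  v <- qt$values
  if (!qt$log2) {
    bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop("nonpositive raw intensities at (row, sample): ",
           paste(sprintf("(%d,%s)", bad[, 1], colnames(v)[bad[, 2]])[
             seq_len(min(5, nrow(bad)))], collapse = ", "))
    }
    v <- log2(v)
  }
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  v <- sweep(v, 2, med)
  qt$values <- v
  qt$log2 <- TRUE
  qt$centered <- TRUE
  qt
}

#' Left-censored imputation of missing intensities (MinProb)
#'
#' Each missing cell is drawn independently from a Gaussian centred on a low
#' quantile of all observed values -- emulating values missing because they
#' fell below the detection limit. The standard deviation is
#' `spread` times the median per-peptide (row) standard deviation.
#'
#' @param qt A normalised `qpisa_quant`.
#' @param seed Integer seed; the draw is fully determined by it.
#' @param q Quantile of observed values used as the mean (default 0.01).
#' @param spread Multiplier on the median row sd (default 0.3).
#' @return The table with no missing values.
#' @export
impute_minprob <- function(qt, seed = 1L, q = 0.01, spread = 0.3) {
  stopifnot(inherits(qt, "qpisa_quant"), q > 0, q < 1, spread > 0)
  v <- qt$values
  miss <- is.na(v)
  if (!any(miss)) return(qt)
  obs <- v[!miss]
  if (length(obs) == 0L) stop("no observed values to impute from")
  mu <- stats::quantile(obs, probs = q, names = FALSE)
  row_sd <- apply(v, 1, stats::sd, na.rm = TRUE)
  sd0 <- spread * stats::median(row_sd, na.rm = TRUE)
  if (!is.finite(sd0) || sd0 <= 0) sd0 <- spread * stats::sd(obs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  v[miss] <- stats::rnorm(sum(miss), mean = mu, sd = sd0)
  qt$values <- v
  qt
}

#' Filter a quantification table on mapping and intensity
#'
#' Drops rows whose peptide is unmapped or has an ambiguous N-terminal flank,
#' and rows whose mean log2 intensity falls below `min_log2_intensity`
#' (boundary inclusive: exactly at the threshold is kept). Counts removed per
#' filter are attached as attribute `"filter_log"`.
#'
#' @param qt Normalised `qpisa_quant`.
#' @param classified Classification data.frame ([classify_peptides()]).
#' @param min_log2_intensity Mean log2 intensity threshold (e.g. -4.7).
#' @return Filtered table.
#' @export
filter_quant <- function(qt, classified, min_log2_intensity = -Inf) {
  stopifnot(inherits(qt, "qpisa_quant"), qt$log2)
  idx <- match(qt$peptide, classified$peptide)
  unmapped <- is.na(idx) | classified$cls[idx] == "unmapped"
  ambiguous <- !unmapped & !is.na(classified$ambiguous_flank[idx]) &
    classified$ambiguous_flank[idx]
  means <- rowMeans(qt$values, na.rm = TRUE)
  low <- !unmapped & !ambiguous & means < min_log2_intensity
  keep <- !(unmapped | ambiguous | low)
  log <- c(unmapped = sum(unmapped), ambiguous_flank = sum(ambiguous),
           low_intensity = sum(low))
  qt$values <- qt$values[keep, , drop = FALSE]
  qt$peptide <- qt$peptide[keep]
  qt$form_id <- qt$form_id[keep]
  attr(qt, "filter_log") <- log
  qt
}

#' Collapse redundant modification forms to the most abundant
#'
#' Peptides carrying several modification forms (e.g. differing oxidation or
#' acetylation) are reduced to the single most abundant form by mean
#' intensity; exact ties keep the lexicographically smallest form id.
#'
#' @param qt A `qpisa_quant`.
#' @return Table with one row per peptide sequence; the number of rows
#'   removed is attached as attribute `"collapsed"`.
#' @export
collapse_forms <- function(qt) {
  stopifnot(inherits(qt, "qpisa_quant"))
  means <- rowMeans(qt$values, na.rm = TRUE)
  ord <- order(qt$peptide, -means, qt$form_id)
  first <- !duplicated(qt$peptide[ord])
  keep <- sort(ord[first])
  n_drop <- nrow(qt$values) - length(keep)
  qt$values <- qt$values[keep, , drop = FALSE]
  qt$peptide <- qt$peptide[keep]
  qt$form_id <- qt$form_id[keep]
  attr(qt, "collapsed") <- n_drop
  qt
}

#' Compute cleavage-oriented log2 fold changes
#'
#' Averages replicates within each condition and differences the means, signed
#' so that efficient cleavage is positive: substrate orientation is
#' buffer - enzyme (depletion), product orientation enzyme - buffer
#' (accumulation). Peptides shorter than 6 residues (no full hexamer) and
#' peptides with non-standard letters are dropped with a logged count.
#'
#' @param qt Normalised (and imputed) `qpisa_quant`.
#' @param orientation `"substrate"` or `"product"`.
#' @param classified Optional classification data.frame supplying `cls`.
#' @return data.frame of fold-change records: `peptide`, `cls`, `hexamer`
#'   (positions P2..P4'), `delta` (log2 units) and `mean_intensity`; dropped
#'   counts in attribute `"drop_log"`.
#' @export
compute_delta <- function(qt, orientation = c("substrate", "product"),
                          classified = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(qt, "qpisa_quant"), qt$log2)
  is_enz <- qt$samples$condition == "enzyme"
  if (!any(is_enz) || !all(xor(is_enz, qt$samples$condition == "buffer"))) {
    stop("need samples in both conditions")
  }
  enz <- rowMeans(qt$values[, is_enz, drop = FALSE], na.rm = TRUE)
  buf <- rowMeans(qt$values[, !is_enz, drop = FALSE], na.rm = TRUE)
  delta <- if (orientation == "substrate") buf - enz else enz - buf
  short <- nchar(qt$peptide) < 6L
  nonstd <- !short & !is_standard_seq(qt$peptide)
  keep <- !short & !nonstd
  rec <- data.frame(
    peptide = qt$peptide[keep],
    cls = NA_character_,
    hexamer = substr(qt$peptide[keep], 1L, 6L),
    delta = delta[keep],
    mean_intensity = rowMeans(qt$values, na.rm = TRUE)[keep],
    stringsAsFactors = FALSE
  )
  if (!is.null(classified)) {
    rec$cls <- classified$cls[match(rec$peptide, classified$peptide)]
  }
  attr(rec, "drop_log") <- c(too_short = sum(short),
                             nonstandard = sum(nonstd))
  rec
}
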