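#' Select foreground product peptides
#'
#' Foreground for product-based modelling: semi-tryptic (product) peptides
#' that accumulated by at least `min_delta` log2 units (product orientation),
#' with each sequence extended N-terminally by the cleavage offset so it
#' represents the cleaved substrate. Products too close to the protein
#' N-terminus to be extended are dropped with a logged count.
#'
#' @param records Product-orientation fold-change records
#'   ([compute_delta()]), typically restricted to semi-tryptic peptides.
#' @param locations Mapped locations for these peptides.
#' @param proteome A `protein_db`.
#' @param offset Residues removed per cleavage (default 2).
#' @param min_delta Minimum log2 fold increase (default 1).
#' @return Records with extended sequences, `provenance = "foreground"`;
#'   dropped counts in attribute `"drop_log"`.
#' @export
select_foreground <- function(records, locations, proteome, offset = 2L,
                              min_delta = 1) {
  rec <- records[records$delta >= min_delta, , drop = FALSE]
  n_low <- nrow(records) - nrow(rec)
  idx <- match(rec$peptide, locations$peptide)
  ok_map <- !is.na(idx) & locations$mapped[idx]
  rec <- rec[ok_map, , drop = FALSE]
  idx <- idx[ok_map]
  extendable <- locations$start[idx] - offset >= 1L
  n_edge <- sum(!extendable)
  rec <- rec[extendable, , drop = FALSE]
  idx <- idx[extendable]
  ext <- extend_n_terminus(locations[idx, , drop = FALSE], proteome, offset)
  rec$peptide <- ext
  rec$hexamer <- substr(ext, 1L, 6L)
  rec$provenance <- "foreground"
  attr(rec, "drop_log") <- c(below_min_delta = n_low,
                             unmapped = sum(!ok_map),
                             too_close_to_nterm = n_edge)
  rec
}

#' Build the background for product-based modelling
#'
#' Tryptic peptides whose intensity did not change upon incubation
#' (substrate-orientation depletion below `max_decrease`), with their
#' response fixed to 0. These peptides carry the proteome's skewed amino-acid
#' composition, the K/R depletion of tryptic digests and the detection bias
#' of the instrument, making them the appropriate null for the foreground.
#'
#' @param tryptic Substrate-orientation fold-change records of tryptic
#'   peptides.
#' @param max_decrease Maximum log2 fold decrease to count as unchanged
#'   (default 1).
#' @return Records with `delta = 0`, `provenance = "background"`.
#' @export
build_background <- function(tryptic, max_decrease = 1) {
  rec <- tryptic[tryptic$delta < max_decrease, , drop = FALSE]
  rec$delta <- 0
  rec$provenance <- "background"
  rec
}

#' Fit the product-based specificity model
#'
#' Concatenates foreground (accumulated products, N-terminally extended,
#' product-orientation response) and background (unchanged tryptic peptides
#' at response 0) and applies the same fitting and rearrangement machinery as
#' the substrate model, so the two parameter sets are directly comparable.
#'
#' @param foreground Output of [select_foreground()].
#' @param background Output of [build_background()].
#' @param reference Reference residue for dummy coding.
#' @param full_suite Also fit the twelve-model suite (default FALSE).
#' @return List: `fit` (final `qpisa` model), `params` (`qpisa_params`),
#'   `suite` (or NULL), `n_foreground`, `n_background`.
#' @export
fit_product_model <- function(foreground, background, reference = "A",
                              full_suite = FALSE) {
  cols <- c("peptide", "hexamer", "delta")
  fg <- foreground[, cols, drop = FALSE]; fg$provenance <- "foreground"
  bg <- background[, cols, drop = FALSE]; bg$provenance <- "background"
  rec <- rbind(fg, bg)
  fit <- qpisa(rec, reference = reference)
  list(fit = fit,
       params = rearrange(fit),
       suite = if (full_suite) run_model_suite(rec, reference) else NULL,
       n_foreground = nrow(fg),
       n_background = nrow(bg))
}
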