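#' Pipeline settings
#'
#' Homes for the thresholds that shape a qPISA run: the mean log2 intensity
#' floor (-4.7 in the reference experiment), the minimum product accumulation
#' (1 log2 unit), the background stability bound (depletion < 1), the
#' coverage audit depth (10 detection events) and the dipeptidyl cleavage
#' offset (2).
#'
#' @param min_log2_intensity Mean log2 intensity threshold (inclusive).
#' @param product_min_delta Foreground threshold, log2 units.
#' @param background_max_decrease Background stability bound, log2 units.
#' @param coverage_min_events Coverage audit depth.
#' @param offset Residues removed per cleavage.
#' @param impute_seed,impute_q,impute_spread MinProb imputation settings.
#' @param reference Dummy-coding reference residue.
#' @param init_met Accept initiator-Met-trimmed N-termini in classification.
#' @param product_model Fit the product-based model as well.
#' @param product_full_suite Fit all twelve models on the product data too.
#' @return Settings list for [run_pipeline()].
#' @export
pipeline_config <- function(min_log2_intensity = -4.7, product_min_delta = 1,
                            background_max_decrease = 1,
                            coverage_min_events = 10L, offset = 2L,
                            impute_seed = 1L, impute_q = 0.01,
                            impute_spread = 0.3, reference = "A",
                            init_met = TRUE, product_model = TRUE,
                            product_full_suite = FALSE) {
  stopifnot(is.finite(product_min_delta), is.finite(background_max_decrease),
            coverage_min_events >= 1L, offset >= 1L)
  list(min_log2_intensity = min_log2_intensity,
       product_min_delta = product_min_delta,
       background_max_decrease = background_max_decrease,
       coverage_min_events = as.integer(coverage_min_events),
       offset = as.integer(offset), impute_seed = as.integer(impute_seed),
       impute_q = impute_q, impute_spread = impute_spread,
       reference = reference, init_met = init_met,
       product_model = product_model,
       product_full_suite = product_full_suite)
}

#' Run the end-to-end qPISA pipeline
#'
#' Classification, preprocessing, substrate model suite, coefficient
#' rearrangement, logos, coverage audit and (optionally) the product-based
#' model, from a quantification table and a protein database.
#'
#' @param quant A `qpisa_quant` (raw or log2).
#' @param proteome A `protein_db`; may be NULL when `locations` is given.
#' @param locations Optional precomputed peptide locations (e.g. from a
#'   synthetic experiment); located from `proteome` when NULL.
#' @param config Settings from [pipeline_config()].
#' @return A `qpisa_run` bundle: `records`, `classified`, `suite`, `fit`
#'   (final model), `params`, `logo6`, `coverage`, `product` (or NULL),
#'   `matches` (product/substrate matching, or NULL) and `manifest` (config
#'   echo, versions, per-filter record counts).
#' @export
run_pipeline <- function(quant, proteome = NULL, locations = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(quant, "qpisa_quant"))
  if (is.null(locations)) {
    if (is.null(proteome)) stop("need a proteome or precomputed locations")
    locations <- locate_peptides(unique(quant$peptide), proteome)
  }
  classified <- classify_peptides(locations, init_met = config$init_met)

  qt <- log2_median_center(quant)
  if (anyNA(qt$values)) {
    qt <- impute_minprob(qt, seed = config$impute_seed, q = config$impute_q,
                         spread = config$impute_spread)
  }
  qt <- filter_quant(qt, classified, config$min_log2_intensity)
  filter_log <- attr(qt, "filter_log")
  qt <- collapse_forms(qt)
  collapsed <- attr(qt, "collapsed")

  rec <- compute_delta(qt, "substrate", classified)
  drop_log <- attr(rec, "drop_log")
  tryptic <- rec[rec$cls == "tryptic", , drop = FALSE]

  suite <- run_model_suite(tryptic, reference = config$reference)
  fit <- suite$fits[["final (+P2:P1 +P1:P1')"]]
  params <- rearrange(fit)
  logo6 <- linear_logo(suite$fits[["all six linear"]])
  coverage <- audit_coverage(tryptic, config$coverage_min_events)

  product <- NULL
  matches <- NULL
  if (config$product_model) {
    rec_p <- compute_delta(qt, "product", classified)
    semi <- rec_p[rec_p$cls == "semi_tryptic", , drop = FALSE]
    semi_loc <- classified[classified$peptide %in% semi$peptide &
                             classified$mapped, , drop = FALSE]
    tryp_loc <- classified[classified$peptide %in% tryptic$peptide &
                             classified$mapped, , drop = FALSE]
    matches <- match_products(semi_loc, tryp_loc, config$offset)
    if (is.null(proteome)) {
      warning("no proteome supplied; skipping the product-based model")
    } else if (nrow(semi) > 0L) {
      fg <- select_foreground(semi, semi_loc, proteome,
                              offset = config$offset,
                              min_delta = config$product_min_delta)
      bg <- build_background(tryptic, config$background_max_decrease)
      product <- fit_product_model(fg, bg, reference = config$reference,
                                   full_suite = config$product_full_suite)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("qpisa")),
    r_version = R.version.string,
    config = config,
    n_input_forms = nrow(quant$values),
    filtered = as.list(filter_log),
    collapsed_forms = collapsed,
    dropped_records = as.list(drop_log),
    n_records = nrow(rec),
    n_tryptic = nrow(tryptic),
    n_semi_tryptic = sum(rec$cls == "semi_tryptic"),
    n_models = length(suite$fits)
  )
  structure(list(records = rec, classified = classified, suite = suite,
                 fit = fit, params = params, logo6 = logo6,
                 coverage = coverage, product = product, matches = matches,
                 manifest = manifest),
            class = "qpisa_run")
}

#' @export
print.qpisa_run <- function(x, ...) {
  m <- x$manifest
  cat("qpisa pipeline run\n")
  cat("  records: ", m$n_records, " (", m$n_tryptic, " tryptic, ",
      m$n_semi_tryptic, " semi-tryptic); ", m$n_models,
      " models fitted\n", sep = "")
  cat(sprintf("  final model: adjusted R^2 = %.3f (n = %d, p = %d)\n",
              x$fit$adj_r2, x$fit$n, x$fit$p))
  if (!is.null(x$matches)) {
    cat(sprintf("  product matching: %d / %d products matched (%.1f%%)\n",
                x$matches$n_matched, x$matches$n_products,
                100 * x$matches$match_rate))
  }
  invisible(x)
}

#' Serialise a fitted model to JSON
#'
#' Coefficients are written with 17 significant digits so a reloaded model
#' predicts bit-identically.
#'
#' @param fit A `qpisa` model.
#' @param path Output path.
#' @export
write_model_json <- function(fit, path) {
  obj <- list(
    positions = fit$positions,
    interactions = fit$interactions,
    reference = fit$reference,
    coefficients = as.list(fit$coefficients),
    dropped = fit$dropped,
    n = fit$n, p = fit$p, r2 = fit$r2, adj_r2 = fit$adj_r2,
    triplet_counts = as.integer(fit$triplet_counts)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Reload a fitted model from JSON
#'
#' @param path Path written by [write_model_json()].
#' @return A `qpisa` model usable with [predict.qpisa()] and [rearrange()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cnt <- array(as.integer(obj$triplet_counts), dim = c(20L, 20L, 20L),
               dimnames = list(P2 = AA_ALPHABET, P1 = AA_ALPHABET,
                               P1p = AA_ALPHABET))
  interactions <- obj$interactions
  if (is.matrix(interactions)) {
    interactions <- lapply(seq_len(nrow(interactions)),
                           function(i) interactions[i, ])
  } else if (is.character(interactions)) {
    interactions <- list(interactions)
  } else if (is.null(interactions)) {
    interactions <- list()
  }
  structure(list(
    coefficients = unlist(obj$coefficients),
    dropped = as.character(obj$dropped %||% character()),
    positions = obj$positions,
    interactions = interactions,
    reference = obj$reference,
    n = obj$n, p = obj$p, r2 = obj$r2, adj_r2 = obj$adj_r2,
    fitted.values = NULL, residuals = NULL,
    triplet_counts = cnt,
    call = NULL
  ), class = "qpisa")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write rearranged parameters as a long-format table
#'
#' One row per entry of the three motif tables: 20 (term1) + 400 (term2) +
#' 400 (term3) = 820 value rows, with training support.
#'
#' @param params A `qpisa_params`.
#' @param path Output TSV path.
#' @export
write_params_tsv <- function(params, path) {
  df <- params_table(params)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params_tsv
#' @return `params_table()` returns the long-format data.frame itself.
#' @export
params_table <- function(params) {
  rbind(
    data.frame(term = "term1", res1 = names(params$term1), res2 = NA,
               value = as.numeric(params$term1),
               support = as.integer(params$support$term1)),
    data.frame(term = "term2",
               res1 = rep(rownames(params$term2), 20L),
               res2 = rep(colnames(params$term2), each = 20L),
               value = as.vector(params$term2),
               support = as.integer(params$support$term2)),
    data.frame(term = "term3",
               res1 = rep(rownames(params$term3), 20L),
               res2 = rep(colnames(params$term3), each = 20L),
               value = as.vector(params$term3),
               support = as.integer(params$support$term3))
  )
}

#' Write all artifacts of a pipeline run
#'
#' Fixed filenames under one results directory: fold-change records,
#' classification, model-suite summary, final model JSON, rearranged
#' parameters, six-position logo, coverage and manifest.
#'
#' @param bundle A `qpisa_run`.
#' @param dir Output directory (created if needed).
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "qpisa_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(bundle$records, "records.tsv")
  w(bundle$classified, "classification.tsv")
  w(bundle$suite$summary, "model_suite.tsv")
  write_model_json(bundle$fit, file.path(dir, "final_model.json"))
  write_params_tsv(bundle$params, file.path(dir, "params.tsv"))
  w(data.frame(residue = rownames(bundle$logo6), unclass(bundle$logo6),
               check.names = FALSE), "linear_logo.tsv")
  jsonlite::write_json(
    list(coverage = unclass(bundle$coverage), manifest = bundle$manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = I(17))
  if (!is.null(bundle$product)) {
    write_params_tsv(bundle$product$params, file.path(dir, "product_params.tsv"))
    write_model_json(bundle$product$fit, file.path(dir, "product_model.json"))
  }
  invisible(dir)
}

#' Read a quantification table and sample sheet from TSV
#'
#' Input schema: `peptide`, `form_id`, `protein_id`, then one intensity
#' column per sample; the sample sheet has `sample_id`, `condition`,
#' `replicate`.
#'
#' @param path Quantification TSV.
#' @param sample_sheet Sample sheet TSV.
#' @param log2,centered State flags for the intensity columns.
#' @return A `qpisa_quant`.
#' @export
read_quant_tsv <- function(path, sample_sheet, log2 = FALSE,
                           centered = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE)
  ss <- utils::read.delim(sample_sheet)
  miss <- setdiff(ss$sample_id, names(df))
  if (length(miss)) stop("sample columns missing from ", path, ": ",
                         paste(miss, collapse = ", "))
  vals <- as.matrix(df[, as.character(ss$sample_id), drop = FALSE])
  quant_table(vals, df$peptide, ss,
              form_id = if (!is.null(df$form_id)) df$form_id else NULL,
              log2 = log2, centered = centered)
}
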