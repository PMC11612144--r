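#' Build a dummy-coded design matrix over N-terminal positions
#'
#' Each position contributes a treatment-coded block: the 20-state residue
#' identity becomes 19 dummy columns, the reference residue being all zeros.
#' An interaction contributes the elementwise products of the two main-effect
#' blocks (up to 19 x 19 columns). Columns that are all zero (residues or
#' combinations absent from the data) are removed and recorded.
#'
#' @param seqs Character vector of sequences (length >= the largest position
#'   index used; hexamers for the full position set).
#' @param positions Character subset of `c("P2","P1","P1p","P2p","P3p","P4p")`.
#' @param interactions List of length-2 character vectors naming position
#'   pairs, each a subset of `positions`.
#' @param reference Reference residue for the treatment coding (default "A").
#' @param drop_empty Drop all-zero columns (default TRUE).
#' @return Numeric matrix with intercept column; attributes `labels` (full
#'   column label set before dropping), `dropped` (labels removed), and
#'   `assign_info`.
#' @export
build_design_matrix <- function(seqs, positions = c("P2", "P1", "P1p"),
                                interactions = list(c("P2", "P1"),
                                                    c("P1", "P1p")),
                                reference = "A", drop_empty = TRUE) {
  stopifnot(all(positions %in% names(QPISA_POSITIONS)),
            reference %in% AA_ALPHABET)
  for (ia in interactions) {
    if (length(ia) != 2L || !all(ia %in% positions)) {
      stop("each interaction must pair two of the model's positions")
    }
  }
  width <- max(QPISA_POSITIONS[positions])
  check_standard(substr(seqs, 1L, width), "model sequences")
  chars <- seq_to_matrix(seqs, width)
  levels <- c(reference, setdiff(AA_ALPHABET, reference))
  df <- data.frame(row.names = seq_along(seqs))
  for (pos in positions) {
    df[[pos]] <- factor(chars[, QPISA_POSITIONS[pos]], levels = levels)
  }
  terms <- c(positions,
             vapply(interactions, paste, "", collapse = ":"))
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, df)
  colnames(X) <- relabel_design(colnames(X), positions)
  labels <- colnames(X)
  dropped <- character()
  if (drop_empty) {
    empty <- colSums(X != 0) == 0
    empty[1L] <- FALSE  # never drop the intercept
    dropped <- labels[empty]
    X <- X[, !empty, drop = FALSE]
  }
  attr(X, "labels") <- labels
  attr(X, "dropped") <- dropped
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  X
}

# turn model.matrix names ("P1C", "P2C:P1pD") into canonical labels
# ("P1=C", "P2=C:P1'=D"); positions matched longest-first so P1p beats P1
relabel_design <- function(nms, positions) {
  pos_sorted <- positions[order(nchar(positions), decreasing = TRUE)]
  one <- function(part) {
    for (p in pos_sorted) {
      if (startsWith(part, p) && nchar(part) == nchar(p) + 1L) {
        return(paste0(position_label(p), "=", substr(part, nchar(p) + 1L,
                                                     nchar(part))))
      }
    }
    part
  }
  vapply(nms, function(nm) {
    if (nm == "(Intercept)") return(nm)
    paste(vapply(strsplit(nm, ":", fixed = TRUE)[[1]], one, ""),
          collapse = ":")
  }, "", USE.NAMES = FALSE)
}

#' Fit a protease specificity model
#'
#' Models the cleavage-oriented log2 fold change of each peptide as a linear
#' function of its N-terminal residue identities, dummy-coded, optionally with
#' pairwise subsite interaction terms, by ordinary least squares. The default
#' specification is the cooperative cleavage model: positions P2, P1, P1' with
#' P2:P1 and P1:P1' interactions.
#'
#' @param records Fold-change records ([compute_delta()]): a data.frame with
#'   at least `hexamer` (or `peptide`) and `delta`.
#' @param positions,interactions,reference Model specification; see
#'   [build_design_matrix()].
#' @return An object of class `qpisa`: coefficients (full label set, dropped
#'   levels fixed at 0), `n`, `p` (retained predictor columns excluding the
#'   intercept), `r2`, `adj_r2`, fitted values and residuals.
#' @seealso [rearrange()], [run_model_suite()], [predict.qpisa()]
#' @examples
#' sim <- simulate_qpisa(n_proteins = 40, seed = 1)
#' rec <- compute_delta(sim$quant, "substrate")
#' fit <- qpisa(rec[rec$delta > -Inf, ])
#' fit
#' @export
qpisa <- function(records, positions = c("P2", "P1", "P1p"),
                  interactions = list(c("P2", "P1"), c("P1", "P1p")),
                  reference = "A") {
  seqs <- if (!is.null(records$hexamer)) records$hexamer else records$peptide
  y <- records$delta
  stopifnot(is.character(seqs), is.numeric(y), length(seqs) == length(y))
  X <- build_design_matrix(seqs, positions, interactions, reference)
  n <- nrow(X)
  p <- ncol(X) - 1L
  if (n <= p) {
    stop("n (", n, ") must exceed the number of predictors (", p,
         "); supply more records or a simpler specification")
  }
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    warning("rank-deficient design (rank ", fit$rank, " < ", ncol(X),
            "); using the minimum-norm least-squares solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- drop(beta)
    names(beta) <- colnames(X)
    fitted <- drop(X %*% beta)
  } else {
    beta <- fit$coefficients
    fitted <- y - fit$residuals
  }
  labels <- attr(X, "labels")
  coefs <- stats::setNames(numeric(length(labels)), labels)
  coefs[names(beta)] <- beta
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  adj <- if (n > p + 1L) adjusted_r2(r2, n, p) else NA_real_
  structure(list(
    coefficients = coefs,
    dropped = attr(X, "dropped"),
    positions = positions,
    interactions = interactions,
    reference = reference,
    n = n, p = p, r2 = r2, adj_r2 = adj,
    fitted.values = fitted,
    residuals = y - fitted,
    triplet_counts = count_triplets(seqs),
    call = match.call()
  ), class = "qpisa")
}

# 20x20x20 table of observed (P2, P1, P1') triplets
count_triplets <- function(seqs) {
  f <- function(j) factor(substr(seqs, j, j), levels = AA_ALPHABET)
  table(P2 = f(1L), P1 = f(2L), P1p = f(3L))
}

#' Adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`: variance explained corrected for
#' the number of predictors, enabling fair comparison of models of different
#' complexity.
#'
#' @param r2 Coefficient of determination.
#' @param n Number of observations.
#' @param p Number of predictors (excluding the intercept).
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (any(n <= p + 1)) stop("adjusted R-squared requires n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' @export
print.qpisa <- function(x, ...) {
  ints <- if (length(x$interactions)) {
    paste(vapply(x$interactions,
                 function(i) paste(position_label(i), collapse = ":"), ""),
          collapse = ", ")
  } else "none"
  cat("qpisa specificity model\n")
  cat("  positions:   ", paste(position_label(x$positions), collapse = ", "),
      "\n  interactions:", ints,
      "\n  reference:   ", x$reference, "\n")
  cat(sprintf("  n = %d, p = %d (%d level(s) unobserved)\n",
              x$n, x$p, length(x$dropped)))
  cat(sprintf("  R^2 = %.4f, adjusted R^2 = %.4f\n", x$r2, x$adj_r2))
  invisible(x)
}

#' @export
summary.qpisa <- function(object, ...) {
  co <- coef(object)
  top <- co[names(co) != "(Intercept)"]
  top <- top[order(abs(top), decreasing = TRUE)]
  structure(list(fit = object, top = utils::head(top, 10L)),
            class = "summary.qpisa")
}

#' @export
print.summary.qpisa <- function(x, ...) {
  print(x$fit)
  cat("  largest coefficients (log2 units):\n")
  print(round(x$top, 4))
  invisible(x)
}

#' @export
coef.qpisa <- function(object, ...) object$coefficients

#' @export
residuals.qpisa <- function(object, ...) object$residuals

#' @export
fitted.qpisa <- function(object, ...) object$fitted.values

#' Predict cleavage scores for new sequences
#'
#' Scores are intercept plus the sum of matching coefficients. Residues or
#' combinations unobserved during fitting contribute 0 and are flagged in the
#' `"novel_levels"` attribute of the result.
#'
#' @param object A fitted `qpisa` model.
#' @param newdata Character vector of sequences (at least as long as the
#'   model's outermost position: triplets for the default specification,
#'   hexamers for six-position models).
#' @param ... Unused.
#' @return Numeric vector of predicted cleavage-oriented log2 fold changes.
#' @export
predict.qpisa <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  X <- build_design_matrix(newdata, object$positions, object$interactions,
                           object$reference, drop_empty = FALSE)
  pred <- drop(X %*% object$coefficients[colnames(X)])
  if (length(object$dropped)) {
    novel <- unname(rowSums(X[, object$dropped, drop = FALSE] != 0) > 0)
  } else {
    novel <- rep(FALSE, length(pred))
  }
  attr(pred, "novel_levels") <- novel
  pred
}

#' @export
plot.qpisa <- function(x, ...) {
  if (is_final_spec(x)) {
    plot(rearrange(x), ...)
  } else if (length(x$interactions) == 0L && length(x$positions) == 6L) {
    plot(linear_logo(x), ...)
  } else {
    co <- coef(x)
    co <- co[names(co) != "(Intercept)"]
    graphics::barplot(sort(co), las = 2, cex.names = 0.5,
                      ylab = "coefficient (log2)", ...)
  }
  invisible(x)
}

is_final_spec <- function(fit) {
  setequal(fit$positions, c("P2", "P1", "P1p")) &&
    length(fit$interactions) == 2L &&
    any(vapply(fit$interactions, setequal, TRUE, y = c("P2", "P1"))) &&
    any(vapply(fit$interactions, setequal, TRUE, y = c("P1", "P1p")))
}

# the canonical 12 model specifications, in presentation order
suite_specs <- function() {
  lin3 <- c("P2", "P1", "P1p")
  all6 <- names(QPISA_POSITIONS)
  list(
    `P2 only`            = list(positions = "P2",  interactions = list()),
    `P1 only`            = list(positions = "P1",  interactions = list()),
    `P1' only`           = list(positions = "P1p", interactions = list()),
    `P2' only`           = list(positions = "P2p", interactions = list()),
    `P3' only`           = list(positions = "P3p", interactions = list()),
    `P4' only`           = list(positions = "P4p", interactions = list()),
    `P2+P1+P1' linear`   = list(positions = lin3,  interactions = list()),
    `all six linear`     = list(positions = all6,  interactions = list()),
    `P2+P1+P1' +P2:P1'`  = list(positions = lin3,
                                interactions = list(c("P2", "P1p"))),
    `P2+P1+P1' +P2:P1`   = list(positions = lin3,
                                interactions = list(c("P2", "P1"))),
    `P2+P1+P1' +P1:P1'`  = list(positions = lin3,
                                interactions = list(c("P1", "P1p"))),
    `final (+P2:P1 +P1:P1')` = list(positions = lin3,
                                    interactions = list(c("P2", "P1"),
                                                        c("P1", "P1p")))
  )
}

#' Fit the twelve-model specificity suite
#'
#' Fits, on the same records, the six single-position models (P2..P4'), the
#' linear three-position and six-position models, and the three-position model
#' with each pairwise interaction set (P2:P1', P2:P1, P1:P1', and the final
#' model with both P2:P1 and P1:P1'), and compares them by adjusted R-squared.
#'
#' @param records Fold-change records (see [qpisa()]).
#' @param reference Reference residue for dummy coding.
#' @return A `qpisa_suite`: list of 12 `qpisa` fits plus a `summary`
#'   data.frame (model, n, p, r2, adj_r2) in presentation order.
#' @export
run_model_suite <- function(records, reference = "A") {
  specs <- suite_specs()
  fits <- lapply(specs, function(s) {
    qpisa(records, positions = s$positions, interactions = s$interactions,
          reference = reference)
  })
  summary <- data.frame(
    model = names(specs),
    n = vapply(fits, `[[`, 0L, "n"),
    p = vapply(fits, `[[`, 0L, "p"),
    r2 = vapply(fits, `[[`, 0, "r2"),
    adj_r2 = vapply(fits, `[[`, 0, "adj_r2"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(fits = fits, summary = summary), class = "qpisa_suite")
}

#' @export
print.qpisa_suite <- function(x, ...) {
  cat("qpisa model suite (", nrow(x$summary), " models, n = ",
      x$summary$n[1], " records)\n", sep = "")
  df <- x$summary
  df$`adj R2 (%)` <- sprintf("%.1f", 100 * df$adj_r2)
  print(df[, c("model", "p", "adj R2 (%)")], row.names = FALSE)
  invisible(x)
}

#' @export
plot.qpisa_suite <- function(x, ...) {
  graphics::barplot(rev(100 * x$summary$adj_r2),
                    names.arg = rev(x$summary$model), horiz = TRUE,
                    las = 1, cex.names = 0.7,
                    xlab = "variance explained, adjusted R2 (%)", ...)
  invisible(x)
}

#' Audit sequence-space coverage of the records
#'
#' Reports how many of the 8000 (20^3) tripeptide combinations and of the
#' 1200 (3 x 20^2) pairwise dipeptide combinations (P2:P1, P1:P1', P2:P1')
#' are observed in at least `min_events` records -- the sampling depth that
#' bounds how much of the motif space the model can estimate.
#'
#' @param records Fold-change records.
#' @param min_events Minimum detection events per combination (default 10).
#' @return A `qpisa_coverage` list: per-space size and covered count.
#' @export
audit_coverage <- function(records, min_events = 10L) {
  stopifnot(min_events >= 1L)
  seqs <- if (!is.null(records$hexamer)) records$hexamer else records$peptide
  tri <- count_triplets(seqs)
  pair_cov <- function(i, j) {
    f <- function(k) factor(substr(seqs, k, k), levels = AA_ALPHABET)
    sum(table(f(i), f(j)) >= min_events)
  }
  structure(list(
    min_events = min_events,
    tripeptide = list(space = 20L^3, covered = sum(tri >= min_events)),
    dipeptide = list(
      space = 3L * 20L^2,
      P2_P1 = pair_cov(1L, 2L),
      P1_P1p = pair_cov(2L, 3L),
      P2_P1p = pair_cov(1L, 3L)
    )
  ), class = "qpisa_coverage")
}

#' @export
print.qpisa_coverage <- function(x, ...) {
  d <- x$dipeptide
  cat(sprintf("coverage at >= %d detection events per combination:\n",
              x$min_events))
  cat(sprintf("  tripeptides: %d / %d\n", x$tripeptide$covered,
              x$tripeptide$space))
  cat(sprintf("  dipeptides:  %d / %d (P2:P1 %d, P1:P1' %d, P2:P1' %d)\n",
              d$P2_P1 + d$P1_P1p + d$P2_P1p, d$space,
              d$P2_P1, d$P1_P1p, d$P2_P1p))
  invisible(x)
}
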