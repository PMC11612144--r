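all_triplets <- function() {
  g <- expand.grid(P2 = AA_ALPHABET, P1 = AA_ALPHABET, P1p = AA_ALPHABET,
                   stringsAsFactors = FALSE)
  paste0(g$P2, g$P1, g$P1p)
}

#' Rearrange fitted coefficients into the three cleavage-motif tables
#'
#' Converts the final cooperative model (P2, P1, P1' with P2:P1 and P1:P1'
#' interactions) into its canonical three-term form: a P1 table (absorbing the
#' intercept and all centring shifts), a P2-given-P1 table and a P1'-given-P1
#' table, whose sum reproduces the model prediction for every one of the
#' 8000 triplets exactly. Construction: with yhat(b,a,c) the model prediction
#' over the full triplet space (unobserved levels contributing 0),
#' `term1(a)` is the mean of yhat over b and c; `term2(b,a)` the mean over c
#' minus term1; `term3(a,c)` the mean over b minus term1 -- all means uniform
#' over the 20 residues. The folding proceeds through an intermediate
#' four-term form (intercept, P1, P2:P1, P1:P1'), returned alongside.
#'
#' @param fit A `qpisa` model over (a subset of) positions P2, P1, P1' whose
#'   interactions are a subset of {P2:P1, P1:P1'}; with a P2:P1' term the
#'   three-term decomposition is no longer exact and rearrangement refuses.
#' @return A `qpisa_params` object: `term1` (20 values), `term2`, `term3`
#'   (20 x 20 matrices, rows = context residue, columns/rows = P1 as named),
#'   `support` (training observation counts per entry) and `intermediate`.
#' @export
rearrange <- function(fit) {
  stopifnot(inherits(fit, "qpisa"))
  ok_pos <- all(fit$positions %in% c("P2", "P1", "P1p"))
  ok_int <- all(vapply(fit$interactions, function(i) {
    setequal(i, c("P2", "P1")) || setequal(i, c("P1", "P1p"))
  }, TRUE))
  if (!ok_pos || !ok_int) {
    stop("rearrange() requires a model over P2, P1, P1' whose interactions ",
         "are a subset of {P2:P1, P1:P1'} (the three-term decomposition is ",
         "exact only without a P2:P1' term)")
  }
  yhat <- predict(fit, all_triplets())
  Y <- array(as.numeric(yhat), dim = c(20L, 20L, 20L),
             dimnames = list(P2 = AA_ALPHABET, P1 = AA_ALPHABET,
                             P1p = AA_ALPHABET))
  term1 <- apply(Y, 2L, mean)
  term2 <- sweep(apply(Y, c(1L, 2L), mean), 2L, term1)  # [P2, P1]
  term3 <- sweep(apply(Y, c(2L, 3L), mean), 1L, term1)  # [P1, P1']
  cnt <- fit$triplet_counts
  support <- list(
    term1 = apply(cnt, 2L, sum),
    term2 = apply(cnt, c(1L, 2L), sum),
    term3 = apply(cnt, c(2L, 3L), sum)
  )
  grand <- mean(Y)
  structure(list(
    term1 = term1, term2 = term2, term3 = term3, support = support,
    intermediate = list(intercept = grand, P1 = term1 - grand,
                        P2_P1 = term2, P1_P1p = term3)
  ), class = "qpisa_params")
}

new_params <- function(term1, term2, term3, support) {
  grand <- mean(term1)
  structure(list(term1 = term1, term2 = term2, term3 = term3,
                 support = support,
                 intermediate = list(intercept = grand, P1 = term1 - grand,
                                     P2_P1 = term2, P1_P1p = term3)),
            class = "qpisa_params")
}

#' @export
print.qpisa_params <- function(x, ...) {
  cat("qpisa cleavage-motif parameters (term1[P1] + term2[P2,P1] +",
      "term3[P1,P1'])\n")
  t1 <- x$term1[x$support$term1 > 0]  # hide unobserved P1 residues
  ord <- order(t1, decreasing = TRUE)
  k <- min(5L, length(t1))
  cat("  top P1 residues:",
      paste(sprintf("%s=%.2f", names(t1)[ord][seq_len(k)],
                    t1[ord][seq_len(k)]), collapse = ", "), "\n")
  cat("  entries with zero training support:",
      sum(x$support$term2 == 0) + sum(x$support$term3 == 0),
      "of 800 pairwise\n")
  invisible(x)
}

#' Score peptide triplets with rearranged parameters
#'
#' The predicted cleavage efficiency of a peptide is the sum of the three
#' contributions of its (P2, P1, P1') triplet -- its first three residues for
#' a dipeptidyl peptidase substrate.
#'
#' @param params A `qpisa_params` object.
#' @param seqs Character vector of sequences (first three residues used).
#' @return Numeric scores (log2 units); attribute `"zero_support"` flags
#'   triplets containing an entry never observed during training.
#' @export
score_triplets <- function(params, seqs) {
  stopifnot(inherits(params, "qpisa_params"))
  check_standard(substr(seqs, 1L, 3L), "triplets")
  b <- substr(seqs, 1L, 1L)
  a <- substr(seqs, 2L, 2L)
  cc <- substr(seqs, 3L, 3L)
  sc <- params$term1[a] + params$term2[cbind(b, a)] +
    params$term3[cbind(a, cc)]
  names(sc) <- NULL
  attr(sc, "zero_support") <- params$support$term1[a] == 0 |
    params$support$term2[cbind(b, a)] == 0 |
    params$support$term3[cbind(a, cc)] == 0
  sc
}

#' @rdname score_triplets
#' @param object A `qpisa_params` object.
#' @param newdata Sequences to score.
#' @param ... Unused.
#' @export
predict.qpisa_params <- function(object, newdata, ...) {
  score_triplets(object, newdata)
}

#' Differential cleavage-motif parameters
#'
#' Entrywise difference of two rearranged parameter sets; rendering the
#' result as a logo depicts the specificity differences between two enzymes.
#' Support becomes the entrywise minimum.
#'
#' @param a,b `qpisa_params` objects.
#' @return A `qpisa_params` object holding `a - b`.
#' @export
differential_params <- function(a, b) {
  stopifnot(inherits(a, "qpisa_params"), inherits(b, "qpisa_params"))
  new_params(a$term1 - b$term1, a$term2 - b$term2, a$term3 - b$term3,
             list(term1 = pmin(a$support$term1, b$support$term1),
                  term2 = pmin(a$support$term2, b$support$term2),
                  term3 = pmin(a$support$term3, b$support$term3)))
}

params_vector <- function(p) {
  c(stats::setNames(p$term1, paste0("P1=", names(p$term1))),
    stats::setNames(as.vector(p$term2),
                    outer(rownames(p$term2), colnames(p$term2),
                          function(b, a) paste0("P2=", b, ":P1=", a))),
    stats::setNames(as.vector(p$term3),
                    outer(rownames(p$term3), colnames(p$term3),
                          function(a, cc) paste0("P1=", a, ":P1'=", cc))))
}

support_vector <- function(p) {
  c(p$support$term1, as.vector(p$support$term2), as.vector(p$support$term3))
}

#' Correlate two sets of cleavage-motif parameters
#'
#' Pearson correlation over the concatenated 820 entries (term1, term2,
#' term3), restricted to entries observed at least `min_support` times in
#' both training sets. Used to compare enzymes, replicates, or the
#' substrate- and product-based models.
#'
#' @param a,b `qpisa_params` objects.
#' @param min_support Minimum training support per entry in both sets.
#' @return Pearson correlation coefficient; attributes `"n_entries"`.
#' @export
compare_params <- function(a, b, min_support = 1L) {
  va <- params_vector(a); vb <- params_vector(b)
  keep <- support_vector(a) >= min_support & support_vector(b) >= min_support
  if (sum(keep) < 3L) stop("fewer than 3 entries with sufficient support")
  r <- stats::cor(va[keep], vb[keep])
  attr(r, "n_entries") <- sum(keep)
  r
}

#' Position-wise logo from the six-position linear model
#'
#' For each of the six positions, re-inserts the reference residue at zero
#' and mean-centres the 20 coefficient values; the centred values are the
#' signed letter heights of a single-stack sequence logo (positive = promotes
#' cleavage, negative = disfavours it).
#'
#' @param fit A `qpisa` model over all six positions with no interactions.
#' @return A `qpisa_logo`: 20 x 6 numeric matrix (residues x positions).
#' @export
linear_logo <- function(fit) {
  stopifnot(inherits(fit, "qpisa"))
  if (length(fit$interactions) != 0L ||
      !setequal(fit$positions, names(QPISA_POSITIONS))) {
    stop("linear_logo() requires the six-position linear specification")
  }
  co <- coef(fit)
  m <- matrix(0, 20L, 6L,
              dimnames = list(AA_ALPHABET,
                              position_label(names(QPISA_POSITIONS))))
  for (pos in names(QPISA_POSITIONS)) {
    lab <- position_label(pos)
    v <- stats::setNames(numeric(20L), AA_ALPHABET)
    for (r in setdiff(AA_ALPHABET, fit$reference)) {
      v[r] <- co[paste0(lab, "=", r)]
    }
    m[, lab] <- v - mean(v)
  }
  structure(m, class = c("qpisa_logo", class(m)))
}

#' @export
print.qpisa_logo <- function(x, digits = 3, ...) {
  cat("qpisa linear sequence logo (letter heights, log2 units)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

# draw one signed letter stack at horizontal slot i
draw_stack <- function(i, heights, width = 0.8, col_pos = "#1b7837",
                       col_neg = "#762a83") {
  up <- sort(heights[heights > 0])
  dn <- sort(heights[heights < 0], decreasing = TRUE)
  y <- 0
  for (r in names(up)) {
    h <- up[[r]]
    graphics::text(i, y + h / 2, r, cex = min(3, 0.4 + 2.4 * h),
                   col = col_pos)
    y <- y + h
  }
  y <- 0
  for (r in names(dn)) {
    h <- dn[[r]]
    graphics::text(i, y + h / 2, r, cex = min(3, 0.4 + 2.4 * abs(h)),
                   col = col_neg)
    y <- y + h
  }
}

#' @export
plot.qpisa_logo <- function(x, ...) {
  m <- unclass(x)
  ylim <- range(c(colSums(pmax(m, 0)), colSums(pmin(m, 0)), 0))
  graphics::plot(NULL, xlim = c(0.5, ncol(m) + 0.5), ylim = ylim,
                 xaxt = "n", xlab = "position",
                 ylab = "contribution to cleavage (log2)", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m))
  graphics::abline(h = 0, col = "grey")
  for (i in seq_len(ncol(m))) {
    h <- m[, i]
    draw_stack(i, stats::setNames(h, rownames(m)))
  }
  invisible(x)
}

#' Multi-panel cleavage-motif logo
#'
#' For each selected P1 residue, draws a triplet panel: the P2 stack
#' (`term2[, P1]`), the P1 contribution (`term1[P1]`) and the P1' stack
#' (`term3[P1, ]`). The total efficiency of a triplet is the sum of the three
#' contributions.
#'
#' @param x A `qpisa_params` object.
#' @param p1 P1 residues to panel (default: the four highest `term1`).
#' @param ... Passed to `plot`.
#' @export
plot.qpisa_params <- function(x, p1 = NULL, ...) {
  if (is.null(p1)) {
    p1 <- names(sort(x$term1, decreasing = TRUE))[1:4]
  }
  old <- graphics::par(mfrow = c(1, length(p1)), mar = c(3, 3, 2, 0.5))
  on.exit(graphics::par(old))
  for (a in p1) {
    vals <- c(x$term2[, a], x$term1[a], x$term3[a, ])
    ylim <- range(c(sum(pmax(x$term2[, a], 0)), sum(pmin(x$term2[, a], 0)),
                    x$term1[a],
                    sum(pmax(x$term3[a, ], 0)), sum(pmin(x$term3[a, ], 0)), 0))
    graphics::plot(NULL, xlim = c(0.5, 3.5), ylim = ylim, xaxt = "n",
                   xlab = "", ylab = "contribution (log2)",
                   main = paste0("P1 = ", a), ...)
    graphics::axis(1, at = 1:3, labels = c("P2", "P1", "P1'"))
    graphics::abline(h = 0, col = "grey")
    draw_stack(1, x$term2[, a])
    draw_stack(2, stats::setNames(x$term1[a], a))
    draw_stack(3, x$term3[a, ])
  }
  invisible(x)
}

#' Validate model scores against measured peptide half-lives
#'
#' Scores each peptide's N-terminal triplet and correlates the score with the
#' experimentally determined half-life upon enzyme incubation. Peptides
#' flagged as undergoing multiple successive cleavages are excluded, since no
#' unique triplet explains their turnover. Efficient substrates should show
#' short half-lives, i.e. a negative correlation.
#'
#' @param params A `qpisa_params` object.
#' @param halflives data.frame with columns `peptide`, `half_life` (minutes)
#'   and optionally logical `multi_cleavage`.
#' @return List: `r` (Pearson correlation), `n_used`, and `used` (the peptide
#'   roster with scores).
#' @export
validate_half_lives <- function(params, halflives) {
  stopifnot(all(c("peptide", "half_life") %in% names(halflives)))
  df <- halflives
  if (!is.null(df$multi_cleavage)) {
    df <- df[!df$multi_cleavage, , drop = FALSE]
  }
  df <- df[nchar(df$peptide) >= 3L & is_standard_seq(substr(df$peptide, 1, 3)), ,
           drop = FALSE]
  if (nrow(df) < 3L) stop("fewer than 3 usable peptides")
  df$score <- as.numeric(score_triplets(params, df$peptide))
  list(r = stats::cor(df$score, df$half_life), n_used = nrow(df), used = df)
}
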