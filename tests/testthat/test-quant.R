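samples3 <- function(r = 1) {
  data.frame(sample_id = c(paste0("b", 1:r), paste0("e", 1:r)),
             condition = rep(c("buffer", "enzyme"), each = r),
             replicate = rep(1:r, 2), stringsAsFactors = FALSE)
}

test_that("log2 + median centering behaves and is idempotent", {
  qt <- quant_table(matrix(c(2, 4, 8, 1, 2, 4), ncol = 2),
                    c("AAAAAA", "CCCCCC", "DDDDDD"), samples3())
  out <- log2_median_center(qt)
  expect_equal(out$values[, 1], c(-1, 0, 1), ignore_attr = TRUE)
  expect_true(out$log2 && out$centered)
  # per-column median is 0 after normalization
  expect_equal(unname(apply(out$values, 2, median)), c(0, 0))
  # idempotence on already-centred input
  expect_identical(log2_median_center(out), out)
  # identical raw values collapse to zeros
  qt2 <- quant_table(matrix(5, 3, 2), c("A", "B", "C"), samples3())
  expect_true(all(log2_median_center(qt2)$values == 0))
  # nonpositive raw intensity is an error naming cells
  qt3 <- quant_table(matrix(c(1, -2, 3, 4, 5, 6), ncol = 2),
                     c("A", "B", "C"), samples3())
  expect_error(log2_median_center(qt3), "nonpositive")
})

test_that("MinProb imputation is seeded, left-censored, and a no-op without NAs", {
  set.seed(3)
  v <- matrix(rnorm(2000, 0, 2), ncol = 2)
  qt <- quant_table(v, sprintf("P%04d", 1:1000), samples3(),
                    log2 = TRUE, centered = TRUE)
  expect_identical(impute_minprob(qt, seed = 1), qt)

  miss <- v
  miss[sample(length(miss), 1000)] <- NA
  qtm <- quant_table(miss, sprintf("P%04d", 1:1000), samples3(),
                     log2 = TRUE, centered = TRUE)
  a <- impute_minprob(qtm, seed = 7)
  b <- impute_minprob(qtm, seed = 7)
  expect_identical(a$values, b$values)
  expect_false(anyNA(a$values))
  # draws centred on the 1% quantile with a narrow spread lie far in the
  # left tail: nearly all below the observed 5th percentile
  imputed <- a$values[is.na(qtm$values)]
  p5 <- quantile(qtm$values, 0.05, na.rm = TRUE)
  expect_gte(mean(imputed < p5), 0.99)
})

test_that("filtering drops unmapped, ambiguous and low-intensity rows", {
  peps <- sprintf("PEP%03dAK", 1:10)
  cls <- data.frame(peptide = peps, cls = "tryptic", ambiguous_flank = FALSE,
                    stringsAsFactors = FALSE)
  cls$cls[1] <- "unmapped"
  cls$ambiguous_flank[2] <- TRUE
  v <- matrix(0, 10, 2)
  v[3, ] <- -5.0      # below threshold
  v[4, ] <- -4.7      # exactly at threshold: kept (inclusive)
  qt <- quant_table(v, peps, samples3(), log2 = TRUE, centered = TRUE)
  out <- filter_quant(qt, cls, min_log2_intensity = -4.7)
  expect_equal(nrow(out$values), 7L)
  expect_equal(attr(out, "filter_log"),
               c(unmapped = 1L, ambiguous_flank = 1L, low_intensity = 1L))
  expect_true("PEP004AK" %in% out$peptide)
})

test_that("redundant forms collapse to the most abundant, ties lexicographic", {
  v <- rbind(c(-1, -1), c(-2, -2), c(0, 0), c(3, 3), c(3, 3))
  qt <- quant_table(v, c("TESTK", "TESTK", "OTHER", "TIEPEP", "TIEPEP"),
                    samples3(), form_id = c("f1", "f2", "na", "z2", "a1"),
                    log2 = TRUE, centered = TRUE)
  out <- collapse_forms(qt)
  expect_equal(nrow(out$values), 3L)
  expect_equal(out$form_id[out$peptide == "TESTK"], "f1")
  expect_equal(out$form_id[out$peptide == "TIEPEP"], "a1")
  expect_equal(attr(out, "collapsed"), 2L)
  # unique-form peptides pass through unchanged
  expect_equal(out$values[out$peptide == "OTHER", ], c(0, 0),
               ignore_attr = TRUE)
})

test_that("delta is the replicate-mean difference with cleavage-positive sign", {
  v <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 1, 3, 1, 2))
  qt <- quant_table(v, c("AAAAAA", "CCCCCC"), samples3(3),
                    log2 = TRUE, centered = TRUE)
  sub <- compute_delta(qt, "substrate")
  expect_equal(sub$delta, c(1, -5 / 3))
  prod <- compute_delta(qt, "product")
  expect_equal(prod$delta, -sub$delta)

  # swapping condition labels flips the sign
  qt_sw <- qt
  qt_sw$samples$condition <- rev(qt$samples$condition)
  expect_equal(compute_delta(qt_sw, "substrate")$delta, -sub$delta)

  # identical conditions give exactly zero
  v0 <- matrix(2, 1, 6)
  qt0 <- quant_table(v0, "DDDDDD", samples3(3), log2 = TRUE, centered = TRUE)
  expect_equal(compute_delta(qt0, "substrate")$delta, 0)
})

test_that("short and non-standard peptides are dropped with a logged count", {
  v <- matrix(0, 3, 2)
  qt <- quant_table(v, c("AAAAAA", "SHORT", "AAXBZA"), samples3(),
                    log2 = TRUE, centered = TRUE)
  rec <- compute_delta(qt, "substrate")
  expect_equal(rec$peptide, "AAAAAA")
  expect_equal(attr(rec, "drop_log"), c(too_short = 1L, nonstandard = 1L))
})

test_that("the preprocessing chain is a no-op when nothing needs fixing", {
  sim <- simulate_qpisa(n_proteins = 15, seed = 21, noise_sd = 0.2,
                        dropout_q = 0)
  cls <- classify_peptides(sim$locations)
  direct <- compute_delta(sim$quant, "substrate", cls)
  qt <- log2_median_center(sim$quant)
  qt <- impute_minprob(qt, seed = 1)
  qt <- filter_quant(qt, cls, -Inf)
  qt <- collapse_forms(qt)
  piped <- compute_delta(qt, "substrate", cls)
  expect_equal(piped, direct, ignore_attr = TRUE)
})

test_that("noiseless linear simulation yields delta equal to the true score", {
  sim <- simulate_qpisa(n_proteins = 10, seed = 31, noise_sd = 0,
                        dropout_q = 0)
  cls <- classify_peptides(sim$locations)
  rec <- compute_delta(sim$quant, "substrate", cls)
  meta <- sim$meta[sim$meta$type == "substrate", ]
  prods <- sim$meta$peptide[sim$meta$type == "product"]
  m <- match(rec$peptide, meta$peptide)
  ok <- !is.na(m) & !(rec$peptide %in% prods)
  expect_gt(sum(ok), 100)
  expect_equal(rec$delta[ok], pmax(meta$true_score[m[ok]], 0),
               tolerance = 1e-12)
})
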