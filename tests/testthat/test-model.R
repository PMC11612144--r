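test_that("dummy coding produces the expected column structure", {
  rec <- random_records(200, seed = 2)
  X1 <- build_design_matrix(rec$hexamer, positions = "P1",
                            interactions = list())
  expect_lte(ncol(X1), 1 + 19)
  expect_equal(length(attr(X1, "labels")), 1 + 19)

  # full cooperative specification: 1 + 3*19 + 2*19^2 labelled columns
  Xf <- build_design_matrix(rec$hexamer)
  expect_equal(length(attr(Xf, "labels")), 1 + 57 + 722)
  expect_equal(ncol(Xf) + length(attr(Xf, "dropped")), 780)

  # a record made of reference residues has all-zero predictors
  Xr <- build_design_matrix("AAAAAA", drop_empty = FALSE)
  expect_equal(ncol(Xr), 780)
  expect_equal(unname(Xr[1, -1]), rep(0, 779))

  # interaction columns are products of the main-effect dummies; the
  # reference level has no column anywhere
  Xc <- build_design_matrix("HACAAA", drop_empty = FALSE)
  expect_equal(unname(Xc[1, "P2=H"]), 1)
  expect_false("P2=H:P1=A" %in% colnames(Xc))
  expect_equal(sum(Xc[1, grepl(":", colnames(Xc))]), 0)  # P1 at reference
  Xc2 <- build_design_matrix("HPCAAA", drop_empty = FALSE)
  expect_equal(unname(Xc2[1, "P2=H:P1=P"]), 1)
  expect_equal(unname(Xc2[1, "P1=P:P1'=C"]), 1)

  expect_error(build_design_matrix("AXAAAA"), "non-standard")
  expect_error(build_design_matrix("AAAAAA", interactions = list(c("P2", "P3p"))),
               "interaction")
})

test_that("OLS coefficients match an independent normal-equations oracle", {
  for (seed in c(4, 5)) {
    rec <- random_records(80, seed = seed)
    fit <- qpisa(rec, positions = c("P2", "P1"), interactions = list())
    X <- build_design_matrix(rec$hexamer, positions = c("P2", "P1"),
                             interactions = list())
    beta <- oracle_ols(X, rec$delta)
    expect_equal(fit$coefficients[names(beta)], beta, tolerance = 1e-8)
  }
})

test_that("degenerate responses fit as expected", {
  # y perfectly determined by P1 over two observed residues
  rec <- data.frame(hexamer = c("APAAAA", "APAAAA", "AGAAAA", "AGAAAA"),
                    delta = c(2, 2, -1, -1))
  fit <- qpisa(rec, positions = "P1", interactions = list())
  expect_equal(fit$r2, 1)
  expect_equal(unname(fit$residuals), rep(0, 4))

  # constant y: zero predictor coefficients, R2 = 0
  rec2 <- random_records(50, seed = 6)
  rec2$delta <- 3
  fit2 <- qpisa(rec2, positions = "P1", interactions = list())
  expect_equal(fit2$r2, 0)
  co <- coef(fit2)
  expect_equal(unname(co[names(co) != "(Intercept)"]),
               rep(0, sum(names(co) != "(Intercept)")), tolerance = 1e-10)
  expect_equal(unname(co["(Intercept)"]), 3)

  # too few records for the parameter count
  expect_error(qpisa(random_records(10, seed = 7)), "more records|simpler")
})

test_that("adjusted R2 follows the standard correction", {
  expect_equal(adjusted_r2(0.5, 100, 19), 0.38125)
  expect_equal(adjusted_r2(0.7, 500, 0), 0.7)
  expect_equal(adjusted_r2(1, 50, 10), 1)
  expect_error(adjusted_r2(0.5, 20, 19), "n > p")
  # adjusted never exceeds raw
  fit <- qpisa(random_records(400, seed = 8), positions = "P1",
               interactions = list())
  expect_lte(fit$adj_r2, fit$r2)
})

test_that("predictions are coefficient sums and reference-invariant", {
  rec <- random_records(4000, seed = 9)
  rec$delta <- rec$delta + 2 * (substr(rec$hexamer, 2, 2) == "P")
  fit <- qpisa(rec)
  # all-reference sequence scores the intercept
  expect_equal(as.numeric(predict(fit, "AAAAAA")),
               unname(coef(fit)["(Intercept)"]))
  # training predictions equal fitted values
  expect_equal(as.numeric(predict(fit, rec$hexamer)), unname(fitted(fit)),
               tolerance = 1e-10)
  # changing the dummy reference leaves predictions unchanged
  fit_g <- qpisa(rec, reference = "G")
  tri <- all_triplet_seqs()
  obs <- as.integer(fit$triplet_counts) > 0
  pa <- as.numeric(predict(fit, tri))[obs]
  pg <- as.numeric(predict(fit_g, tri))[obs]
  expect_equal(pa, pg, tolerance = 1e-9)
  # fit statistics are reference-invariant too
  expect_equal(fit$r2, fit_g$r2, tolerance = 1e-12)
})

test_that("unobserved levels predict through zero and are flagged", {
  rec <- random_records(300, seed = 10)
  rec <- rec[substr(rec$hexamer, 2, 2) != "W", ]  # remove Trp at P1
  fit <- qpisa(rec, positions = "P1", interactions = list())
  expect_true("P1=W" %in% fit$dropped)
  p <- predict(fit, c("AWAAAA", "AAAAAA"))
  expect_equal(unname(p[1]), unname(coef(fit)["(Intercept)"]))
  expect_equal(attr(p, "novel_levels"), c(TRUE, FALSE))
})

test_that("nested models never lose training R2", {
  rec <- random_records(2000, seed = 11)
  base <- qpisa(rec, interactions = list())
  one <- qpisa(rec, interactions = list(c("P1", "P1p")))
  both <- qpisa(rec)
  expect_gte(one$r2, base$r2 - 1e-12)
  expect_gte(both$r2, one$r2 - 1e-12)
})

test_that("the model suite fits the twelve canonical specifications", {
  rec <- random_records(2500, seed = 12)
  suite <- run_model_suite(rec)
  expect_length(suite$fits, 12L)
  expect_equal(suite$summary$model[c(2, 7, 12)],
               c("P1 only", "P2+P1+P1' linear", "final (+P2:P1 +P1:P1')"))
  expect_true(all(suite$summary$adj_r2 <= suite$summary$r2))
  # single-position models use one 19-dummy block at most
  expect_true(all(suite$summary$p[1:6] <= 19))
})

test_that("coverage audit counts combination spaces correctly", {
  empty <- audit_coverage(data.frame(hexamer = character(),
                                     delta = numeric()), 1)
  expect_equal(empty$tripeptide$space, 8000L)
  expect_equal(empty$dipeptide$space, 1200L)
  expect_equal(empty$tripeptide$covered, 0L)

  # 12-record fixture, hand enumeration at min_events = 2
  hex <- c(rep("PAEAAA", 3), rep("HAEAAA", 2), "GGGAAA",
           rep("PASAAA", 2), rep("WWWAAA", 2), "CCCAAA", "DDDAAA")
  cov <- audit_coverage(data.frame(hexamer = hex, delta = 0), 2)
  expect_equal(cov$tripeptide$covered, 4L)   # PAE, HAE, PAS, WWW
  expect_equal(cov$dipeptide$P2_P1, 3L)      # PA(5), HA(2), WW(2)
  expect_equal(cov$dipeptide$P1_P1p, 3L)     # AE(5), AS(2), WW(2)
  expect_equal(cov$dipeptide$P2_P1p, 4L)     # PE(3), HE(2), PS(2), WW(2)
})
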