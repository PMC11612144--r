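fit_small <- function(n = 3000, seed = 13) {
  rec <- random_records(n, seed = seed)
  truth <- default_dpp4_truth()
  rec$delta <- rec$delta * 0.3 + as.numeric(score_triplets(truth, rec$hexamer))
  qpisa(rec)
}

test_that("rearranged terms reproduce model predictions on all 8000 triplets", {
  fit <- fit_small()
  pars <- rearrange(fit)
  tri <- all_triplet_seqs()
  yhat <- as.numeric(predict(fit, tri))
  sc <- as.numeric(score_triplets(pars, tri))
  expect_lt(max(abs(yhat - sc)), 1e-9)
  # zero-mean constraints per P1 residue
  expect_lt(max(abs(colMeans(pars$term2))), 1e-9)
  expect_lt(max(abs(rowMeans(pars$term3))), 1e-9)
  # intermediate four-term folding also reproduces predictions
  im <- pars$intermediate
  expect_length(im, 4L)
  sc4 <- im$intercept + im$P1[substr(tri, 2, 2)] +
    im$P2_P1[cbind(substr(tri, 1, 1), substr(tri, 2, 2))] +
    im$P1_P1p[cbind(substr(tri, 2, 2), substr(tri, 3, 3))]
  expect_lt(max(abs(yhat - unname(sc4))), 1e-9)
})

test_that("rearrangement matches a brute-force averaging oracle", {
  fit <- fit_small(n = 1500, seed = 14)
  pars <- rearrange(fit)
  tri <- all_triplet_seqs()
  yhat <- as.numeric(predict(fit, tri))
  Y <- array(yhat, dim = c(20, 20, 20))  # [P2, P1, P1']
  for (ai in c(1, 13, 20)) {
    a <- AA_ALPHABET[ai]
    expect_equal(unname(pars$term1[a]), mean(Y[, ai, ]), tolerance = 1e-12)
    expect_equal(unname(pars$term2["H", a]),
                 mean(Y[which(AA_ALPHABET == "H"), ai, ]) - mean(Y[, ai, ]),
                 tolerance = 1e-12)
    expect_equal(unname(pars$term3[a, "P"]),
                 mean(Y[, ai, which(AA_ALPHABET == "P")]) - mean(Y[, ai, ]),
                 tolerance = 1e-12)
  }
})

test_that("without interactions the P2 table is P1-independent", {
  rec <- random_records(2000, seed = 15)
  fit <- qpisa(rec, interactions = list())
  pars <- rearrange(fit)
  expect_lt(max(apply(pars$term2, 1, function(r) diff(range(r)))), 1e-9)
  expect_lt(max(apply(pars$term3, 2, function(r) diff(range(r)))), 1e-9)
})

test_that("rearrangement refuses a specification with a P2:P1' term", {
  rec <- random_records(3000, seed = 16)
  fit <- qpisa(rec, interactions = list(c("P2", "P1p")))
  expect_error(rearrange(fit), "P2:P1'")
})

test_that("rearranged parameters are invariant to the dummy reference", {
  # full-coverage design (every triplet once) so no level is dropped and the
  # parameterisations span identical prediction spaces
  set.seed(17)
  truth <- default_dpp4_truth()
  rec <- data.frame(hexamer = paste0(all_triplet_seqs(), "AAA"))
  rec$delta <- as.numeric(score_triplets(truth, rec$hexamer)) +
    rnorm(nrow(rec), 0, 0.3)
  pa <- rearrange(qpisa(rec, reference = "A"))
  pg <- rearrange(qpisa(rec, reference = "G"))
  expect_lt(max(abs(pa$term1 - pg$term1)), 1e-9)
  expect_lt(max(abs(pa$term2 - pg$term2)), 1e-9)
  expect_lt(max(abs(pa$term3 - pg$term3)), 1e-9)
})

test_that("differential parameters subtract entrywise and score additively", {
  a <- rearrange(fit_small(seed = 18))
  b <- rearrange(fit_small(seed = 19))
  z <- differential_params(a, a)
  expect_true(all(abs(params_table(z)$value) < 1e-12))
  d <- differential_params(a, b)
  back <- differential_params(d, differential_params(z, b))
  expect_equal(params_table(back)$value, params_table(a)$value,
               tolerance = 1e-9)
  tri <- sample(all_triplet_seqs(), 100)
  expect_equal(as.numeric(score_triplets(d, tri)),
               as.numeric(score_triplets(a, tri)) -
                 as.numeric(score_triplets(b, tri)),
               tolerance = 1e-9)
  expect_equal(d$support$term2, pmin(a$support$term2, b$support$term2))
})

test_that("two truths differing in one P1 weight differ only in term1", {
  t1 <- default_dpp4_truth()
  raw1 <- t1$term1; raw1["A"] <- raw1["A"] + 1
  t2 <- new_truth(raw1, t1$term2, t1$term3)
  d <- differential_params(t2, t1)
  expect_equal(unname(d$term1["A"]), 1, tolerance = 1e-12)
  expect_lt(max(abs(d$term1[names(d$term1) != "A"])), 1e-12)
  expect_lt(max(abs(d$term2)), 1e-12)
  expect_lt(max(abs(d$term3)), 1e-12)
})

test_that("parameter correlation behaves at its fixed points", {
  a <- rearrange(fit_small(seed = 20))
  expect_equal(as.numeric(compare_params(a, a)), 1, tolerance = 1e-12)
  z <- differential_params(a, a)
  neg <- differential_params(z, a)
  expect_equal(as.numeric(compare_params(a, neg)), -1, tolerance = 1e-12)
  expect_error(compare_params(a, a, min_support = 10^9), "support")
})

test_that("independent refits of one truth give highly correlated parameters", {
  truth <- random_truth(23)
  fits <- lapply(c(101, 202), function(s) {
    sim <- simulate_qpisa(n_proteins = 260, truth = truth, seed = s)
    qpisa(sim_to_tryptic(sim))
  })
  r <- compare_params(rearrange(fits[[1]]), rearrange(fits[[2]]),
                      min_support = 3)
  expect_gte(as.numeric(r), 0.95)
})

test_that("the six-position linear logo is centred per position", {
  rec <- random_records(3000, seed = 24)
  fit6 <- qpisa(rec, positions = names(qpisa:::QPISA_POSITIONS),
                interactions = list())
  logo <- linear_logo(fit6)
  expect_equal(dim(logo), c(20L, 6L))
  expect_lt(max(abs(colSums(logo))), 1e-9)
  expect_error(linear_logo(qpisa(rec, interactions = list())), "six-position")
})

test_that("half-life validation recovers a perfect anticorrelation", {
  pars <- default_dpp4_truth()
  peps <- c("HAEGTFTSDV", "YAEGTFISDY", "HGEGTFTSDL", "PPAQGAMG",
            "APPRLICDSR", "WKEAKAGGG")
  sc <- as.numeric(score_triplets(pars, peps))
  tab <- data.frame(peptide = peps, half_life = 100 - 10 * sc)
  out <- validate_half_lives(pars, tab)
  expect_equal(out$r, -1, tolerance = 1e-12)
  expect_equal(out$n_used, length(peps))
  # multi-cleavage peptides are excluded from the roster
  tab$multi_cleavage <- c(TRUE, rep(FALSE, 5))
  expect_equal(validate_half_lives(pars, tab)$n_used, 5L)
  expect_error(validate_half_lives(pars, tab[1:3, ]), "fewer than 3")
})

test_that("shuffled half-lives show no systematic correlation", {
  pars <- default_dpp4_truth()
  set.seed(25)
  peps <- replicate(30, paste(sample(AA_ALPHABET, 6, TRUE), collapse = ""))
  sc <- as.numeric(score_triplets(pars, peps))
  half <- 100 - 10 * sc
  rs <- replicate(300, {
    validate_half_lives(pars, data.frame(peptide = peps,
                                         half_life = sample(half)))$r
  })
  expect_lt(abs(mean(rs)), 0.1)
})
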