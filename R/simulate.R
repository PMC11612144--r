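#' Default residue frequencies of a skewed proteome
#'
#' Human-proteome-like amino-acid composition (fractions summing to 1), with
#' the characteristic skew of e.g. Leu at 9.9% and Trp at 1.2%.
#'
#' @return Named numeric vector over [AA_ALPHABET].
#' @export
default_residue_freqs <- function() {
  c(A = 7.0, C = 2.3, D = 4.7, E = 7.1, F = 3.7, G = 6.6, H = 2.6, I = 4.3,
    K = 5.7, L = 9.9, M = 2.1, N = 3.6, P = 6.3, Q = 4.8, R = 5.6, S = 8.3,
    T = 5.5, V = 6.0, W = 1.2, Y = 2.7) / 100
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic proteome
#'
#' Protein sequences with i.i.d. residues drawn from a (skewed) frequency
#' table and log-normal lengths; fully determined by the seed.
#'
#' @param n_proteins Number of proteins.
#' @param avg_length Mean protein length (residues).
#' @param length_sdlog Log-scale sd of the length distribution.
#' @param freqs Residue frequency table summing to 1 (default
#'   [default_residue_freqs()]).
#' @param seed Integer seed.
#' @return A `protein_db` data.frame (`id`, `sequence`).
#' @export
generate_proteome <- function(n_proteins = 500L, avg_length = 450,
                              length_sdlog = 0.45,
                              freqs = default_residue_freqs(), seed = 1L) {
  stopifnot(n_proteins >= 1L, avg_length > 0)
  if (!setequal(names(freqs), AA_ALPHABET) ||
      abs(sum(freqs) - 1) > 1e-9 || any(freqs < 0)) {
    stop("freqs must be a non-negative table over the 20 residues summing to 1")
  }
  freqs <- freqs[AA_ALPHABET]
  with_seed(seed, {
    lens <- pmax(30L, round(stats::rlnorm(
      n_proteins, meanlog = log(avg_length) - length_sdlog^2 / 2,
      sdlog = length_sdlog)))
    seqs <- vapply(lens, function(n) {
      paste(sample(AA_ALPHABET, n, replace = TRUE, prob = freqs),
            collapse = "")
    }, "")
  })
  db <- data.frame(id = sprintf("SYN%05d", seq_len(n_proteins)),
                   sequence = seqs, stringsAsFactors = FALSE)
  class(db) <- c("protein_db", "data.frame")
  db
}

#' Write a protein database to FASTA
#'
#' @param db A `protein_db` data.frame.
#' @param path Output path.
#' @export
write_protein_fasta <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(db))) {
    writeLines(c(paste0(">", db$id[i]),
                 gsub("(.{60})", "\\1\n", db$sequence[i])), con)
  }
  invisible(path)
}

#' In-silico tryptic digestion
#'
#' Cleaves after Lys/Arg (optionally not when followed by Pro) and emits all
#' fragments with up to `missed_cleavages` internal sites left uncleaved,
#' with 1-based start positions.
#'
#' @param sequence A protein sequence (single string).
#' @param missed_cleavages 0-2 missed cleavage sites allowed.
#' @param suppress_before_proline Skip K/R sites followed by Pro.
#' @return data.frame with `peptide` and `start`.
#' @export
digest_trypsin <- function(sequence, missed_cleavages = 0L,
                           suppress_before_proline = FALSE) {
  stopifnot(missed_cleavages >= 0L)
  n <- nchar(sequence)
  ch <- strsplit(sequence, "")[[1]]
  sites <- which(ch %in% c("K", "R"))
  sites <- sites[sites < n]
  if (suppress_before_proline && length(sites)) {
    sites <- sites[ch[sites + 1L] != "P"]
  }
  bounds <- c(0L, sites, n)
  nb <- length(bounds)
  out_start <- integer(); out_end <- integer()
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + missed_cleavages)) {
      out_start <- c(out_start, bounds[i] + 1L)
      out_end <- c(out_end, bounds[j])
    }
  }
  data.frame(peptide = substring(sequence, out_start, out_end),
             start = out_start, stringsAsFactors = FALSE)
}

#' Digest every protein of a database
#'
#' @param db A `protein_db`.
#' @inheritParams digest_trypsin
#' @return Location-style data.frame: `peptide`, `protein_id`, `start`,
#'   `preceding`, `is_cterm`, `mapped`, `ambiguous_flank` (FALSE; positions
#'   are known by construction).
#' @export
digest_proteome <- function(db, missed_cleavages = 0L,
                            suppress_before_proline = FALSE) {
  parts <- lapply(seq_len(nrow(db)), function(i) {
    d <- digest_trypsin(db$sequence[i], missed_cleavages,
                        suppress_before_proline)
    d$protein_id <- db$id[i]
    d$preceding <- ifelse(d$start == 1L, NA_character_,
                          substring(db$sequence[i], d$start - 1L, d$start - 1L))
    d$is_cterm <- d$start + nchar(d$peptide) - 1L == nchar(db$sequence[i])
    d
  })
  out <- do.call(rbind, parts)
  out$mapped <- TRUE
  out$ambiguous_flank <- FALSE
  out[, c("peptide", "mapped", "protein_id", "start", "preceding",
          "is_cterm", "ambiguous_flank")]
}

#' Construct a ground-truth cleavage motif
#'
#' Builds a `qpisa_truth` from raw term tables: the per-P1 means of the
#' interaction tables are folded into `term1` so that the zero-mean
#' constraints hold while every triplet score is preserved.
#'
#' @param term1 Named numeric vector over the 20 residues (P1 effect,
#'   including the overall level).
#' @param term2,term3 20 x 20 matrices (`term2[P2, P1]`, `term3[P1, P1']`).
#' @return A `qpisa_truth` (also a `qpisa_params`, so [score_triplets()]
#'   applies).
#' @export
new_truth <- function(term1, term2, term3) {
  stopifnot(setequal(names(term1), AA_ALPHABET),
            all(dim(term2) == 20L), all(dim(term3) == 20L))
  term1 <- term1[AA_ALPHABET]
  term2 <- term2[AA_ALPHABET, AA_ALPHABET]
  term3 <- term3[AA_ALPHABET, AA_ALPHABET]
  m2 <- colMeans(term2)          # per-P1 mean over P2
  m3 <- rowMeans(term3)          # per-P1 mean over P1'
  term2 <- sweep(term2, 2L, m2)
  term3 <- sweep(term3, 1L, m3)
  term1 <- term1 + m2 + m3
  ones <- matrix(1L, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  p <- new_params(term1, term2, term3,
                  list(term1 = stats::setNames(rep(1L, 20L), AA_ALPHABET),
                       term2 = ones, term3 = ones))
  class(p) <- c("qpisa_truth", class(p))
  p
}

zero_tab <- function() {
  matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
}

#' DPP4-like ground-truth motif
#'
#' A fixed, documented motif with the qualitative shape of dipeptidyl
#' peptidase 4 specificity: Pro and Ala at P1 strongly cleavage-promoting,
#' Ser/Thr moderately so; Pro at P1' strongly detrimental in combination with
#' all productive P1 residues; Thr/Val at P1' mildly beneficial after P1 Pro
#' but detrimental after Ala; assorted small P2:P1 effects (e.g. His over Asp
#' at P2 before Ala).
#'
#' @return A `qpisa_truth`.
#' @export
default_dpp4_truth <- function() {
  term1 <- stats::setNames(rep(-0.25, 20L), AA_ALPHABET)
  term1[c("P", "A", "S", "T")] <- c(2.5, 2.4, 1.2, 1.0)
  term1[c("G", "M")] <- c(0.3, 0.2)
  term1[c("D", "E", "W")] <- c(-0.45, -0.45, -0.5)
  term2 <- zero_tab()
  term2["H", "A"] <- 0.4
  term2["D", "A"] <- -0.6
  term2["R", "P"] <- 0.2
  term2["G", "A"] <- 0.2
  term2["P", c("P", "A", "S", "T")] <- -0.3
  term3 <- zero_tab()
  term3[c("P", "A", "S", "T"), "P"] <- -2.5
  term3["P", c("T", "V")] <- 0.3
  term3["A", c("T", "V")] <- -0.3
  term3[c("P", "A", "S", "T"), "W"] <- -0.2
  new_truth(term1, term2, term3)
}

#' Random ground-truth motif with subsite cooperativity
#'
#' Gaussian term tables with P2:P1 and P1:P1' cooperativity, shifted so that
#' most triplet scores are positive -- the regime in which substrate depletion
#' identifies the full motif (the simulator clamps negative scores to zero
#' depletion, so predominantly negative motifs are only partially
#' identifiable).
#'
#' @param seed Integer seed.
#' @param term1_mean,term1_sd Mean and sd of the P1 effects.
#' @param term2_sd,term3_sd Sds of the interaction entries.
#' @return A `qpisa_truth`.
#' @export
random_truth <- function(seed = 1L, term1_mean = 2, term1_sd = 0.8,
                         term2_sd = 0.3, term3_sd = 0.3) {
  with_seed(seed, {
    term1 <- stats::setNames(stats::rnorm(20L, term1_mean, term1_sd),
                             AA_ALPHABET)
    term2 <- matrix(stats::rnorm(400L, 0, term2_sd), 20L, 20L,
                    dimnames = list(AA_ALPHABET, AA_ALPHABET))
    term3 <- matrix(stats::rnorm(400L, 0, term3_sd), 20L, 20L,
                    dimnames = list(AA_ALPHABET, AA_ALPHABET))
    new_truth(term1, term2, term3)
  })
}

#' Simulation settings
#'
#' @param mode `"linear"` (depletion equals the clamped score) or
#'   `"kinetic"` (first-order turnover: cleaved fraction
#'   `f = 1 - exp(-k0 * 2^score * time)`).
#' @param time Incubation time (arbitrary units; kinetic mode).
#' @param k0 Base cleavage rate (kinetic mode).
#' @param noise_sd Replicate noise sd, log2 units.
#' @param n_replicates Replicates per condition.
#' @param baseline_sd Sd of per-peptide baseline log2 intensities.
#' @param dropout_q Left-censoring quantile: cells below this quantile of all
#'   simulated log2 values are set missing.
#' @param offset N-terminal residues removed per cleavage (2 = dipeptidyl).
#' @param pseudocount Linear-scale pseudocount for product intensities
#'   (avoids log2(0); products start at zero abundance in buffer).
#' @param seed Integer seed.
#' @return A list of settings for [simulate_experiment()].
#' @export
sim_config <- function(mode = c("linear", "kinetic"), time = 1, k0 = 0.1,
                       noise_sd = 0.3, n_replicates = 3L, baseline_sd = 1.5,
                       dropout_q = 0.01, offset = 2L, pseudocount = 1e-3,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_replicates >= 1L, noise_sd >= 0, dropout_q >= 0, dropout_q < 1,
            offset >= 1L, k0 > 0, time > 0)
  list(mode = mode, time = time, k0 = k0, noise_sd = noise_sd,
       n_replicates = as.integer(n_replicates), baseline_sd = baseline_sd,
       dropout_q = dropout_q, offset = as.integer(offset),
       pseudocount = pseudocount, seed = as.integer(seed))
}

#' Simulate a quantified protease experiment
#'
#' Given tryptic peptides and a ground-truth motif, simulates enzyme and
#' buffer replicate intensities for substrates and their exopeptidase
#' products. Per substrate the true score `s` of its (P2, P1, P1') triplet
#' sets the effect: in linear mode the depletion is `max(s, 0)` log2 units
#' (an enzyme cannot increase its substrate) and the product accumulates by
#' the same amount; in kinetic mode a fraction `f = 1 - exp(-k0 * 2^s * time)`
#' of the substrate is cleaved, the substrate change is `-log2(1 - f)` and
#' the product gains exactly the substrate's linear-scale loss (mass
#' conservation). Gaussian replicate noise and left-censored dropout are then
#' applied; everything is determined by the seed.
#'
#' @param peptides Location-style data.frame from [digest_proteome()] (columns
#'   `peptide`, `protein_id`, `start`, `preceding`, `is_cterm`). Peptides
#'   shorter than 6 residues are skipped; duplicate sequences keep the first
#'   mapping.
#' @param truth A `qpisa_truth`.
#' @param config Settings from [sim_config()].
#' @return A `qpisa_sim` list: `quant` (a `qpisa_quant`, log2, centred-scale),
#'   `meta` (per-row truth: `peptide`, `type`, `true_score`, `true_delta`),
#'   `locations` (for [classify_peptides()]), `truth`, `config`.
#' @export
simulate_experiment <- function(peptides, truth, config = sim_config()) {
  stopifnot(inherits(truth, "qpisa_params"))
  pep <- peptides[nchar(peptides$peptide) >= 6L &
                    is_standard_seq(peptides$peptide), , drop = FALSE]
  pep <- pep[!duplicated(pep$peptide), , drop = FALSE]
  n <- nrow(pep)
  if (n == 0L) stop("no usable peptides (need length >= 6, standard letters)")
  s <- as.numeric(score_triplets(truth, pep$peptide))
  R <- config$n_replicates
  off <- config$offset

  with_seed(config$seed, {
    base_s <- stats::rnorm(n, 0, config$baseline_sd)
    if (config$mode == "linear") {
      dstar <- pmax(s, 0)
      sub_buf <- base_s + dstar / 2
      sub_enz <- base_s - dstar / 2
      keep_p <- dstar > 0 & nchar(pep$peptide) - off >= 1L
      base_p <- stats::rnorm(sum(keep_p), 0, config$baseline_sd)
      prod_buf <- base_p - dstar[keep_p] / 2
      prod_enz <- base_p + dstar[keep_p] / 2
      true_delta_s <- dstar
      true_delta_p <- dstar[keep_p]
    } else {
      f <- 1 - exp(-config$k0 * 2^s * config$time)
      I0 <- 2^base_s
      sub_buf <- base_s
      sub_enz <- log2(I0 * (1 - f))
      keep_p <- f > 0 & nchar(pep$peptide) - off >= 1L
      pc <- config$pseudocount
      prod_buf <- rep(log2(pc), sum(keep_p))
      prod_enz <- log2(I0[keep_p] * f[keep_p] + pc)
      true_delta_s <- -log2(1 - f)
      true_delta_p <- prod_enz - prod_buf
    }
    prod_pep <- substr(pep$peptide[keep_p], off + 1L,
                       nchar(pep$peptide[keep_p]))
    mu <- cbind(matrix(c(sub_buf, prod_buf), ncol = 1)[, rep(1L, R)],
                matrix(c(sub_enz, prod_enz), ncol = 1)[, rep(1L, R)])
    noise <- if (config$noise_sd > 0) {
      matrix(stats::rnorm(length(mu), 0, config$noise_sd), nrow = nrow(mu))
    } else 0
    vals <- mu + noise
    if (config$dropout_q > 0) {
      thr <- stats::quantile(vals, config$dropout_q, names = FALSE)
      vals[vals < thr] <- NA_real_
    }
  })

  samples <- data.frame(
    sample_id = c(paste0("buffer_", seq_len(R)), paste0("enzyme_", seq_len(R))),
    condition = rep(c("buffer", "enzyme"), each = R),
    replicate = rep(seq_len(R), 2L),
    stringsAsFactors = FALSE
  )
  all_pep <- c(pep$peptide, prod_pep)
  qt <- quant_table(vals, all_pep, samples, log2 = TRUE, centered = TRUE)
  meta <- data.frame(
    peptide = all_pep,
    protein_id = c(pep$protein_id, pep$protein_id[keep_p]),
    start = c(pep$start, pep$start[keep_p] + off),
    type = c(rep("substrate", n), rep("product", sum(keep_p))),
    true_score = c(s, s[keep_p]),
    true_delta = c(true_delta_s, true_delta_p),
    stringsAsFactors = FALSE
  )
  locations <- data.frame(
    peptide = all_pep,
    mapped = TRUE,
    protein_id = meta$protein_id,
    start = meta$start,
    preceding = c(pep$preceding,
                  substr(pep$peptide[keep_p], off, off)),
    is_cterm = c(pep$is_cterm, pep$is_cterm[keep_p]),
    ambiguous_flank = FALSE,
    stringsAsFactors = FALSE
  )
  structure(list(quant = qt, meta = meta, locations = locations,
                 truth = truth, config = config),
            class = "qpisa_sim")
}

#' @export
print.qpisa_sim <- function(x, ...) {
  cat("qpisa synthetic experiment (", x$config$mode, " mode): ",
      sum(x$meta$type == "substrate"), " substrates, ",
      sum(x$meta$type == "product"), " products, ",
      x$config$n_replicates, " replicates/condition, noise sd ",
      x$config$noise_sd, "\n", sep = "")
  invisible(x)
}

#' One-call synthetic qPISA experiment
#'
#' Convenience wrapper: generate a skewed proteome, digest it in silico, and
#' simulate the quantification under a ground-truth motif.
#'
#' @param n_proteins Number of synthetic proteins.
#' @param truth Ground-truth motif (default [default_dpp4_truth()]).
#' @param seed Master seed (proteome and experiment seeds derive from it).
#' @param missed_cleavages,suppress_before_proline Digestion settings.
#' @param ... Passed to [sim_config()].
#' @return A `qpisa_sim` with an extra `proteome` element.
#' @export
simulate_qpisa <- function(n_proteins = 500L, truth = default_dpp4_truth(),
                           seed = 1L, missed_cleavages = 0L,
                           suppress_before_proline = FALSE, ...) {
  db <- generate_proteome(n_proteins = n_proteins, seed = seed)
  peps <- digest_proteome(db, missed_cleavages, suppress_before_proline)
  sim <- simulate_experiment(peps, truth,
                             sim_config(seed = seed + 1L, ...))
  sim$proteome <- db
  sim
}
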