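# Shared fixtures and independent oracles for the test suite.

# independent normal-equations OLS solver: the cross-check for lm-based fits
oracle_ols <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# tiny fixture protein used throughout the catalog tests
FIX_PROT <- "MKAVLPRTESTKGG"

fixture_db <- function(entries = c(P1 = FIX_PROT)) {
  db <- data.frame(id = names(entries), sequence = unname(entries),
                   stringsAsFactors = FALSE)
  class(db) <- c("protein_db", "data.frame")
  db
}

write_fasta_lines <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# random fold-change records over hexamers, seeded
random_records <- function(n, seed = 1, width = 6) {
  set.seed(seed)
  seqs <- replicate(n, paste(sample(AA_ALPHABET, width, replace = TRUE),
                             collapse = ""))
  data.frame(peptide = seqs, hexamer = substr(seqs, 1, width),
             delta = rnorm(n), stringsAsFactors = FALSE)
}

all_triplet_seqs <- function() {
  g <- expand.grid(b = AA_ALPHABET, a = AA_ALPHABET, c = AA_ALPHABET,
                   stringsAsFactors = FALSE)
  paste0(g$b, g$a, g$c)
}

# run the full preprocessing pipeline of a simulated experiment and return
# the tryptic substrate records
sim_to_tryptic <- function(sim, min_log2_intensity = -Inf,
                           impute_seed = 5L) {
  qt <- log2_median_center(sim$quant)
  if (anyNA(qt$values)) qt <- impute_minprob(qt, seed = impute_seed)
  cls <- classify_peptides(sim$locations)
  qt <- filter_quant(qt, cls, min_log2_intensity)
  qt <- collapse_forms(qt)
  rec <- compute_delta(qt, "substrate", cls)
  rec[rec$cls == "tryptic", , drop = FALSE]
}
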