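#' The 20-letter amino-acid alphabet
#'
#' Standard one-letter codes, alphabetical. All categorical modelling in the
#' package operates on this alphabet; peptides carrying other letters
#' (B, J, O, U, X, Z) are excluded from modelling with a logged count.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Subsite positions of the N-terminal hexamer, Schechter-Berger style.
# For a dipeptidyl peptidase the scissile bond lies between residues 2 and 3
# of the peptide, so P2 is residue 1, P1 residue 2, P1' residue 3, etc.
QPISA_POSITIONS <- c(P2 = 1L, P1 = 2L, P1p = 3L, P2p = 4L, P3p = 5L, P4p = 6L)

# display labels for positions (P1p -> P1')
position_label <- function(x) {
  gsub("p$", "'", x)
}

#' @keywords internal
is_standard_seq <- function(x) {
  !is.na(x) & grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")), x)
}

# split sequences into a character matrix of single residues (n x width)
seq_to_matrix <- function(seqs, width) {
  if (any(nchar(seqs) < width)) {
    stop("all sequences must have at least ", width, " residues")
  }
  mat <- matrix("", nrow = length(seqs), ncol = width)
  for (j in seq_len(width)) mat[, j] <- substr(seqs, j, j)
  mat
}

check_standard <- function(seqs, what = "sequence") {
  bad <- !is_standard_seq(seqs)
  if (any(bad)) {
    stop("non-standard residue letters in ", what, ": ",
         paste(utils::head(unique(seqs[bad]), 5), collapse = ", "))
  }
  invisible(TRUE)
}
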