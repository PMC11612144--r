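#' Read a protein database from FASTA
#'
#' Parses a protein FASTA file into a data frame of accession/sequence pairs.
#' The accession is the header token before the first whitespace; sequences
#' are uppercased. Duplicate accessions and malformed files are errors.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`, one row per entry,
#'   of class `protein_db`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    db <- data.frame(id = character(), sequence = character(),
                     stringsAsFactors = FALSE)
    class(db) <- c("protein_db", "data.frame")
    return(db)
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA: line ", nonblank[1],
         " precedes the first header ('>')")
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  db <- data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
  class(db) <- c("protein_db", "data.frame")
  db
}

#' @export
print.protein_db <- function(x, ...) {
  cat("protein database:", nrow(x), "sequences,",
      sum(nchar(x$sequence)), "residues\n")
  invisible(x)
}

#' Locate peptides in a protein database
#'
#' Exhaustive substring search in database order, then position order. When a
#' peptide maps to several positions, the first hit is kept and
#' `ambiguous_flank` records whether the preceding residues differ across
#' hits. Unmatched peptides get `mapped = FALSE`.
#'
#' @param peptides Character vector of peptide sequences.
#' @param proteome A `protein_db` (see [read_protein_fasta()]).
#' @return data.frame with one row per peptide: `peptide`, `mapped`,
#'   `protein_id`, `start` (1-based), `preceding` (residue before the peptide,
#'   `NA` at the protein N-terminus), `is_cterm`, `ambiguous_flank`.
#' @export
locate_peptides <- function(peptides, proteome) {
  stopifnot(is.character(peptides), all(nchar(peptides) >= 1L))
  n <- length(peptides)
  out <- data.frame(
    peptide = peptides,
    mapped = FALSE,
    protein_id = NA_character_,
    start = NA_integer_,
    preceding = NA_character_,
    is_cterm = NA,
    ambiguous_flank = NA,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    pep <- peptides[i]
    first <- NULL
    flanks <- character()
    for (k in seq_len(nrow(proteome))) {
      seq <- proteome$sequence[k]
      hits <- gregexpr(pep, seq, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      for (st in as.integer(hits)) {
        pre <- if (st == 1L) NA_character_ else substr(seq, st - 1L, st - 1L)
        flanks <- c(flanks, ifelse(is.na(pre), "^", pre))
        if (is.null(first)) {
          first <- list(id = proteome$id[k], start = st, pre = pre,
                        cterm = st + nchar(pep) - 1L == nchar(seq))
        }
      }
    }
    if (!is.null(first)) {
      out$mapped[i] <- TRUE
      out$protein_id[i] <- first$id
      out$start[i] <- first$start
      out$preceding[i] <- first$pre
      out$is_cterm[i] <- first$cterm
      out$ambiguous_flank[i] <- length(unique(flanks)) > 1L
    }
  }
  out
}

#' Classify located peptides as tryptic or semi-tryptic
#'
#' A mapped peptide is tryptic when any of three criteria holds:
#' (i) it starts downstream of Arg/Lys and ends with Arg/Lys;
#' (ii) it starts downstream of Arg/Lys and ends at the protein C-terminus;
#' (iii) it ends with Arg/Lys and derives from the protein N-terminus.
#' Everything else mapped is semi-tryptic -- the signature of an exopeptidase
#' product. "Derives from the N-terminus" also accepts start = 2 behind an
#' initiator Met when `init_met = TRUE`.
#'
#' @param locations Output of [locate_peptides()] (or a compatible data.frame
#'   with known coordinates, e.g. from the synthetic digester).
#' @param init_met Accept initiator-Met-trimmed N-termini (default TRUE).
#' @return The input with columns `cls` (`"tryptic"`, `"semi_tryptic"` or
#'   `"unmapped"`) and `criterion` (`"i"`, `"ii"`, `"iii"` or `NA`).
#' @export
classify_peptides <- function(locations, init_met = TRUE) {
  loc <- locations
  last <- substr(loc$peptide, nchar(loc$peptide), nchar(loc$peptide))
  ends_kr <- last %in% c("K", "R")
  down_kr <- !is.na(loc$preceding) & loc$preceding %in% c("K", "R")
  nterm <- !is.na(loc$start) &
    (loc$start == 1L |
       (init_met & loc$start == 2L & !is.na(loc$preceding) & loc$preceding == "M"))
  cterm <- !is.na(loc$is_cterm) & loc$is_cterm
  cls <- rep(NA_character_, nrow(loc))
  crit <- rep(NA_character_, nrow(loc))
  mapped <- loc$mapped
  cls[!mapped] <- "unmapped"
  i1 <- mapped & down_kr & ends_kr
  i2 <- mapped & !i1 & down_kr & cterm
  i3 <- mapped & !i1 & !i2 & ends_kr & nterm
  cls[i1] <- "tryptic"; crit[i1] <- "i"
  cls[i2] <- "tryptic"; crit[i2] <- "ii"
  cls[i3] <- "tryptic"; crit[i3] <- "iii"
  rest <- mapped & is.na(cls)
  cls[rest] <- "semi_tryptic"
  loc$cls <- cls
  loc$criterion <- crit
  loc
}

#' Match product peptides to their substrate peptides
#'
#' A semi-tryptic product matches a tryptic substrate when both map to the
#' same protein, the product starts `offset` residues downstream of the
#' substrate, and both end at the same residue. `offset` is the number of
#' N-terminal residues removed per cleavage (2 for dipeptidyl peptidases).
#'
#' @param products,substrates Location data.frames (mapped rows only).
#' @param offset Positive integer, residues removed per cleavage.
#' @return List with `pairs` (data.frame `product`, `substrate`,
#'   `protein_id`), `n_products`, `n_matched` and `match_rate`.
#' @export
match_products <- function(products, substrates, offset = 2L) {
  if (!is.numeric(offset) || offset < 1L) stop("offset must be >= 1")
  offset <- as.integer(offset)
  p <- products[products$mapped, , drop = FALSE]
  s <- substrates[substrates$mapped, , drop = FALSE]
  p$end <- p$start + nchar(p$peptide) - 1L
  s$end <- s$start + nchar(s$peptide) - 1L
  pk <- paste(p$protein_id, p$start, p$end)
  sk <- paste(s$protein_id, s$start + offset, s$end)
  hit <- match(pk, sk)
  matched <- !is.na(hit)
  pairs <- data.frame(
    product = p$peptide[matched],
    substrate = s$peptide[hit[matched]],
    protein_id = p$protein_id[matched],
    stringsAsFactors = FALSE
  )
  list(pairs = pairs,
       n_products = nrow(p),
       n_matched = sum(matched),
       match_rate = if (nrow(p)) sum(matched) / nrow(p) else NA_real_)
}

#' Extend peptides at the N-terminus using protein context
#'
#' Prepends the `n` protein residues preceding each located peptide,
#' reconstructing the substrate sequence from a product. Records too close to
#' the protein N-terminus are an error; callers drop them first (see
#' [select_foreground()]).
#'
#' @param locations Mapped location data.frame.
#' @param proteome A `protein_db`.
#' @param n Number of residues to prepend (0 returns peptides unchanged).
#' @return Character vector of extended sequences.
#' @export
extend_n_terminus <- function(locations, proteome, n = 2L) {
  stopifnot(n >= 0L)
  n <- as.integer(n)
  if (n == 0L) return(locations$peptide)
  if (any(!locations$mapped)) stop("all locations must be mapped")
  short <- locations$start - n < 1L
  if (any(short)) {
    stop(sum(short), " peptide(s) start within ", n,
         " residues of the protein N-terminus and cannot be extended")
  }
  seqs <- proteome$sequence[match(locations$protein_id, proteome$id)]
  paste0(substr(seqs, locations$start - n, locations$start - 1L),
         locations$peptide)
}
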