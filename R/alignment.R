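#' Construct a pairwise alignment
#'
#' @param gappedA,gappedB Equal-length gapped sequences over
#'   `A`,`C`,`G`,`T`,`N`,`-` (case insensitive). No column may be a gap in
#'   both sequences.
#' @param idA,idB Sequence identifiers.
#' @return An object of class `pairwise_alignment`: a list with the gapped
#'   sequences, `columns` (alignment length) and per-column coordinate maps
#'   `mapA`, `mapB` (1-based source position, `NA` at gap columns).
#' @export
pairwise_alignment <- function(gappedA, gappedB, idA = "A", idB = "B") {
  gappedA <- toupper(gappedA); gappedB <- toupper(gappedB)
  if (nchar(gappedA) != nchar(gappedB))
    stop("aligned sequences differ in length (", nchar(gappedA), " vs ",
         nchar(gappedB), ")")
  if (nchar(gappedA) == 0L) stop("empty alignment")
  a <- strsplit(gappedA, "", fixed = TRUE)[[1]]
  b <- strsplit(gappedB, "", fixed = TRUE)[[1]]
  ok <- c("A", "C", "G", "T", "N", "-")
  bad <- unique(c(a[!a %in% ok], b[!b %in% ok]))
  if (length(bad))
    stop("unexpected symbol(s) in alignment: ", paste(bad, collapse = ","))
  both <- a == "-" & b == "-"
  if (any(both))
    stop("column ", which(both)[1], " is a gap in both sequences")
  mapA <- ifelse(a == "-", NA_integer_, cumsum(a != "-"))
  mapB <- ifelse(b == "-", NA_integer_, cumsum(b != "-"))
  structure(list(idA = idA, idB = idB, gappedA = gappedA, gappedB = gappedB,
                 columns = length(a), mapA = as.integer(mapA),
                 mapB = as.integer(mapB)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Pairwise alignment ", x$idA, " / ", x$idB, ": ", x$columns,
      " columns (", sum(!is.na(x$mapA)), " / ", sum(!is.na(x$mapB)),
      " ungapped positions)\n", sep = "")
  invisible(x)
}

# ungapped source sequence of one side
ungapped <- function(aln, which = c("A", "B")) {
  which <- match.arg(which)
  gsub("-", "", if (which == "A") aln$gappedA else aln$gappedB, fixed = TRUE)
}

#' Read an aligned FASTA pair
#'
#' Expects exactly two records of equal aligned length, alphabet
#' `A`,`C`,`G`,`T`,`N`,`-` (case insensitive). Columns containing `N` are
#' later excluded from all counts and tallied separately by
#' [classify_columns()].
#'
#' @param path Path to an aligned FASTA file.
#' @return A [pairwise_alignment()].
#' @export
read_pairwise_fasta <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) != 2L)
    stop("expected exactly 2 FASTA records in '", path, "', found ",
         length(recs))
  pairwise_alignment(as.character(recs[[1]]), as.character(recs[[2]]),
                     idA = names(recs)[1], idB = names(recs)[2])
}

#' Write a pairwise alignment (or sequence pair) as FASTA
#'
#' @param aln A `pairwise_alignment`.
#' @param path Output path.
#' @param gapped Write the gapped (aligned) sequences (default) or the
#'   ungapped source sequences.
#' @return Invisibly, `path`.
#' @export
write_pairwise_fasta <- function(aln, path, gapped = TRUE) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  seqs <- if (gapped) list(aln$gappedA, aln$gappedB)
          else list(ungapped(aln, "A"), ungapped(aln, "B"))
  seqinr::write.fasta(seqs, names = c(aln$idA, aln$idB), file.out = path,
                      as.string = TRUE, nbchar = 70)
  invisible(path)
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh alignment of two nucleotide sequences. A gap of
#' length `k` costs `gap_open + k * gap_extend`. Tie-breaking is
#' deterministic: diagonal moves are preferred, then gaps in `seqB`, then
#' gaps in `seqA`, so repeated runs produce the identical alignment.
#' Intended for desk-scale sequences (both matrices are held in memory);
#' sequences longer than 50 kb are refused.
#'
#' @param seqA,seqB Non-empty nucleotide strings.
#' @param match,mismatch Substitution scores (defaults 1 / -1).
#' @param gap_open,gap_extend Affine gap parameters (defaults -2 / -1).
#' @param idA,idB Identifiers for the output alignment.
#' @return A [pairwise_alignment()] with an extra `score` element.
#' @examples
#' align_global("ACGT", "AGT")
#' @export
align_global <- function(seqA, seqB, match = 1, mismatch = -1,
                         gap_open = -2, gap_extend = -1,
                         idA = "A", idB = "B") {
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  if (!nzchar(seqA) || !nzchar(seqB)) stop("cannot align an empty sequence")
  if (nchar(seqA) > 50000L || nchar(seqB) > 50000L)
    stop("align_global is limited to sequences of at most 50 kb")
  if (grepl("[^ACGTN]", seqA) || grepl("[^ACGTN]", seqB))
    stop("sequences must be over A,C,G,T,N")
  res <- .align_global_cpp(seqA, seqB, match, mismatch, gap_open, gap_extend)
  aln <- pairwise_alignment(res$gappedA, res$gappedB, idA = idA, idB = idB)
  aln$score <- res$score
  aln
}

#' Classify every alignment column
#'
#' Each column is `identical`, a `transition` (A-G or T-C), a `transversion`
#' (T-A, C-A, T-G or C-G), an `indel` (gap on exactly one side) or `excluded`
#' (contains `N`; removed from every numerator and denominator and tallied
#' separately). Base pairs are recorded in the orientation of the aligned
#' sequences (major-strand orientation); minor-strand genes are not
#' complemented before tallying.
#'
#' @param aln A `pairwise_alignment`.
#' @return A data frame with one row per column: `column` (1-based index),
#'   `ref_pos` (position in sequence A, `NA` at columns gapped in A), `kind`
#'   and `pair` (canonical pair label for substitution columns, else `NA`).
#' @examples
#' classify_columns(pairwise_alignment("ACGT", "GCAT"))
#' @export
classify_columns <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  a <- strsplit(aln$gappedA, "", fixed = TRUE)[[1]]
  b <- strsplit(aln$gappedB, "", fixed = TRUE)[[1]]
  n <- length(a)
  kind <- rep("identical", n)
  sub <- a != b & a != "-" & b != "-"
  kind[a == "-" | b == "-"] <- "indel"
  pair <- rep(NA_character_, n)
  if (any(sub)) {
    key <- paste0(pmin(a[sub], b[sub]), pmax(a[sub], b[sub]))
    pair[sub] <- PAIR_LABELS[key]
    kind[sub] <- ifelse(pair[sub] %in% TS_PAIRS, "transition", "transversion")
  }
  ex <- a == "N" | b == "N"
  kind[ex] <- "excluded"
  pair[ex] <- NA_character_
  data.frame(column = seq_len(n), ref_pos = aln$mapA, kind = kind,
             pair = pair, stringsAsFactors = FALSE)
}
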