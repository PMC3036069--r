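COUNT_COLS <- c("AG", "TC", "TA", "CA", "TG", "CG", "indels")
PAIR_TO_COL <- c(`A-G` = "AG", `T-C` = "TC", `T-A` = "TA", `C-A` = "CA",
                 `T-G` = "TG", `C-G` = "CG")

new_spectrum_table <- function(df, comparison = c("A", "B"),
                               reference = comparison[1]) {
  for (col in c(COUNT_COLS, "compared_sites"))
    if (is.null(df[[col]])) df[[col]] <- 0L
  df$ts <- df$AG + df$TC
  df$tv <- df$TA + df$CA + df$TG + df$CG
  df$substitutions <- df$ts + df$tv
  df$variable <- df$substitutions + df$indels
  rownames(df) <- NULL
  structure(df, class = c("spectrum_table", "data.frame"),
            comparison = comparison, reference = reference)
}

#' Build a per-region substitution spectrum table
#'
#' Attributes every substitution and indel column of a pairwise alignment to
#' the gene/region of its reference-genome coordinate, producing one row per
#' feature (plus the pseudo-regions `intergenic` and, when categories are
#' filtered out, `excluded`) with the two transition counts, the four
#' transversion counts, indel columns and compared sites. Sequence A of the
#' alignment is the coordinate and annotation reference; columns that are
#' gaps in the reference are attributed to the region of the nearest
#' preceding reference position.
#'
#' @param aln A [pairwise_alignment()] whose ungapped sequence A equals
#'   `genome$sequence`.
#' @param genome The reference `annotated_genome` (annotations of sequence A).
#' @param categories Feature categories to report as their own rows; columns
#'   falling in features of other categories are pooled into the `excluded`
#'   pseudo-row so that totals are conserved. Default: everything except
#'   tRNA genes, the usual convention for mitogenome difference tables.
#' @param sites Column classification, by default [classify_columns()] of
#'   `aln`.
#' @return A `spectrum_table`: a data frame with columns `region`,
#'   `category`, `strand`, `length` (reference feature length, the default
#'   rate denominator), `compared_sites`, `AG`, `TC`, `TA`, `CA`, `TG`,
#'   `CG`, `indels`, and derived columns `ts`, `tv`, `substitutions`,
#'   `variable`.
#' @export
build_spectrum_table <- function(aln, genome,
                                 categories = c("protein", "rRNA",
                                                "at_rich", "other"),
                                 sites = classify_columns(aln)) {
  stopifnot(inherits(aln, "pairwise_alignment"),
            inherits(genome, "annotated_genome"))
  if (!identical(ungapped(aln, "A"), genome$sequence))
    stop("alignment sequence '", aln$idA,
         "' does not match genome '", genome$id, "' sequence")
  ridx <- region_index(genome)
  # fill reference coordinate forward across reference gap columns
  ref <- sites$ref_pos
  last <- cummax(ifelse(is.na(ref), 0L, seq_along(ref)))
  filled <- ifelse(last == 0L, NA_integer_, ref[pmax(last, 1L)])
  reg <- ifelse(is.na(filled), NA_character_, ridx[filled])
  f <- genome$features
  cat_of <- stats::setNames(f$category, f$name)
  reg[is.na(reg)] <- INTERGENIC
  drop <- reg != INTERGENIC & !(cat_of[reg] %in% categories)
  reg[drop] <- EXCLUDED

  keep <- f$category %in% categories
  regions <- c(f$name[keep], INTERGENIC, EXCLUDED)
  df <- data.frame(region = regions,
                   category = c(f$category[keep], INTERGENIC, EXCLUDED),
                   strand = c(f$strand[keep], NA, NA),
                   length = c(f$length[keep], NA_integer_, NA_integer_),
                   stringsAsFactors = FALSE)
  regf <- factor(reg, levels = regions)
  df$compared_sites <- as.integer(table(regf[sites$kind != "excluded"]))
  for (p in names(PAIR_TO_COL))
    df[[PAIR_TO_COL[p]]] <-
      as.integer(table(regf[sites$kind %in% c("transition", "transversion") &
                              sites$pair == p & !is.na(sites$pair)]))
  df$indels <- as.integer(table(regf[sites$kind == "indel"]))
  out <- new_spectrum_table(df, comparison = c(aln$idA, aln$idB))
  attr(out, "excluded_N_columns") <- sum(sites$kind == "excluded")
  out
}

#' @export
print.spectrum_table <- function(x, digits = 4, ...) {
  cmp <- attr(x, "comparison")
  cat("Substitution spectrum: ", cmp[1], " vs ", cmp[2], "\n", sep = "")
  show <- as.data.frame(x)[, c("region", "length", "AG", "TC", "ts", "TA",
                               "CA", "TG", "CG", "tv", "substitutions",
                               "indels")]
  show$rate <- round(region_rate(x), digits)
  print(show, row.names = FALSE)
  tot <- spectrum_totals(x)
  cat("Totals (named regions): ", tot$substitutions, " substitutions (",
      tot$ts, " ts, ", tot$tv, " tv), ", tot$indels, " indel columns\n",
      sep = "")
  invisible(x)
}

#' Aggregate a spectrum table
#'
#' Sums every count field over a set of rows (by default all real regions,
#' i.e. excluding the `intergenic`/`excluded` pseudo-rows; set
#' `regions = "all"` to include them and recover alignment-wide totals).
#'
#' @param table A `spectrum_table`.
#' @param regions Character vector of region names, or `"all"`.
#' @return Named list of summed counts (`AG` ... `CG`, `indels`,
#'   `compared_sites`, `ts`, `tv`, `substitutions`, `variable`, `length`).
#' @export
spectrum_totals <- function(table, regions = NULL) {
  stopifnot(inherits(table, "spectrum_table"))
  rows <- if (identical(regions, "all")) rep(TRUE, nrow(table))
          else if (is.null(regions)) !table$region %in% c(INTERGENIC, EXCLUDED)
          else table$region %in% regions
  cols <- c(COUNT_COLS, "compared_sites", "ts", "tv", "substitutions",
            "variable")
  out <- lapply(cols, function(cn) sum(table[[cn]][rows]))
  names(out) <- cols
  out$length <- sum(table$length[rows], na.rm = TRUE)
  out
}

#' Per-region substitution rate
#'
#' Substitutions divided by the region's denominator length (the reference
#' feature length unless overridden with [set_denominator()]); indel columns
#' are not substitutions and are excluded from the numerator.
#'
#' @param table A `spectrum_table`.
#' @return Named numeric vector of rates (`NA` for pseudo-rows without a
#'   denominator).
#' @export
region_rate <- function(table) {
  stopifnot(inherits(table, "spectrum_table"))
  if (any(!is.na(table$length) & table$length <= 0))
    stop("non-positive denominator length")
  stats::setNames(table$substitutions / table$length, table$region)
}

#' Override rate denominators
#'
#' Published difference tables sometimes mix length conventions between the
#' two genomes of a pair (e.g. using the second genome's gene length for one
#' row); this sets per-region denominator lengths explicitly.
#'
#' @param table A `spectrum_table`.
#' @param overrides Named integer vector, e.g. `c(cob = 1158)`.
#' @return The table with updated `length` values.
#' @export
set_denominator <- function(table, overrides) {
  stopifnot(inherits(table, "spectrum_table"))
  bad <- setdiff(names(overrides), table$region)
  if (length(bad))
    stop("length override for unknown region(s): ", paste(bad, collapse = ", "))
  table$length[match(names(overrides), table$region)] <-
    as.integer(overrides)
  table
}

#' Sequence divergence
#'
#' Variable alignment columns (substitutions plus indel columns) divided by
#' the alignment length.
#'
#' @param variable_sites Number of variable columns.
#' @param alignment_columns Alignment length (> 0).
#' @return Proportion in `[0, 1]`.
#' @examples
#' divergence(639, 15970) # 4.00%
#' @export
divergence <- function(variable_sites, alignment_columns) {
  if (alignment_columns <= 0) stop("alignment_columns must be > 0")
  if (variable_sites < 0 || variable_sites > alignment_columns)
    stop("variable_sites must lie in [0, alignment_columns]")
  variable_sites / alignment_columns
}

#' Base composition
#'
#' Fractions of A, C, G, T (and A+T) over the counted bases; `N` and gap
#' characters are excluded from the denominator.
#'
#' @param sequence Nucleotide string.
#' @return Named numeric vector with elements `A`, `C`, `G`, `T`, `AT`.
#' @examples
#' base_composition("AATT")["AT"]
#' @export
base_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  s <- s[s %in% c("A", "C", "G", "T")]
  if (!length(s)) stop("no countable bases in sequence")
  n <- table(factor(s, levels = c("A", "C", "G", "T")))
  frac <- as.numeric(n) / length(s)
  names(frac) <- c("A", "C", "G", "T")
  c(frac, AT = unname(frac["A"] + frac["T"]))
}

#' Split transition counts by coding strand
#'
#' Sums the A-G and T-C transition counts of one feature category over
#' major- versus minor-strand features, together with the summed denominator
#' lengths — the input of the strand-asymmetry tests.
#'
#' @param table A `spectrum_table`.
#' @param category Feature category to partition (default `"protein"`).
#' @return An object of class `strand_summary`: list with `major_bp`,
#'   `minor_bp`, `major_AG`, `major_TC`, `minor_AG`, `minor_TC`.
#' @export
strand_partition <- function(table, category = "protein") {
  stopifnot(inherits(table, "spectrum_table"))
  rows <- table[!is.na(table$strand) & table$category %in% category, ,
                drop = FALSE]
  if (!nrow(rows))
    stop("no stranded rows of category '", paste(category, collapse = ","),
         "' in spectrum table")
  mj <- rows$strand == "major"
  structure(list(category = category,
                 major_bp = sum(rows$length[mj]),
                 minor_bp = sum(rows$length[!mj]),
                 major_AG = sum(rows$AG[mj]), major_TC = sum(rows$TC[mj]),
                 minor_AG = sum(rows$AG[!mj]), minor_TC = sum(rows$TC[!mj])),
            class = "strand_summary")
}

#' @export
print.strand_summary <- function(x, ...) {
  cat("Strand transition summary (", paste(x$category, collapse = ","),
      ")\n", sep = "")
  cat(sprintf("  major: %d A-G, %d T-C in %d bp\n",
              x$major_AG, x$major_TC, x$major_bp))
  cat(sprintf("  minor: %d A-G, %d T-C in %d bp\n",
              x$minor_AG, x$minor_TC, x$minor_bp))
  invisible(x)
}

#' Read/write spectrum tables as TSV
#'
#' The TSV mirrors the usual published layout (region, bp, A-G, T-C,
#' transition total, T-A, C-A, T-G, C-G, transversion total, sum, rate) plus
#' `strand`, `category`, optional `bp_alt` (the second genome's length where
#' it differs) and `indels`/`compared_sites`. Printed difference tables can
#' therefore be ingested as fixtures and reanalyzed without sequence data.
#'
#' @param path TSV path.
#' @param table A `spectrum_table`.
#' @param comparison Identifier pair for the ingested table.
#' @return `read_spectrum_tsv()`: a `spectrum_table` (with a `bp_alt`
#'   attribute column if present); `write_spectrum_tsv()`: invisibly `path`.
#' @export
read_spectrum_tsv <- function(path, comparison = c("A", "B")) {
  if (!file.exists(path)) stop("spectrum table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  req <- c("region", "bp", "strand", "category",
           "A.G", "T.C", "T.A", "C.A", "T.G", "C.G")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("spectrum TSV '", path, "': missing column(s): ",
         paste(gsub(".", "-", miss, fixed = TRUE), collapse = ", "))
  df <- data.frame(region = raw$region, category = raw$category,
                   strand = raw$strand, length = as.integer(raw$bp),
                   AG = as.integer(raw$A.G), TC = as.integer(raw$T.C),
                   TA = as.integer(raw$T.A), CA = as.integer(raw$C.A),
                   TG = as.integer(raw$T.G), CG = as.integer(raw$C.G),
                   stringsAsFactors = FALSE)
  df$indels <- if (is.null(raw$indels)) 0L else as.integer(raw$indels)
  df$compared_sites <- if (is.null(raw$compared_sites)) NA_integer_
                       else as.integer(raw$compared_sites)
  if (!is.null(raw$bp_alt)) df$bp_alt <- as.integer(raw$bp_alt)
  pseudo <- df$region %in% c(INTERGENIC, EXCLUDED)
  if (any(is.na(df$length) & !pseudo))
    stop("spectrum TSV '", path, "': unparsable bp column")
  new_spectrum_table(df, comparison = comparison)
}

#' @rdname read_spectrum_tsv
#' @export
write_spectrum_tsv <- function(table, path) {
  stopifnot(inherits(table, "spectrum_table"))
  out <- data.frame(region = table$region, bp = table$length,
                    strand = table$strand, category = table$category,
                    `A-G` = table$AG, `T-C` = table$TC, ts_total = table$ts,
                    `T-A` = table$TA, `C-A` = table$CA, `T-G` = table$TG,
                    `C-G` = table$CG, tv_total = table$tv,
                    sum = table$substitutions,
                    rate = round(region_rate(table), 4),
                    indels = table$indels,
                    compared_sites = table$compared_sites,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
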