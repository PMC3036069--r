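#' Construct an annotated genome
#'
#' Bundles a linearized (circular genomes are analyzed in their deposited
#' orientation) nucleotide sequence with its gene features. Coordinates are
#' 1-based inclusive throughout, the GenBank convention.
#'
#' @param id Genome identifier.
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T` (case
#'   insensitive). Ambiguity codes are rejected unless `ambiguity = "mask"`,
#'   in which case every non-ACGT code is replaced by `N` and later excluded
#'   from all counts.
#' @param features Data frame of gene features with columns `name`, `start`,
#'   `end`, `strand` (`"major"`/`"minor"`), `category` (one of `"protein"`,
#'   `"rRNA"`, `"at_rich"`, `"tRNA"`, `"other"`) and optionally a logical
#'   `overlap` column flagging features that are allowed to overlap others.
#'   May be `NULL` for a feature-less genome.
#' @param ambiguity Policy for non-ACGT symbols: `"reject"` (default) or
#'   `"mask"`.
#' @return An object of class `annotated_genome`: a list with elements `id`,
#'   `sequence`, `features` and `length`.
#' @examples
#' g <- annotated_genome("toy", "ACGTACGTAC",
#'   data.frame(name = "g1", start = 2, end = 6,
#'              strand = "major", category = "protein"))
#' g$length
#' @export
annotated_genome <- function(id, sequence, features = NULL,
                             ambiguity = c("reject", "mask")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("genome '", id, "': empty sequence")
  bad <- gsub("[ACGT]", "", sequence)
  if (nzchar(bad)) {
    if (ambiguity == "reject") {
      stop("genome '", id, "': non-ACGT symbols present (",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ","),
           "); use ambiguity = \"mask\" to replace them with N")
    }
    sequence <- gsub("[^ACGT]", "N", sequence)
  }
  len <- nchar(sequence)
  features <- validate_features(features, len, id)
  structure(list(id = id, sequence = sequence, features = features,
                 length = len),
            class = "annotated_genome")
}

validate_features <- function(features, genome_length, id = "?") {
  if (is.null(features) || nrow(features) == 0L) {
    return(data.frame(name = character(), start = integer(), end = integer(),
                      strand = character(), category = character(),
                      length = integer(), overlap = logical(),
                      stringsAsFactors = FALSE))
  }
  req <- c("name", "start", "end", "strand", "category")
  miss <- setdiff(req, names(features))
  if (length(miss))
    stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (anyNA(features$start) || anyNA(features$end))
    stop("feature table: non-integer coordinates")
  if (any(features$start < 1L))
    stop("feature table: start coordinates must be >= 1")
  bad <- features$end < features$start
  if (any(bad))
    stop("feature '", features$name[which(bad)[1]],
         "': end < start (features wrapping the origin are not supported; ",
         "linearize so that no feature spans the cut)")
  if (any(features$end > genome_length))
    stop("genome '", id, "': feature coordinates exceed genome length ",
         genome_length)
  bad <- !features$strand %in% STRANDS
  if (any(bad))
    stop("feature '", features$name[which(bad)[1]], "': unknown strand '",
         features$strand[which(bad)[1]], "' (expected major/minor)")
  bad <- !features$category %in% CATEGORIES
  if (any(bad))
    stop("feature '", features$name[which(bad)[1]], "': unknown category '",
         features$category[which(bad)[1]], "' (expected ",
         paste(CATEGORIES, collapse = "/"), ")")
  if (anyDuplicated(features$name))
    stop("feature table: duplicated feature name(s): ",
         paste(unique(features$name[duplicated(features$name)]),
               collapse = ", "))
  if (is.null(features$overlap)) features$overlap <- FALSE
  features$overlap <- isTRUE(features$overlap) | features$overlap %in% TRUE
  features$length <- features$end - features$start + 1L
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  # overlap check: consecutive-in-start order is sufficient for detection
  if (nrow(features) > 1L) {
    hi <- cummax(features$end)
    ov <- which(features$start[-1L] <= hi[-nrow(features)])
    for (k in ov) {
      f2 <- features[k + 1L, ]
      prev <- features[seq_len(k), ]
      hit <- prev[prev$end >= f2$start, , drop = FALSE]
      ok <- f2$overlap | hit$overlap
      if (!all(ok))
        stop("features '", hit$name[which(!ok)[1]], "' and '", f2$name,
             "' overlap without an overlap flag")
    }
  }
  features[, c("name", "start", "end", "strand", "category", "length",
               "overlap")]
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("Annotated genome '", x$id, "': ", x$length, " bp, ",
      nrow(x$features), " features\n", sep = "")
  if (nrow(x$features)) {
    tab <- table(x$features$category)
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Read a gene feature table
#'
#' Reads a tab-separated annotation with columns `name`, `start`, `end`,
#' `strand` and `category` (1-based inclusive coordinates) and validates it.
#' An optional logical `overlap` column marks features allowed to overlap.
#'
#' @param file Path to the tab-separated table (header required).
#' @param genome_id Identifier used in error messages.
#' @return Validated feature data frame sorted by start coordinate, with a
#'   computed `length` column.
#' @export
read_annotation <- function(file, genome_id = file) {
  if (!file.exists(file)) stop("annotation file not found: ", file)
  raw <- utils::read.delim(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  req <- c("name", "start", "end", "strand", "category")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("annotation '", file, "': missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v) | v < 1L)
    if (length(bad))
      stop("annotation '", file, "': line ", bad[1] + 1L,
           ": cannot parse '", raw[[col]][bad[1]],
           "' as a positive integer ", col)
    raw[[col]] <- v
  }
  validate_features(raw, genome_length = max(raw$end), id = genome_id)
}

#' Write a gene feature table
#'
#' @param features Feature data frame (as in [annotated_genome()]).
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_annotation <- function(features, file) {
  utils::write.table(
    features[, c("name", "start", "end", "strand", "category")],
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Default conserved/variable gene classes
#'
#' The standard two-class grouping of Bombyx mitochondrial protein-coding
#' genes used in regional-rate contrasts: Class 1, the five protein genes
#' surrounding the A+T-rich control region (more conserved), and Class 2,
#' the remaining large protein genes (less conserved).
#'
#' @return An object of class `gene_class_map`: a list with character vectors
#'   `class1` and `class2`.
#' @examples
#' default_gene_classes()
#' @export
default_gene_classes <- function() {
  gene_class_map(class1 = c("nad2", "cox1", "cox2", "atp6", "nad1"),
                 class2 = c("cox3", "nad4", "nad5", "cob"))
}

#' @rdname default_gene_classes
#' @param class1,class2 Character vectors of protein-coding gene names; the
#'   two sets must be disjoint.
#' @export
gene_class_map <- function(class1, class2) {
  class1 <- as.character(class1); class2 <- as.character(class2)
  if (length(intersect(class1, class2)))
    stop("gene classes must be disjoint; shared: ",
         paste(intersect(class1, class2), collapse = ", "))
  structure(list(class1 = class1, class2 = class2), class = "gene_class_map")
}

#' @export
print.gene_class_map <- function(x, ...) {
  cat("Gene classes:\n  class1:", paste(x$class1, collapse = ", "),
      "\n  class2:", paste(x$class2, collapse = ", "), "\n")
  invisible(x)
}

#' Map genome positions to regions
#'
#' `region_index()` returns, for every position of the genome, the name of the
#' feature covering it (or `NA` for intergenic positions). Where permitted
#' overlaps exist, the covering feature is chosen by category priority
#' (protein > rRNA > at_rich > tRNA > other), ties going to the feature with
#' the smaller start. `region_of()` looks up a single position and returns the
#' prioritized feature row, or `NULL` for intergenic positions.
#'
#' @param genome An `annotated_genome`.
#' @param position 1-based position in `[1, genome$length]`.
#' @return `region_index()`: character vector of length `genome$length`;
#'   `region_of()`: a one-row feature data frame or `NULL`.
#' @export
region_index <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  idx <- rep(NA_character_, genome$length)
  f <- genome$features
  if (!nrow(f)) return(idx)
  prio <- CATEGORY_PRIORITY[f$category]
  # assign in increasing priority so high-priority features overwrite;
  # within a priority level assign later starts first so earlier starts win
  ord <- order(prio, -f$start)
  for (i in ord) idx[f$start[i]:f$end[i]] <- f$name[i]
  idx
}

#' @rdname region_index
#' @export
region_of <- function(genome, position) {
  stopifnot(inherits(genome, "annotated_genome"))
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > genome$length)
    stop("position ", position, " outside [1, ", genome$length, "]")
  f <- genome$features
  hit <- f[f$start <= position & f$end >= position, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  if (nrow(hit) > 1L) {
    hit <- hit[order(-CATEGORY_PRIORITY[hit$category], hit$start), ,
               drop = FALSE]
  }
  hit[1L, , drop = FALSE]
}

# reverse complement of an ACGTN/- string (gaps preserved)
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}
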