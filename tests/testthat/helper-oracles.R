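# Independent oracles and small generators used across the test files.

# Naive Pearson chi-square: cell-by-cell sum((O - E)^2 / E).
# For a matrix, E has the observed margins; for a vector, E = sum(o) * p.
naive_chisq <- function(observed, p = NULL) {
  if (is.matrix(observed)) {
    e <- outer(rowSums(observed), colSums(observed)) / sum(observed)
  } else {
    e <- sum(observed) * p
  }
  sum((observed - e)^2 / e)
}

# Brute-force global affine-gap alignment score by naive recursion with
# memoization over (i, j, previous-move), independent of the DP layout used
# by the package aligner. state: 0 = none/diagonal, 1 = gap in B, 2 = gap in A.
brute_align_score <- function(a, b, match = 1, mismatch = -1,
                              gap_open = -2, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    if (i > n && j > m) return(0)
    key <- paste(i, j, state)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, (if (av[i] == bv[j]) match else mismatch) +
                    rec(i + 1, j + 1, 0))
    if (i <= n)
      best <- max(best, (if (state == 1) gap_extend else
        gap_open + gap_extend) + rec(i + 1, j, 1))
    if (j <= m)
      best <- max(best, (if (state == 2) gap_extend else
        gap_open + gap_extend) + rec(i, j + 1, 2))
    memo[[key]] <- best
    best
  }
  rec(1, 1, 0)
}

random_seq <- function(n, at = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

# Path to the bundled silkmoth gene-difference table
fixture_table_path <- function() {
  system.file("extdata", "bmori_chbm_gene_differences.tsv",
              package = "mitosub")
}

read_fixture_table <- function() {
  read_spectrum_tsv(fixture_table_path(), comparison = c("Bmori_C108", "ChBm"))
}

# Printed per-gene values of the bundled table, used as frozen expectations
fixture_printed_sums <- c(nad2 = 20, cox1 = 33, cox2 = 14, atp8 = 2,
                          atp6 = 12, cox3 = 33, nad3 = 9, nad6 = 5,
                          cob = 50, nad5 = 39, nad4 = 32, nad4L = 9,
                          nad1 = 16, lrRNA = 18, srRNA = 12, at_rich = 13)
fixture_printed_rates <- c(nad2 = 0.0196, cox1 = 0.0215, cox2 = 0.0205,
                           atp8 = 0.0123, atp6 = 0.0177, cox3 = 0.0418,
                           nad3 = 0.0256, nad6 = 0.0094, cob = 0.0434,
                           nad5 = 0.0227, nad4 = 0.0238, nad4L = 0.0309,
                           nad1 = 0.0169, lrRNA = 0.0133, srRNA = 0.0153,
                           at_rich = 0.0269)

# Equal-rate (null) mutation parameters over the default layout
null_params <- function(rate = 0.02, indel_rate = 0) {
  regions <- c(bombyx_layout()$features$name, "intergenic")
  mutation_params(region_rate = setNames(rep(rate, length(regions)), regions),
                  major_TC_given_ts = 0.5, minor_AG_given_ts = 0.5,
                  indel_rate = indel_rate)
}
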