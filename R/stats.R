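new_chisq_result <- function(statistic, df, observed, expected, label) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = chisq_pvalue(unname(statistic), unname(df)),
                 observed = observed, expected = expected, label = label),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("%s: X-squared = %.2f, d.f. = %d, p = %.4g\n",
              x$label, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Upper-tail chi-square probability
#'
#' @param statistic Chi-square statistic (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @return Upper-tail probability.
#' @export
chisq_pvalue <- function(statistic, df) {
  if (any(df < 1)) stop("df must be >= 1")
  if (any(statistic < 0)) stop("statistic must be >= 0")
  stats::pchisq(statistic, df, lower.tail = FALSE)
}

#' Transition:transversion ratio
#'
#' @param ts,tv Transition and transversion counts.
#' @return A `kappa_summary`: list with `ts`, `tv`, `kappa` (`NA` and
#'   flagged `undefined` when `tv` is 0).
#' @examples
#' kappa_ratio(230, 151)
#' @export
kappa_ratio <- function(ts, tv) {
  if (ts < 0 || tv < 0) stop("counts must be non-negative")
  if (ts == 0 && tv == 0) stop("no substitutions: kappa is undefined")
  structure(list(ts = ts, tv = tv,
                 kappa = if (tv > 0) ts / tv else NA_real_,
                 undefined = tv == 0),
            class = "kappa_summary")
}

#' @export
print.kappa_summary <- function(x, ...) {
  if (x$undefined)
    cat(sprintf("ts:tv = %d:%d, kappa undefined (no transversions)\n",
                x$ts, x$tv))
  else
    cat(sprintf("ts:tv = %d/%d, kappa = %.2f\n", x$ts, x$tv, x$kappa))
  invisible(x)
}

#' Chi-square goodness-of-fit test
#'
#' Pearson test of observed counts against expected proportions (e.g. the
#' neutral 1:2 transition:transversion expectation under equal per-type
#' rates). No continuity correction.
#'
#' @param observed Non-negative count vector (length >= 2).
#' @param expected_proportions Proportions summing to 1, all > 0. Default:
#'   the neutral 1:2 transition:transversion expectation.
#' @param label Test label carried into reports.
#' @return A `chisq_result`.
#' @examples
#' chisq_gof(c(230, 151))
#' @export
chisq_gof <- function(observed, expected_proportions = c(1, 2) / 3,
                      label = "goodness-of-fit") {
  if (length(observed) < 2L) stop("need at least 2 cells")
  if (any(observed < 0)) stop("negative observed count")
  p <- expected_proportions
  if (length(p) != length(observed))
    stop("observed and expected_proportions differ in length")
  if (any(p <= 0)) stop("expected proportions must all be > 0")
  if (abs(sum(p) - 1) > 1e-8) stop("expected proportions must sum to 1")
  expected <- sum(observed) * p
  if (any(expected <= 0)) stop("zero expected count")
  ht <- suppressWarnings(stats::chisq.test(observed, p = p))
  new_chisq_result(ht$statistic, ht$parameter, observed, expected, label)
}

#' Chi-square contingency test
#'
#' Pearson test of homogeneity/independence on an r x c count table, no
#' continuity correction (also for 2 x 2 tables, matching the convention of
#' published mitogenome comparisons).
#'
#' @param observed Count matrix, r and c >= 2, all marginals > 0.
#' @param label Test label.
#' @return A `chisq_result` (its `expected` table has the observed margins).
#' @examples
#' chisq_contingency(rbind(c(230, 151), c(414, 100)))
#' @export
chisq_contingency <- function(observed, label = "contingency") {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2L || ncol(observed) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(observed < 0)) stop("negative observed count")
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
    stop("degenerate table: zero row or column marginal")
  ht <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  new_chisq_result(ht$statistic, ht$parameter, observed, ht$expected, label)
}

#' Substitution-rate heterogeneity across regions
#'
#' Treats each site of region i as a Bernoulli trial (substituted or not),
#' builds the k x 2 table `(counts, lengths - counts)` and applies the
#' Pearson contingency test; df = k - 1.
#'
#' @param counts Per-region substitution counts.
#' @param lengths Per-region denominator lengths (counts <= lengths).
#' @param label Test label.
#' @return A `chisq_result`.
#' @examples
#' rate_heterogeneity_test(c(33, 32, 39, 50), c(789, 1341, 1719, 1152))
#' @export
rate_heterogeneity_test <- function(counts, lengths,
                                    label = "rate heterogeneity") {
  if (length(counts) != length(lengths))
    stop("counts and lengths differ in length")
  if (length(counts) < 2L)
    stop("rate heterogeneity needs at least 2 regions (df >= 1)")
  if (any(counts > lengths))
    stop("substitution count exceeds region length")
  m <- cbind(substituted = counts, unsubstituted = lengths - counts)
  rownames(m) <- names(counts)
  chisq_contingency(m, label = label)
}

#' Pooled-rate contrast between two gene classes
#'
#' Pools substitution counts and denominator lengths over each class of
#' protein-coding genes, reports the two pooled rates and tests their
#' equality with a 2 x 2 (substituted / unsubstituted by class) Pearson
#' test.
#'
#' @param table A `spectrum_table` containing every class member as a row.
#' @param classes A [gene_class_map()]; default [default_gene_classes()].
#' @return An object of class `class_contrast`: list with `rate1`, `rate2`,
#'   per-class counts/lengths and `test` (a `chisq_result`).
#' @export
class_rate_contrast <- function(table, classes = default_gene_classes()) {
  stopifnot(inherits(table, "spectrum_table"),
            inherits(classes, "gene_class_map"))
  miss <- setdiff(c(classes$class1, classes$class2), table$region)
  if (length(miss))
    stop("gene(s) missing from spectrum table: ", paste(miss, collapse = ", "))
  t1 <- spectrum_totals(table, classes$class1)
  t2 <- spectrum_totals(table, classes$class2)
  m <- rbind(class1 = c(t1$substitutions, t1$length - t1$substitutions),
             class2 = c(t2$substitutions, t2$length - t2$substitutions))
  colnames(m) <- c("substituted", "unsubstituted")
  structure(list(rate1 = t1$substitutions / t1$length,
                 rate2 = t2$substitutions / t2$length,
                 counts = c(class1 = t1$substitutions,
                            class2 = t2$substitutions),
                 lengths = c(class1 = t1$length, class2 = t2$length),
                 test = chisq_contingency(m, label = "class rate contrast")),
            class = "class_contrast")
}

#' @export
print.class_contrast <- function(x, ...) {
  cat(sprintf("Pooled rates: class1 = %.4f (%d/%d), class2 = %.4f (%d/%d)\n",
              x$rate1, x$counts[1], x$lengths[1],
              x$rate2, x$counts[2], x$lengths[2]))
  print(x$test)
  invisible(x)
}

#' Strand-asymmetry tests for transition counts
#'
#' Three 2 x 2 Pearson tests comparing major- versus minor-strand
#' protein-coding genes, each as (event count, bp - event count): all
#' transitions, T-C transitions only, A-G transitions only.
#'
#' @param s A `strand_summary` from [strand_partition()].
#' @return Named list of three `chisq_result`s: `ts`, `TC`, `AG`.
#' @export
strand_asymmetry_tests <- function(s) {
  stopifnot(inherits(s, "strand_summary"))
  if (s$major_bp <= 0 || s$minor_bp <= 0)
    stop("both strands need a positive bp total")
  one <- function(maj, mnr, what) {
    if (maj > s$major_bp || mnr > s$minor_bp)
      stop("event count exceeds strand bp total")
    m <- rbind(major = c(maj, s$major_bp - maj),
               minor = c(mnr, s$minor_bp - mnr))
    colnames(m) <- c("events", "other_sites")
    chisq_contingency(m, label = paste("strand asymmetry:", what))
  }
  list(ts = one(s$major_AG + s$major_TC, s$minor_AG + s$minor_TC,
                "all transitions"),
       TC = one(s$major_TC, s$minor_TC, "T-C transitions"),
       AG = one(s$major_AG, s$minor_AG, "A-G transitions"))
}

#' Run the full chi-square battery on a spectrum table
#'
#' The standard statistical battery of a pairwise mitogenome comparison,
#' computable from a printed difference table alone: the
#' transition:transversion ratio and its goodness-of-fit against the neutral
#' 1:2 expectation, rate heterogeneity across all protein-coding genes and
#' within each gene class, the pooled class-rate contrast, and the three
#' strand-asymmetry tests.
#'
#' @param table A `spectrum_table`.
#' @param classes A [gene_class_map()].
#' @param strand_length_overrides Optional named vector of denominator
#'   overrides applied only to the strand tests (published strand bp totals
#'   sometimes use the other genome's gene length).
#' @param ts,tv Optional genome-wide transition/transversion counts for the
#'   kappa block; default: totals over the table's named regions.
#' @return An object of class `battery`: named list of results
#'   (`kappa`, `ts_tv_neutral`, `protein_heterogeneity`, `within_class1`,
#'   `within_class2`, `class_contrast`, `strand`).
#' @export
substitution_battery <- function(table, classes = default_gene_classes(),
                                 strand_length_overrides = NULL,
                                 ts = NULL, tv = NULL) {
  stopifnot(inherits(table, "spectrum_table"))
  tot <- spectrum_totals(table)
  if (is.null(ts)) ts <- tot$ts
  if (is.null(tv)) tv <- tot$tv
  prot <- table[table$category %in% "protein", , drop = FALSE]
  het <- if (nrow(prot) >= 2L)
    rate_heterogeneity_test(
      stats::setNames(prot$substitutions, prot$region), prot$length,
      label = "protein-coding gene rate heterogeneity")
  within <- function(members, lab) {
    rows <- table[match(members, table$region), , drop = FALSE]
    rate_heterogeneity_test(
      stats::setNames(rows$substitutions, rows$region), rows$length,
      label = lab)
  }
  stab <- if (is.null(strand_length_overrides)) table
          else set_denominator(table, strand_length_overrides)
  res <- list(
    kappa = kappa_ratio(ts, tv),
    ts_tv_neutral = chisq_gof(c(ts = ts, tv = tv),
                              label = "ts:tv vs neutral 1:2"),
    protein_heterogeneity = het,
    within_class1 = within(classes$class1, "rate heterogeneity within class1"),
    within_class2 = within(classes$class2, "rate heterogeneity within class2"),
    class_contrast = class_rate_contrast(table, classes),
    strand = strand_asymmetry_tests(strand_partition(stab, "protein"))
  )
  structure(res, class = "battery")
}

#' @export
print.battery <- function(x, ...) {
  print(x$kappa)
  print(x$ts_tv_neutral)
  if (!is.null(x$protein_heterogeneity)) print(x$protein_heterogeneity)
  print(x$within_class1)
  print(x$within_class2)
  print(x$class_contrast)
  for (t in x$strand) print(t)
  invisible(x)
}

battery_to_list <- function(x) {
  as_l <- function(r) {
    if (inherits(r, "chisq_result"))
      list(label = r$label, statistic = r$statistic, df = r$df,
           p_value = r$p_value,
           observed = if (is.matrix(r$observed))
             apply(r$observed, 1, as.list, simplify = FALSE)
           else as.list(r$observed),
           expected = if (is.matrix(r$expected))
             apply(r$expected, 1, as.list, simplify = FALSE)
           else as.list(r$expected))
    else if (inherits(r, "kappa_summary"))
      list(ts = r$ts, tv = r$tv, kappa = r$kappa)
    else if (inherits(r, "class_contrast"))
      list(rate1 = r$rate1, rate2 = r$rate2, test = as_l(r$test))
    else if (is.list(r)) lapply(r, as_l)
    else r
  }
  lapply(unclass(x), as_l)
}

#' Write a battery of test results as JSON
#'
#' @param battery A `battery` (or any list of `chisq_result`s).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_battery_json <- function(battery, path) {
  jsonlite::write_json(battery_to_list(battery), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
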