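#' End-to-end pairwise mitogenome comparison
#'
#' Orchestrates the full analysis of one genome pair: column classification,
#' the per-region substitution spectrum, alignment-wide divergence, the
#' transition:transversion ratio and the chi-square battery.
#'
#' @param aln A [pairwise_alignment()] (sequence A is the reference).
#' @param genome The reference `annotated_genome`.
#' @param categories Feature categories reported as spectrum rows (default:
#'   all but tRNA).
#' @param classes A [gene_class_map()] for the class contrast.
#' @param strand_length_overrides Optional denominator overrides for the
#'   strand tests (see [substitution_battery()]).
#' @return An object of class `mito_comparison`: list with `spectrum`
#'   (`spectrum_table`), `battery`, `divergence`, `kappa`,
#'   `composition` (per-genome base composition) and `columns`.
#' @export
compare_mitogenomes <- function(aln, genome,
                                categories = c("protein", "rRNA",
                                               "at_rich", "other"),
                                classes = default_gene_classes(),
                                strand_length_overrides = NULL) {
  sites <- classify_columns(aln)
  spec <- build_spectrum_table(aln, genome, categories = categories,
                               sites = sites)
  allt <- spectrum_totals(spec, "all")
  n_excl <- attr(spec, "excluded_N_columns")
  div <- divergence(allt$variable, aln$columns - n_excl)
  battery <- substitution_battery(
    spec, classes = classes,
    strand_length_overrides = strand_length_overrides,
    ts = allt$ts, tv = allt$tv)
  structure(list(spectrum = spec, battery = battery, divergence = div,
                 kappa = battery$kappa, columns = aln$columns,
                 variable_sites = allt$variable,
                 substitutions = allt$substitutions,
                 composition = list(
                   A = base_composition(ungapped(aln, "A")),
                   B = base_composition(ungapped(aln, "B")))),
            class = "mito_comparison")
}

#' @export
print.mito_comparison <- function(x, ...) {
  cmp <- attr(x$spectrum, "comparison")
  cat("Mitogenome comparison: ", cmp[1], " vs ", cmp[2], "\n", sep = "")
  cat(sprintf("  %d alignment columns, %d variable sites (%.2f%% divergence), %d substitutions\n",
              x$columns, x$variable_sites, 100 * x$divergence,
              x$substitutions))
  cat(sprintf("  A+T content: %.2f%% / %.2f%%\n",
              100 * x$composition$A["AT"], 100 * x$composition$B["AT"]))
  print(x$kappa)
  print(x$battery$class_contrast)
  invisible(x)
}

#' Write a comparison report bundle
#'
#' Writes the spectrum table (TSV, published-table layout), the chi-square
#' battery (JSON) and a short plain-text summary into a directory.
#'
#' @param cmp A `mito_comparison`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_comparison <- function(cmp, dir) {
  stopifnot(inherits(cmp, "mito_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(spectrum = file.path(dir, "spectrum.tsv"),
             battery = file.path(dir, "battery.json"),
             summary = file.path(dir, "summary.txt"))
  write_spectrum_tsv(cmp$spectrum, paths["spectrum"])
  write_battery_json(cmp$battery, paths["battery"])
  con <- file(paths["summary"], "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(cmp)
  invisible(paths)
}

#' Reanalyze a printed difference table
#'
#' Runs the chi-square battery on a spectrum TSV alone — no sequences needed
#' — so published per-gene difference tables can be ingested and their
#' statistics recomputed.
#'
#' @param table_path Spectrum TSV (see [read_spectrum_tsv()]).
#' @param classes A [gene_class_map()].
#' @param strand_length_overrides Optional named denominator overrides for
#'   the strand tests; the special value `"bp_alt"` uses the table's
#'   `bp_alt` column (the second genome's lengths) where present.
#' @param out Optional JSON output path.
#' @return The `battery`, invisibly if `out` is given.
#' @export
table_battery <- function(table_path, classes = default_gene_classes(),
                          strand_length_overrides = NULL, out = NULL) {
  tab <- read_spectrum_tsv(table_path)
  if (identical(strand_length_overrides, "bp_alt")) {
    if (is.null(tab$bp_alt)) stop("table has no bp_alt column")
    sel <- !is.na(tab$bp_alt)
    strand_length_overrides <- stats::setNames(tab$bp_alt[sel],
                                               tab$region[sel])
  }
  bat <- substitution_battery(tab, classes = classes,
                              strand_length_overrides =
                                strand_length_overrides)
  if (!is.null(out)) {
    write_battery_json(bat, out)
    return(invisible(bat))
  }
  bat
}

#' Write a simulated pair to disk
#'
#' Writes the five files of a simulation bundle: the two unaligned genome
#' FASTAs, the two annotation TSVs and the truth ledger JSON (parameters,
#' event list and per-region realized counts).
#'
#' @param sim Result of [simulate_pair()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fastaA = file.path(dir, "ancestor.fasta"),
             fastaB = file.path(dir, "derived.fasta"),
             annoA = file.path(dir, "ancestor_features.tsv"),
             annoB = file.path(dir, "derived_features.tsv"),
             ledger = file.path(dir, "truth_ledger.json"))
  seqinr::write.fasta(list(sim$ancestor$sequence), sim$ancestor$id,
                      paths["fastaA"], as.string = TRUE, nbchar = 70)
  seqinr::write.fasta(list(sim$derived$sequence), sim$derived$id,
                      paths["fastaB"], as.string = TRUE, nbchar = 70)
  write_annotation(sim$ancestor$features, paths["annoA"])
  write_annotation(sim$derived$features, paths["annoB"])
  led <- sim$ledger
  jsonlite::write_json(
    list(params = unclass(led$params), events = led$events,
         counts = led$counts),
    paths["ledger"], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(paths)
}

#' Read simulator parameters from a flat key-value config
#'
#' The config is YAML with flat scalar or vector keys mirroring the
#' [mutation_params()] arguments plus optional `total_length`,
#' `at_fraction` and `seed`; `region_rate` and `tv_profile` are maps.
#' Unknown keys are an error.
#'
#' @param path Config file path.
#' @return List with `layout` (`genome_layout`), `params`
#'   (`mutation_params`) and `seed` (or `NULL`).
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("total_length", "at_fraction", "seed", "region_rate",
             "ts_fraction", "major_TC_given_ts", "minor_AG_given_ts",
             "tv_profile", "indel_rate", "indel_length")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  layout_args <- cfg[intersect(names(cfg), c("total_length", "at_fraction"))]
  layout <- do.call(bombyx_layout, layout_args)
  pnames <- intersect(names(cfg), setdiff(known, c("total_length",
                                                   "at_fraction", "seed")))
  pargs <- lapply(cfg[pnames], function(v)
    if (is.list(v)) unlist(v) else v)
  params <- do.call(mutation_params, pargs)
  list(layout = layout, params = params, seed = cfg$seed)
}
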