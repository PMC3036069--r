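#' Bombyx-like mitogenome layout
#'
#' Default layout for the synthetic genome generator: a ~15.7 kb linearized
#' circular genome carrying the 13 protein-coding genes, the two rRNA genes
#' and one A+T-rich control region of an insect mitogenome, at their typical
#' silkmoth lengths and coding strands, separated by intergenic spacers that
#' stand in for the tRNA clusters. The overall A+T fraction defaults to
#' 0.815, the value typical of *Bombyx* mitogenomes.
#'
#' @param total_length Genome length in bp.
#' @param at_fraction Target A+T fraction of the generated sequence.
#' @return An object of class `genome_layout`: list with `total_length`,
#'   `at_fraction` and a `features` data frame (name, length, strand,
#'   category, in genome order).
#' @export
bombyx_layout <- function(total_length = 15700, at_fraction = 0.815) {
  feats <- data.frame(
    name = c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
             "nad5", "nad4", "nad4L", "nad6", "cob", "nad1",
             "lrRNA", "srRNA", "at_rich"),
    length = c(1023L, 1535L, 682L, 162L, 678L, 789L, 351L,
               1719L, 1341L, 291L, 531L, 1152L, 945L,
               1378L, 783L, 494L),
    strand = c("major", "major", "major", "major", "major", "major", "major",
               "minor", "minor", "minor", "major", "major", "minor",
               "minor", "minor", "minor"),
    category = c(rep("protein", 13), "rRNA", "rRNA", "at_rich"),
    stringsAsFactors = FALSE)
  if (at_fraction <= 0 || at_fraction >= 1)
    stop("at_fraction must lie in (0, 1)")
  slack <- total_length - sum(feats$length)
  if (slack < 0)
    stop("total_length ", total_length, " too short for the ",
         sum(feats$length), " bp of features")
  structure(list(total_length = as.integer(total_length),
                 at_fraction = at_fraction, features = feats),
            class = "genome_layout")
}

# place layout features left to right, spreading the slack over the
# inter-feature spacers (and the two ends) as evenly as possible
layout_positions <- function(layout) {
  f <- layout$features
  k <- nrow(f)
  slack <- layout$total_length - sum(f$length)
  ngap <- k + 1L
  gaps <- rep(slack %/% ngap, ngap)
  extra <- slack %% ngap
  if (extra > 0) gaps[seq_len(extra)] <- gaps[seq_len(extra)] + 1L
  start <- integer(k)
  pos <- 0L
  for (i in seq_len(k)) {
    pos <- pos + gaps[i]
    start[i] <- pos + 1L
    pos <- pos + f$length[i]
  }
  f$start <- start
  f$end <- start + f$length - 1L
  f
}

#' Generate a random annotated genome from a layout
#'
#' Bases are drawn i.i.d. with P(A) = P(T) = `at_fraction/2` and
#' P(C) = P(G) = `(1 - at_fraction)/2`; features are placed in layout order
#' with the remaining length distributed over intergenic spacers. The result
#' is deterministic for a given seed.
#'
#' @param layout A [bombyx_layout()]-style `genome_layout`.
#' @param seed Optional integer seed.
#' @param id Genome identifier.
#' @return An `annotated_genome`.
#' @export
generate_genome <- function(layout, seed = NULL, id = "ancestor") {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.null(seed)) set.seed(seed)
  at <- layout$at_fraction
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  seq <- paste(sample(names(p), layout$total_length, replace = TRUE,
                      prob = p), collapse = "")
  feats <- layout_positions(layout)
  annotated_genome(id, seq,
                   feats[, c("name", "start", "end", "strand", "category")])
}

#' Mutation parameters for the pair simulator
#'
#' The generative counterparts of the quantities the pipeline estimates:
#' per-region substitution probabilities, the transition fraction (kappa's
#' generative twin), the strand-conditional transition-type probabilities
#' (mutational strand bias recorded in major-strand orientation), the
#' transversion-class profile, and rare short indels. Defaults are the
#' region rates and type fractions observed between closely related
#' silkmoth mitogenomes (region rates in the 0.01-0.05 range, transitions
#' T-C-dominated on the major strand and A-G-dominated on the minor strand).
#'
#' @param region_rate Named per-site substitution probabilities; regions of
#'   the genome absent from this map (and the implicit `intergenic` region)
#'   fall back to the `intergenic` entry, or 0 if none.
#' @param ts_fraction Probability that a substitution is a transition.
#' @param major_TC_given_ts P(transition is T-C | region on major strand).
#' @param minor_AG_given_ts P(transition is A-G | region on minor strand).
#' @param tv_profile Probability vector over the transversion classes
#'   `T-A`, `C-A`, `T-G`, `C-G` (must sum to 1).
#' @param indel_rate Per-site probability of initiating an indel event.
#' @param indel_length Probability vector over indel lengths 1..5.
#' @return An object of class `mutation_params`.
#' @export
mutation_params <- function(
    region_rate = c(nad2 = 0.0196, cox1 = 0.0215, cox2 = 0.0205,
                    atp8 = 0.0123, atp6 = 0.0177, cox3 = 0.0418,
                    nad3 = 0.0256, nad6 = 0.0094, cob = 0.0434,
                    nad5 = 0.0227, nad4 = 0.0239, nad4L = 0.0309,
                    nad1 = 0.0169, lrRNA = 0.0131, srRNA = 0.0153,
                    at_rich = 0.0263, intergenic = 0.0200),
    ts_fraction = 0.60,
    major_TC_given_ts = 0.82,
    minor_AG_given_ts = 0.79,
    tv_profile = c(`T-A` = 0.55, `C-A` = 0.17, `T-G` = 0.21, `C-G` = 0.07),
    indel_rate = 0.0065,
    indel_length = c(0.60, 0.20, 0.10, 0.07, 0.03)) {
  chk01 <- function(x, nm) {
    if (any(x < 0 | x > 1)) stop(nm, " must lie in [0, 1]")
    x
  }
  chk01(region_rate, "region_rate")
  chk01(ts_fraction, "ts_fraction")
  chk01(major_TC_given_ts, "major_TC_given_ts")
  chk01(minor_AG_given_ts, "minor_AG_given_ts")
  chk01(indel_rate, "indel_rate")
  if (length(tv_profile) != 4L || abs(sum(tv_profile) - 1) > 1e-8)
    stop("tv_profile must be 4 probabilities summing to 1")
  if (!is.null(names(tv_profile)) && all(nzchar(names(tv_profile)))) {
    if (!setequal(names(tv_profile), TV_PAIRS))
      stop("tv_profile names must be ", paste(TV_PAIRS, collapse = ", "))
    tv_profile <- tv_profile[TV_PAIRS]
  } else {
    names(tv_profile) <- TV_PAIRS
  }
  if (length(indel_length) != 5L || abs(sum(indel_length) - 1) > 1e-8)
    stop("indel_length must be 5 probabilities (lengths 1..5) summing to 1")
  structure(list(region_rate = region_rate, ts_fraction = ts_fraction,
                 major_TC_given_ts = major_TC_given_ts,
                 minor_AG_given_ts = minor_AG_given_ts,
                 tv_profile = tv_profile, indel_rate = indel_rate,
                 indel_length = indel_length),
            class = "mutation_params")
}

# draw one index uniformly from a logical availability vector; NA if none
draw_site <- function(avail) {
  idx <- which(avail)
  if (!length(idx)) return(NA_integer_)
  idx[sample.int(length(idx), 1L)]
}

# transition partner / transversion partner within a pair class
flip_base <- function(base, pair) {
  pb <- PAIR_BASES[[pair]]
  if (base == pb[1]) pb[2] else pb[1]
}

#' Mutate a genome under region-specific, strand-biased parameters
#'
#' Evolves a derived copy of `genome`. Per region, the number of
#' substitution events is Binomial(region length, region rate); each event
#' is a transition with probability `ts_fraction`, the transition class
#' (T-C or A-G, in major-strand orientation) is drawn from the containing
#' region's coding strand, the transversion class from `tv_profile`
#' (renormalized over classes feasible in the region when necessary), and
#' the event is placed uniformly on a not-yet-mutated site whose current
#' base belongs to the drawn class, so each site mutates at most once.
#' Indel events (insertions and deletions, lengths 1-5) are placed so that
#' they never cross a feature boundary; derived feature coordinates are
#' recomputed by offset propagation. Every event is recorded in a truth
#' ledger, and the true alignment implied by the event list is returned so
#' downstream counting can be validated without re-aligning.
#'
#' @param genome The ancestral `annotated_genome`.
#' @param params A [mutation_params()].
#' @param seed Optional integer seed (deterministic output for a given seed).
#' @param id Identifier of the derived genome.
#' @param alignment Build the true `pairwise_alignment` (disable to speed up
#'   large replicate studies that only need the ledger).
#' @return A list with elements `derived` (`annotated_genome`), `ledger`
#'   (class `truth_ledger`: `params`, `events` data frame and per-region
#'   `counts`), and `alignment` (or `NULL`).
#' @export
mutate_genome <- function(genome, params, seed = NULL, id = NULL,
                          alignment = TRUE) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(params, "mutation_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(id)) id <- paste0(genome$id, "_derived")
  unknown <- setdiff(names(params$region_rate),
                     c(genome$features$name, INTERGENIC))
  if (length(unknown))
    stop("region_rate names not present in genome: ",
         paste(unknown, collapse = ", "))
  seqv <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  ridx <- region_index(genome)
  ridx[is.na(ridx)] <- INTERGENIC
  strand_of <- c(stats::setNames(genome$features$strand,
                                 genome$features$name),
                 stats::setNames("major", INTERGENIC))
  fallback <- if (INTERGENIC %in% names(params$region_rate))
    params$region_rate[[INTERGENIC]] else 0

  # event accumulator (parallel vectors; a data frame is built once at the end)
  ev <- new.env()
  ev$type <- ev$region <- ev$pair <- ev$from <- ev$to <- character()
  ev$pos <- ev$length <- integer()
  push_event <- function(type, region, pos, length, pair, from, to) {
    ev$type <- c(ev$type, type); ev$region <- c(ev$region, region)
    ev$pos <- c(ev$pos, pos); ev$length <- c(ev$length, length)
    ev$pair <- c(ev$pair, pair); ev$from <- c(ev$from, from)
    ev$to <- c(ev$to, to)
  }
  mutated <- logical(length(seqv))
  derivedv <- seqv

  for (rg in unique(ridx)) {
    rate <- if (rg %in% names(params$region_rate))
      params$region_rate[[rg]] else fallback
    if (rate <= 0) next
    pos <- which(ridx == rg)
    n <- stats::rbinom(1L, length(pos), rate)
    if (n == 0L) next
    p_TC <- if (strand_of[[rg]] == "major") params$major_TC_given_ts
            else 1 - params$minor_AG_given_ts
    for (i in seq_len(n)) {
      is_ts <- stats::runif(1) < params$ts_fraction
      if (is_ts) {
        pair <- if (stats::runif(1) < p_TC) "T-C" else "A-G"
        j <- draw_site(!mutated[pos] & seqv[pos] %in% PAIR_BASES[[pair]])
        if (is.na(j)) {  # no compatible site left: use the other class
          pair <- setdiff(TS_PAIRS, pair)
          j <- draw_site(!mutated[pos] & seqv[pos] %in% PAIR_BASES[[pair]])
        }
      } else {
        prof <- params$tv_profile
        pair <- NA_character_
        j <- NA_integer_
        while (any(prof > 0)) {
          cand <- sample(TV_PAIRS, 1L, prob = prof)
          j <- draw_site(!mutated[pos] & seqv[pos] %in% PAIR_BASES[[cand]])
          if (!is.na(j)) { pair <- cand; break }
          prof[cand] <- 0  # infeasible here: renormalize over the rest
        }
      }
      if (is.na(j)) next  # region exhausted (degenerate tiny regions)
      site <- pos[j]
      from <- seqv[site]
      to <- flip_base(from, pair)
      derivedv[site] <- to
      mutated[site] <- TRUE
      push_event(if (pair %in% TS_PAIRS) "transition" else "transversion",
                 rg, site, 1L, pair, from, to)
    }
  }

  # indels: initiate events genome-wide, avoid feature boundaries and
  # already-mutated sites so every recorded event stays visible
  if (params$indel_rate > 0) {
    n_ind <- stats::rbinom(1L, length(seqv), params$indel_rate)
    indel_used <- logical(length(seqv))
    # positions in the same region run share an id; a span of s cells stays
    # inside one region iff runid[p] == runid[p + s - 1]
    runid <- cumsum(c(TRUE, ridx[-1L] != ridx[-length(ridx)]))
    at <- genome_at_fraction(genome)
    for (i in seq_len(n_ind)) {
      len <- sample.int(5L, 1L, prob = params$indel_length)
      del <- stats::runif(1) < 0.5
      span <- if (del) len else 2L  # anchor p: insertion sits between p, p+1
      cand <- seq_len(length(seqv) - span + 1L)
      cu <- cumsum(indel_used | mutated)
      ok <- which(runid[cand] == runid[cand + span - 1L] &
                    (cu[cand + span - 1L] - c(0, cu)[cand]) == 0L)
      if (!length(ok)) break
      p <- ok[sample.int(length(ok), 1L)]
      if (del) {
        indel_used[p:(p + len - 1L)] <- TRUE
        push_event("deletion", ridx[p], p, len, NA_character_,
                   paste(seqv[p:(p + len - 1L)], collapse = ""), "")
      } else {
        indel_used[p:(p + 1L)] <- TRUE
        ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                            prob = c(at / 2, (1 - at) / 2, (1 - at) / 2,
                                     at / 2)), collapse = "")
        push_event("insertion", ridx[p], p, len, NA_character_, "", ins)
      }
    }
  }

  events <- data.frame(type = ev$type, region = ev$region, pos = ev$pos,
                       length = ev$length, pair = ev$pair, from = ev$from,
                       to = ev$to, stringsAsFactors = FALSE)
  events <- events[order(events$pos), , drop = FALSE]
  rownames(events) <- NULL

  built <- apply_indels(derivedv, genome$features, events)
  derived <- annotated_genome(id, paste(built$seq, collapse = ""),
                              built$features)
  ledger <- structure(list(params = params, events = events,
                           counts = ledger_counts(events, genome)),
                      class = "truth_ledger")
  aln <- if (alignment)
    true_alignment(seqv, derivedv, events, genome$id, id) else NULL
  list(derived = derived, ledger = ledger, alignment = aln)
}

genome_at_fraction <- function(genome) {
  unname(base_composition(genome$sequence)["AT"])
}

# apply indel events (ancestral coordinates) to the substituted sequence
# vector and propagate offsets into the feature table
apply_indels <- function(seqv, features, events) {
  ind <- events[events$type %in% c("deletion", "insertion"), , drop = FALSE]
  if (!nrow(ind)) return(list(seq = seqv, features = features))
  ind <- ind[order(-ind$pos), , drop = FALSE]  # right-to-left keeps coords valid
  f <- features
  for (k in seq_len(nrow(ind))) {
    p <- ind$pos[k]; len <- ind$length[k]
    if (ind$type[k] == "deletion") {
      seqv <- seqv[-(p:(p + len - 1L))]
      contains <- f$start <= p & f$end >= p + len - 1L
      after <- f$start > p
      f$end[contains] <- f$end[contains] - len
      f$start[after] <- f$start[after] - len
      f$end[after & !contains] <- f$end[after & !contains] - len
    } else {
      seqv <- append(seqv, strsplit(ind$to[k], "", fixed = TRUE)[[1]],
                     after = p)
      contains <- f$start <= p & f$end >= p + 1L
      after <- f$start > p
      f$end[contains] <- f$end[contains] + len
      f$start[after] <- f$start[after] + len
      f$end[after & !contains] <- f$end[after & !contains] + len
    }
  }
  f$length <- f$end - f$start + 1L
  list(seq = seqv, features = f)
}

# per-region realized counts (the ground truth the pipeline must recover)
ledger_counts <- function(events, genome) {
  regions <- c(genome$features$name, INTERGENIC)
  df <- data.frame(region = regions, stringsAsFactors = FALSE)
  regf <- factor(events$region, levels = regions)
  for (p in names(PAIR_TO_COL))
    df[[PAIR_TO_COL[p]]] <-
      as.integer(table(regf[!is.na(events$pair) & events$pair == p]))
  isind <- events$type %in% c("deletion", "insertion")
  df$indel_events <- as.integer(table(regf[isind]))
  df$indel_columns <- as.integer(
    vapply(split(events$length[isind] * 1L, regf[isind]), sum, numeric(1)))
  df$ts <- df$AG + df$TC
  df$tv <- df$TA + df$CA + df$TG + df$CG
  df$substitutions <- df$ts + df$tv
  df
}

# build the true gapped alignment implied by the event list
true_alignment <- function(anc, derived_sub, events, idA, idB) {
  rowA <- anc
  rowB <- derived_sub
  ind <- events[events$type %in% c("deletion", "insertion"), , drop = FALSE]
  if (nrow(ind)) {
    ind <- ind[order(-ind$pos), , drop = FALSE]
    for (k in seq_len(nrow(ind))) {
      p <- ind$pos[k]; len <- ind$length[k]
      if (ind$type[k] == "deletion") {
        rowB[p:(p + len - 1L)] <- "-"
      } else {
        rowA <- append(rowA, rep("-", len), after = p)
        rowB <- append(rowB, strsplit(ind$to[k], "", fixed = TRUE)[[1]],
                       after = p)
      }
    }
  }
  pairwise_alignment(paste(rowA, collapse = ""), paste(rowB, collapse = ""),
                     idA = idA, idB = idB)
}

#' @export
print.truth_ledger <- function(x, ...) {
  cat("Truth ledger: ", nrow(x$events), " events (",
      sum(x$events$type == "transition"), " ts, ",
      sum(x$events$type == "transversion"), " tv, ",
      sum(x$events$type %in% c("deletion", "insertion")), " indels)\n",
      sep = "")
  invisible(x)
}

#' Simulate an annotated mitogenome pair
#'
#' Convenience wrapper: generates an ancestral genome from `layout`, mutates
#' it under `params`, and returns the pair together with the true alignment
#' and the truth ledger.
#'
#' @param layout A `genome_layout` (default [bombyx_layout()]).
#' @param params A [mutation_params()].
#' @param seed Integer seed driving both generation and mutation.
#' @param alignment Build the true alignment (see [mutate_genome()]).
#' @return List with `ancestor`, `derived`, `alignment`, `ledger`.
#' @export
simulate_pair <- function(layout = bombyx_layout(),
                          params = mutation_params(), seed = NULL,
                          alignment = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  anc <- generate_genome(layout, seed = NULL)
  mut <- mutate_genome(anc, params, seed = NULL, alignment = alignment)
  list(ancestor = anc, derived = mut$derived, alignment = mut$alignment,
       ledger = mut$ledger)
}

#' Compare pipeline estimates with simulator ground truth
#'
#' For a spectrum table built from a simulated pair, reports per-region
#' absolute and relative errors of the estimated substitution counts and
#' rates against the ledger's realized counts and the generating parameters,
#' plus the estimated transition:transversion ratio against its generative
#' counterpart `ts_fraction / (1 - ts_fraction)`.
#'
#' @param table `spectrum_table` built from the simulated pair.
#' @param ledger The matching `truth_ledger`.
#' @return An object of class `recovery_report`: list with a per-region
#'   data frame `regions` and scalars `kappa_est`, `kappa_true`.
#' @export
recover_parameters <- function(table, ledger) {
  stopifnot(inherits(table, "spectrum_table"),
            inherits(ledger, "truth_ledger"))
  est <- table[!table$region %in% c(INTERGENIC, EXCLUDED), , drop = FALSE]
  truth <- ledger$counts
  miss <- setdiff(est$region, truth$region)
  if (length(miss))
    stop("regions absent from ledger: ", paste(miss, collapse = ", "))
  tr <- truth[match(est$region, truth$region), ]
  rate_param <- ledger$params$region_rate[est$region]
  df <- data.frame(region = est$region, length = est$length,
                   param_rate = unname(rate_param),
                   realized = tr$substitutions,
                   estimated = est$substitutions,
                   est_rate = est$substitutions / est$length,
                   stringsAsFactors = FALSE)
  df$count_error <- df$estimated - df$realized
  df$abs_err <- abs(df$est_rate - df$param_rate)
  df$rel_err <- ifelse(df$param_rate > 0, df$abs_err / df$param_rate, NA)
  tot <- spectrum_totals(table, "all")
  structure(list(regions = df,
                 kappa_est = if (tot$tv > 0) tot$ts / tot$tv else NA_real_,
                 kappa_true = ledger$params$ts_fraction /
                   (1 - ledger$params$ts_fraction)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("kappa: estimated %.3f, generative %.3f\n",
              x$kappa_est, x$kappa_true))
  cat(sprintf("mean |count error| = %.2f, mean rate rel. error = %.1f%%\n",
              mean(abs(x$regions$count_error)),
              100 * mean(x$regions$rel_err, na.rm = TRUE)))
  invisible(x)
}
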