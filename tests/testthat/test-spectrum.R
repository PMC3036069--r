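# plant specific substitutions into a generated genome and check attribution
test_that("build_spectrum_table localizes engineered mutations", {
  g <- generate_genome(bombyx_layout(), seed = 5)
  cob <- g$features[g$features$name == "cob", ]
  seqv <- strsplit(g$sequence, "")[[1]]
  # force known bases just inside cob, then substitute them:
  # 2 A-G, 13 T-C, 2 T-A, 3 C-A  (sum 20)
  plan <- c(rep("A-G", 2), rep("T-C", 13), rep("T-A", 2), rep("C-A", 3))
  pos <- cob$start + seq_along(plan) - 1
  from <- c(rep("A", 2), rep("T", 13), rep("T", 2), rep("C", 3))
  to   <- c(rep("G", 2), rep("C", 13), rep("A", 2), rep("A", 3))
  seqv[pos] <- from
  der <- seqv; der[pos] <- to
  genome <- annotated_genome(g$id, paste(seqv, collapse = ""), g$features)
  aln <- pairwise_alignment(paste(seqv, collapse = ""),
                            paste(der, collapse = ""), "ref", "derived")
  tab <- build_spectrum_table(aln, genome)
  cobrow <- tab[tab$region == "cob", ]
  expect_equal(cobrow$AG, 2L)
  expect_equal(cobrow$TC, 13L)
  expect_equal(cobrow$TA, 2L)
  expect_equal(cobrow$CA, 3L)
  expect_equal(cobrow$substitutions, 20L)
  # nothing anywhere else
  expect_equal(sum(tab$substitutions), 20L)
  expect_equal(sum(tab$indels), 0L)
})

test_that("attribution conserves alignment-wide counts, incl. ref gaps", {
  sim <- simulate_pair(seed = 88, params = mutation_params(indel_rate = 0.004))
  tab <- build_spectrum_table(sim$alignment, sim$ancestor)
  cls <- classify_columns(sim$alignment)
  tot <- spectrum_totals(tab, "all")
  expect_equal(tot$substitutions,
               sum(cls$kind %in% c("transition", "transversion")))
  expect_equal(tot$indels, sum(cls$kind == "indel"))
  expect_equal(tot$compared_sites, sum(cls$kind != "excluded"))
  # per-pair conservation too
  for (p in c("AG", "TC", "TA", "CA", "TG", "CG")) {
    lab <- c(AG = "A-G", TC = "T-C", TA = "T-A",
             CA = "C-A", TG = "T-G", CG = "C-G")[p]
    expect_equal(sum(tab[[p]]), sum(cls$pair == lab, na.rm = TRUE))
  }
})

test_that("excluded categories are pooled, not dropped", {
  feats <- data.frame(name = c("g1", "t1"), start = c(1, 11),
                      end = c(10, 20), strand = "major",
                      category = c("protein", "tRNA"))
  ref <- "ACGTACGTACACGTACGTAC"
  der <- "GCGTACGTACACGTACGTAT"  # one sub in g1 (A>G), one in t1 (C>T)
  g <- annotated_genome("r", ref, feats)
  tab <- build_spectrum_table(pairwise_alignment(ref, der), g)
  expect_equal(tab$substitutions[tab$region == "g1"], 1L)
  expect_false("t1" %in% tab$region)
  expect_equal(tab$substitutions[tab$region == "excluded"], 1L)
  expect_equal(spectrum_totals(tab, "all")$substitutions, 2L)
})

test_that("genome/alignment mismatch is a consistency error", {
  g <- annotated_genome("r", "ACGTACGT")
  expect_error(build_spectrum_table(pairwise_alignment("ACGTACGA", "ACGTACGT"),
                                    g), "does not match")
})

test_that("divergence and region_rate follow their definitions", {
  expect_equal(divergence(639, 15970), 639 / 15970)
  expect_equal(round(100 * divergence(639, 15970), 2), 4.00)
  expect_equal(round(100 * divergence(89, 15685), 2), 0.57)
  expect_equal(divergence(0, 100), 0)
  expect_error(divergence(5, 0), "> 0")
  expect_error(divergence(11, 10), "\\[0, alignment_columns\\]")
  tab <- read_fixture_table()
  r <- region_rate(tab)
  expect_equal(round(unname(r["cob"]), 4), 0.0434)    # 50 / 1,152
  expect_equal(round(unname(r["nad6"]), 4), 0.0094)   # most conserved gene
  zero <- tab; zero$substitutions <- 0L
  expect_true(all(region_rate(zero) == 0, na.rm = TRUE))
})

test_that("base composition excludes N and sums to one", {
  expect_equal(unname(base_composition("AATT")["AT"]), 1.0)
  expect_equal(unname(base_composition("ACGT")["AT"]), 0.5)
  bc <- base_composition("ACGTNNN")
  expect_equal(sum(bc[c("A", "C", "G", "T")]), 1.0)
  expect_error(base_composition("NNN"), "no countable")
})

test_that("strand partition sums transition counts by coding strand", {
  tab <- set_denominator(read_fixture_table(), c(cob = 1158))
  ss <- strand_partition(tab, "protein")
  expect_equal(ss$major_bp, 6909)
  expect_equal(ss$minor_bp, 4296)
  expect_equal(ss$major_AG, 22)
  expect_equal(ss$major_TC, 101)
  expect_equal(ss$minor_AG, 48)
  expect_equal(ss$minor_TC, 13)
  # consistency with the category aggregate
  tot <- spectrum_totals(tab, tab$region[tab$category == "protein"])
  expect_equal(ss$major_AG + ss$minor_AG, tot$AG)
  expect_equal(ss$major_TC + ss$minor_TC, tot$TC)
  expect_error(strand_partition(tab, "tRNA"), "no stranded rows")
})

test_that("a single-strand category leaves the other side empty", {
  feats <- data.frame(name = "g1", start = 1, end = 8, strand = "major",
                      category = "protein")
  g <- annotated_genome("r", "ACGTACGT", feats)
  tab <- build_spectrum_table(pairwise_alignment("ACGTACGT", "GCGTACGT"), g)
  ss <- strand_partition(tab)
  expect_equal(ss$minor_bp, 0)
  expect_equal(ss$minor_AG + ss$minor_TC, 0)
  expect_equal(ss$major_AG, 1)
})

test_that("spectrum TSV writer/reader round-trips tables", {
  sim <- simulate_pair(seed = 19)
  tab <- build_spectrum_table(sim$alignment, sim$ancestor)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_tsv(tab, path)
  back <- read_spectrum_tsv(path)
  for (col in c("region", "length", "AG", "TC", "TA", "CA", "TG", "CG",
                "indels", "substitutions"))
    expect_equal(back[[col]], tab[[col]], info = col)
})

test_that("set_denominator overrides rate denominators", {
  tab <- read_fixture_table()
  tab2 <- set_denominator(tab, c(at_rich = 484))
  expect_equal(round(unname(region_rate(tab2)["at_rich"]), 4), 0.0269)
  expect_error(set_denominator(tab, c(nope = 10)), "unknown region")
})
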