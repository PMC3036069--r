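test_that("pairwise_alignment validates and builds coordinate maps", {
  aln <- pairwise_alignment("AC-T", "ACGT")
  expect_equal(aln$columns, 4L)
  expect_equal(aln$mapA, c(1L, 2L, NA, 3L))
  expect_equal(aln$mapB, 1:4)
  expect_error(pairwise_alignment("ACGT", "ACG"), "differ in length")
  expect_error(pairwise_alignment("A-GT", "A-GT"), "gap in both")
  expect_error(pairwise_alignment("AXGT", "ACGT"), "unexpected symbol")
})

test_that("aligned FASTA round-trips through read/write", {
  sim <- simulate_pair(seed = 301)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_pairwise_fasta(sim$alignment, path)
  back <- read_pairwise_fasta(path)
  expect_equal(back$gappedA, sim$alignment$gappedA)
  expect_equal(back$gappedB, sim$alignment$gappedB)
  expect_identical(classify_columns(back), classify_columns(sim$alignment))
})

test_that("read_pairwise_fasta enforces the two-record contract", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT", ">c", "ACGT"), path)
  expect_error(read_pairwise_fasta(path), "exactly 2")
  writeLines(c(">a", "ACGT", ">b", "ACG"), path)
  expect_error(read_pairwise_fasta(path), "differ in length")
})

test_that("classify_columns assigns the canonical pair classes", {
  aln <- pairwise_alignment("AACGTACGT", "GACATACGA")
  cls <- classify_columns(aln)
  expect_equal(cls$kind[1], "transition")      # A/G
  expect_equal(cls$pair[1], "A-G")
  expect_equal(cls$kind[4], "transition")      # column 4: G vs A
  expect_equal(cls$pair[4], "A-G")
  expect_equal(cls$kind[9], "transversion")    # column 9: T vs A
  expect_equal(cls$pair[9], "T-A")
  expect_equal(sum(cls$kind == "identical"), 6)
  # explicit single-column checks
  one <- function(x, y) classify_columns(pairwise_alignment(x, y))
  expect_equal(one("A", "G")$pair, "A-G")
  expect_equal(one("C", "T")$pair, "T-C")
  expect_equal(one("C", "G")$kind, "transversion")
  expect_equal(one("C", "G")$pair, "C-G")
  expect_equal(one("A", "-")$kind, "indel")
  expect_equal(one("N", "A")$kind, "excluded")
  # all-identical alignment has zero variable sites
  allsame <- one("ACGTACGT", "ACGTACGT")
  expect_equal(sum(allsame$kind != "identical"), 0)
})

test_that("column classification is symmetric in the two sequences", {
  set.seed(91)
  for (i in 1:10) {
    sim <- simulate_pair(seed = 400 + i,
                         params = mutation_params(indel_rate = 0.003))
    ab <- classify_columns(sim$alignment)
    ba <- classify_columns(pairwise_alignment(sim$alignment$gappedB,
                                              sim$alignment$gappedA))
    expect_equal(table(ab$kind), table(ba$kind))
    expect_equal(table(ab$pair), table(ba$pair))
  }
})

test_that("reverse complementation swaps A-G/T-C and C-A/T-G, fixes T-A/C-G", {
  rc <- function(s) {
    chartr("ACGTN-", "TGCAN-",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  sim <- simulate_pair(seed = 77, params = mutation_params(indel_rate = 0.003))
  fwd <- classify_columns(sim$alignment)
  rev <- classify_columns(pairwise_alignment(rc(sim$alignment$gappedA),
                                             rc(sim$alignment$gappedB)))
  cnt <- function(cls) table(factor(cls$pair,
                                    c("A-G", "T-C", "T-A", "C-A", "T-G", "C-G")))
  f <- cnt(fwd); r <- cnt(rev)
  expect_equal(unname(r["A-G"]), unname(f["T-C"]))
  expect_equal(unname(r["T-C"]), unname(f["A-G"]))
  expect_equal(unname(r["C-A"]), unname(f["T-G"]))
  expect_equal(unname(r["T-G"]), unname(f["C-A"]))
  expect_equal(unname(r["T-A"]), unname(f["T-A"]))
  expect_equal(unname(r["C-G"]), unname(f["C-G"]))
  expect_equal(table(rev$kind), table(fwd$kind))  # kind totals preserved
})

test_that("align_global handles the textbook cases deterministically", {
  a <- align_global("ACGT", "ACGT")
  expect_equal(a$score, 4)
  expect_equal(sum(classify_columns(a)$kind == "identical"), 4)
  b <- align_global("ACGT", "AGT")
  cls <- classify_columns(b)
  expect_equal(sum(cls$kind == "indel"), 1)     # single gap, score 3 - 3 = 0
  expect_equal(b$score, brute_align_score("ACGT", "AGT"))
  # identical call twice gives the identical alignment (tie-break stability)
  c1 <- align_global("ACACAC", "ACAC")
  c2 <- align_global("ACACAC", "ACAC")
  expect_identical(c1$gappedA, c2$gappedA)
  expect_identical(c1$gappedB, c2$gappedB)
  expect_error(align_global("", "ACGT"), "empty")
})

test_that("align_global matches the brute-force oracle on short pairs", {
  set.seed(20)
  for (i in 1:60) {
    a <- random_seq(sample(1:12, 1))
    b <- random_seq(sample(1:12, 1))
    aln <- align_global(a, b)
    expect_equal(aln$score, brute_align_score(a, b),
                 info = paste(a, b))
    # gapped rows reproduce their sources and score the reported score
    expect_equal(gsub("-", "", aln$gappedA), a)
    expect_equal(gsub("-", "", aln$gappedB), b)
  }
})

test_that("align_global honours custom scoring parameters", {
  set.seed(21)
  for (i in 1:15) {
    a <- random_seq(sample(2:10, 1))
    b <- random_seq(sample(2:10, 1))
    aln <- align_global(a, b, match = 2, mismatch = -3,
                        gap_open = -4, gap_extend = -2)
    expect_equal(aln$score,
                 brute_align_score(a, b, match = 2, mismatch = -3,
                                   gap_open = -4, gap_extend = -2))
  }
})
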