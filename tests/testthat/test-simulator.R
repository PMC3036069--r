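test_that("generate_genome is deterministic and hits the target A+T", {
  g1 <- generate_genome(bombyx_layout(), seed = 100)
  g2 <- generate_genome(bombyx_layout(), seed = 100)
  expect_identical(g1$sequence, g2$sequence)
  expect_equal(g1$length, 15700L)
  # binomial bound: sd of the A+T fraction at n = 15,700 is ~0.003
  expect_lt(abs(base_composition(g1$sequence)["AT"] - 0.815), 0.01)
  # zero-slack layout tiles exactly
  tiled <- generate_genome(bombyx_layout(total_length = 13854), seed = 1)
  expect_equal(sum(tiled$features$length), tiled$length)
  expect_equal(min(tiled$features$start), 1L)
  expect_equal(max(tiled$features$end), tiled$length)
})

test_that("zero rates leave the genome untouched", {
  g <- generate_genome(bombyx_layout(), seed = 2)
  par0 <- mutation_params(region_rate = c(intergenic = 0), indel_rate = 0)
  m <- mutate_genome(g, par0, seed = 3)
  expect_identical(m$derived$sequence, g$sequence)
  expect_equal(nrow(m$ledger$events), 0L)
  expect_equal(sum(m$ledger$counts$substitutions), 0L)
})

test_that("same seed reproduces the identical mutated pair", {
  g <- generate_genome(bombyx_layout(), seed = 4)
  m1 <- mutate_genome(g, mutation_params(), seed = 9)
  m2 <- mutate_genome(g, mutation_params(), seed = 9)
  expect_identical(m1$derived$sequence, m2$derived$sequence)
  expect_identical(m1$ledger$events, m2$ledger$events)
})

test_that("realized counts concentrate around length x rate", {
  g <- generate_genome(bombyx_layout(), seed = 6)
  par <- mutation_params(region_rate = c(nad2 = 0.03, intergenic = 0),
                         indel_rate = 0)
  # nad2 is 1,023 bp: expect ~30.7 events, Poisson-style 3-sigma band
  m <- mutate_genome(g, par, seed = 10)
  n <- sum(m$ledger$counts$substitutions)
  expect_equal(m$ledger$counts$substitutions[m$ledger$counts$region == "nad2"],
               n)  # all events inside nad2
  expect_gt(n, 30.7 - 3 * sqrt(30.7))
  expect_lt(n, 30.7 + 3 * sqrt(30.7))
})

test_that("degenerate type parameters produce a single event class", {
  lay <- bombyx_layout()
  lay$features$strand <- "major"        # all-major layout
  g <- generate_genome(lay, seed = 12)
  par <- mutation_params(region_rate = c(cox1 = 0.02, intergenic = 0),
                         ts_fraction = 1, major_TC_given_ts = 1,
                         indel_rate = 0)
  m <- mutate_genome(g, par, seed = 13)
  expect_gt(nrow(m$ledger$events), 0)
  expect_true(all(m$ledger$events$pair == "T-C"))
  expect_true(all(m$ledger$events$type == "transition"))
})

test_that("events respect the one-event-per-site rule and region bounds", {
  g <- generate_genome(bombyx_layout(), seed = 14)
  m <- mutate_genome(g, mutation_params(), seed = 15)
  ev <- m$ledger$events
  sub <- ev[ev$type %in% c("transition", "transversion"), ]
  expect_false(anyDuplicated(sub$pos) > 0)
  ridx <- region_index(g)
  ridx[is.na(ridx)] <- "intergenic"
  expect_equal(ridx[sub$pos], sub$region)
  # deleted runs stay within one region; insertions sit strictly between
  # two positions of the same region
  ind <- ev[ev$type %in% c("deletion", "insertion"), ]
  for (k in seq_len(nrow(ind))) {
    span <- if (ind$type[k] == "deletion")
      ind$pos[k]:(ind$pos[k] + ind$length[k] - 1)
    else ind$pos[k]:(ind$pos[k] + 1)
    expect_length(unique(ridx[span]), 1)
  }
})

test_that("indels shift derived coordinates consistently", {
  g <- generate_genome(bombyx_layout(), seed = 16)
  m <- mutate_genome(g, mutation_params(indel_rate = 0.004), seed = 17)
  net <- sum(m$ledger$events$length[m$ledger$events$type == "insertion"]) -
    sum(m$ledger$events$length[m$ledger$events$type == "deletion"])
  expect_equal(m$derived$length, g$length + net)
  # derived annotation stays valid (constructor re-validates) and the
  # derived sequence matches the alignment's ungapped B row
  expect_identical(gsub("-", "", m$alignment$gappedB),
                   m$derived$sequence)
  expect_identical(gsub("-", "", m$alignment$gappedA), g$sequence)
  # per-region net length change matches each feature's event history
  ev <- m$ledger$events
  for (nm in g$features$name) {
    d <- sum(ev$length[ev$type == "insertion" & ev$region == nm]) -
      sum(ev$length[ev$type == "deletion" & ev$region == nm])
    expect_equal(m$derived$features$length[m$derived$features$name == nm],
                 g$features$length[g$features$name == nm] + d)
  }
})

test_that("indel-free simulation gives exact ledger/pipeline agreement", {
  sim <- simulate_pair(seed = 18, params = mutation_params(indel_rate = 0))
  expect_false(grepl("-", sim$alignment$gappedA, fixed = TRUE))
  tab <- build_spectrum_table(sim$alignment, sim$ancestor)
  rec <- recover_parameters(tab, sim$ledger)
  expect_true(all(rec$regions$count_error == 0))
  expect_true(all(rec$regions$estimated == rec$regions$realized))
})

test_that("kappa estimate sits within 3 SE of its generative value", {
  # delta-method SE of ts/tv at n substitutions with ts fraction f:
  # SE(kappa) ~ sqrt(f / (1-f)^3 / n)
  sim <- simulate_pair(seed = 21, params = mutation_params(indel_rate = 0))
  tab <- build_spectrum_table(sim$alignment, sim$ancestor)
  rec <- recover_parameters(tab, sim$ledger)
  f <- sim$ledger$params$ts_fraction
  n <- sum(sim$ledger$counts$substitutions)
  se <- sqrt(f / (1 - f)^3 / n)
  expect_lt(abs(rec$kappa_est - rec$kappa_true), 3 * se)
})

test_that("recover_parameters flags mismatched regions", {
  sim <- simulate_pair(seed = 22, params = mutation_params(indel_rate = 0))
  tab <- build_spectrum_table(sim$alignment, sim$ancestor)
  tab$region[tab$region == "cob"] <- "mystery"
  expect_error(recover_parameters(tab, sim$ledger), "absent from ledger")
})

test_that("mutation_params validates probability inputs", {
  expect_error(mutation_params(ts_fraction = 1.2), "\\[0, 1\\]")
  expect_error(mutation_params(tv_profile = c(0.5, 0.5, 0.2, 0.1)),
               "summing to 1")
  expect_error(mutation_params(indel_length = rep(0.2, 4)), "5 probabilities")
  expect_error(mutate_genome(generate_genome(bombyx_layout(), seed = 1),
                             mutation_params(region_rate = c(zzz = 0.1))),
               "not present")
})
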