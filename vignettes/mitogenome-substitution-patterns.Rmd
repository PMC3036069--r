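---
title: "Substitution patterns between paired mitochondrial genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substitution patterns between paired mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosub)
```

## The analysis

`mitosub` implements the comparative analysis commonly applied to a pair of
closely related insect mitochondrial genomes — for instance a domesticated
silkmoth and its wild relatives. Given a pairwise alignment of two
annotated genomes, the pipeline:

1. classifies every alignment column as identical, a transition (A-G or
   T-C), a transversion (T-A, C-A, T-G or C-G), or an indel column;
2. attributes each variable column to the gene or region of its
   reference-genome coordinate, producing a per-gene substitution spectrum
   (the familiar published table layout: per gene, the two transition
   counts, the four transversion counts, their sums and a per-site rate);
3. summarizes divergence (variable columns / alignment length), base
   composition and the transition:transversion ratio
   $\kappa = n_{ts}/n_{tv}$; and
4. runs a battery of Pearson chi-square tests on site counts:
   * goodness-of-fit of $(n_{ts}, n_{tv})$ against the neutral 1:2
     expectation (under equal per-type rates, twice as many transversion
     as transition classes are available);
   * 2×2 homogeneity tests contrasting two comparisons (divergence or
     $\kappa$ between genome pairs);
   * k×2 rate-heterogeneity tests across genes, treating every site as a
     Bernoulli trial (substituted / not substituted);
   * a pooled-rate contrast between two gene classes — by default the five
     protein genes flanking the A+T-rich control region
     (`nad2, cox1, cox2, atp6, nad1`; Class 1) versus the remaining large
     protein genes (`cox3, nad4, nad5, cob`; Class 2);
   * three 2×2 strand-asymmetry tests of transition counts (all
     transitions, T-C only, A-G only) between major- and minor-strand
     protein-coding genes.

All tests are plain Pearson statistics with no continuity correction; this
is the convention under which the published statistics of the silkmoth
comparisons are reproduced exactly from their printed counts, and the test
suite pins that behaviour. p-values are upper-tail chi-square
probabilities reported numerically.

### The site-as-trial assumption

The rate tests model each nucleotide position as an independent Bernoulli
trial. Real mitochondrial sites are neither independent nor identically
distributed (codon structure, strand-specific mutation pressure, local
context), so these tests are a descriptive convention of the field rather
than a claim about the true sampling process. The simulator (below)
generates data under exactly this convention, which is why the type-I
error calibration is a meaningful check of the implementation and not of
biology.

### Orientation conventions

Everything is 1-based and inclusive, the GenBank convention; genomes are
analyzed as linearized in deposited orientation, and features wrapping the
origin are rejected. Substitution pairs are recorded in the orientation of
the aligned sequences (major-strand orientation); minor-strand genes are
*not* reverse-complemented before tallying. That is what makes strand
asymmetry visible: a T-C-rich transition spectrum on major-strand genes
appears as an A-G-rich spectrum on minor-strand genes when both are read
in major-strand orientation. The column classifier's behaviour under
reverse complementation (A-G↔T-C and C-A↔T-G swap; T-A and C-G are
invariant) is property-tested.

## Reading printed tables as data

A published per-gene difference table carries everything the statistical
battery needs, so `read_spectrum_tsv()` ingests such tables and
`table_battery()` reanalyzes them with no sequence data. The package
bundles the table for the *B. mori* C108 × Chinese *B. mandarina*
comparison:

```{r}
tab <- read_spectrum_tsv(system.file("extdata",
  "bmori_chbm_gene_differences.tsv", package = "mitosub"),
  comparison = c("Bmori_C108", "ChBm"))
bat <- substitution_battery(tab, strand_length_overrides = c(cob = 1158))
bat$class_contrast
```

### Denominator conventions

Published tables sometimes mix gene-length conventions between the two
genomes of the pair, and this one does: the strand bp totals (6,909 /
4,296) require the *second* genome's `cob` length (1,158), while the rate
tests use the first genome's lengths; the printed A+T-rich and `lrRNA`
rates are computed over the second genome's lengths (484 and 1,350), and
the printed `nad4` rate (0.0238) is a truncation of 32/1341 = 0.02386.
Rather than guess intent, the package keeps the reference (first) genome's
lengths as the default denominator and exposes `set_denominator()` for
explicit per-region overrides; the acceptance tests wire the published
conventions explicitly and compare rates within 1e-4, which absorbs the
truncated digit.

Two published statistics are internally inconsistent with the formula that
reproduces all the others exactly: the Japanese-comparison neutrality
statistic (printed 517.47; the Pearson statistic for counts 414:100
against 1:2 is 515.55) and the within-Class-1 heterogeneity (printed 0.77;
the k×2 recomputation gives 0.80). The package reports the recomputed
values; the tests assert them and document the discrepancy.

## The synthetic genome-pair generator

Because the real genome records live in external databases, validation
uses a generator that emulates their salient structure:

* **Layout** (`bombyx_layout()`): a 15,700 bp linearized genome with the
  13 protein-coding genes, two rRNA genes and one A+T-rich region at their
  typical silkmoth lengths and coding strands, in genomic order, with the
  remaining ~1.8 kb spread over intergenic spacers standing in for the
  tRNA clusters. The A+T-rich region is placed on the minor strand: it has
  no coding strand of its own, and its observed transition mix matches the
  minor-strand pattern. A+T fraction defaults to 0.815, the typical
  *Bombyx* value; bases are drawn i.i.d. with P(A)=P(T)=0.4075.
* **Mutation model** (`mutation_params()`): per region, the number of
  substitution events is Binomial(length, rate); each event is a
  transition with probability `ts_fraction` (default 0.60, matching the
  observed transition fraction 230/381); the transition class is T-C with
  probability 0.82 in major-strand regions and A-G with probability 0.79
  in minor-strand regions (the observed strand-conditional fractions
  101/123 and 48/61); transversion classes follow the observed profile
  (0.55, 0.17, 0.21, 0.07 over T-A, C-A, T-G, C-G). Default region rates
  are the observed per-gene rates (0.0094–0.0434, intergenic 0.02). Each
  event is placed uniformly on a not-yet-mutated site whose base is
  compatible with the drawn pair, so a site mutates at most once and every
  parameter is directly identifiable from the realized counts. A literal
  "draw a type, then mutate this site" scheme cannot honour a drawn
  transition class (the site's base fixes it), which is why the
  count-then-place formulation is used; when a drawn transversion class
  has no compatible site left, the draw is renormalized over the feasible
  classes.
* **Indels**: events are initiated at rate 0.0065 per site (the observed
  ratio of indel columns to alignment length), lengths 1–5 with a short-
  biased distribution, insertion/deletion equally likely. Indels never
  cross a feature boundary and avoid already-mutated sites, so the truth
  ledger stays exactly realizable; derived-genome feature coordinates are
  recomputed by offset propagation.
* **Truth ledger**: every event (type, region, position, pair, bases) is
  recorded, together with per-region realized counts, and the exact
  alignment implied by the event list is returned — so the pipeline's
  counting can be validated without re-aligning 15.7 kb sequences.

What the generator does *not* emulate: codon structure and selection,
rate variation within genes, tRNA genes as features, context-dependent
mutation, heteroplasmy, and alignment uncertainty (the true alignment is
known by construction). Passing tests therefore demonstrate correct
counting, attribution and inference *given* an alignment — not robustness
to aligner gap-placement choices on real data, which is why consensus
alignment lengths of real genome pairs are treated as emergent quantities
rather than targets.

## The built-in aligner

`align_global()` is a Needleman–Wunsch/Gotoh global aligner with affine
gaps (a gap of length $k$ costs `gap_open` + $k\,\cdot$ `gap_extend`;
defaults 1 / −1 / −2 / −1 for match/mismatch/open/extend) intended for
desk-scale inputs such as single-gene sequences. Tie-breaking is
deterministic — diagonal, then gap in the second sequence, then gap in the
first — so identical inputs always produce byte-identical alignments. The
test suite checks it against an independent brute-force recursion on
random short pairs. Full traceback matrices are held in memory, so inputs
are capped at 50 kb; whole-mitogenome re-alignment is possible but is not
a validated path (simulated pairs carry their true alignment instead).

## Numerical and degenerate-input choices

* Chi-square tests refuse degenerate inputs (zero marginals, zero expected
  cells, k < 2) rather than returning NaN; `kappa_ratio()` flags the
  zero-transversion case as undefined instead of dividing by zero.
* Columns containing `N` are excluded from every numerator and denominator
  and tallied separately; a policy flag on `annotated_genome()` masks
  other ambiguity codes to `N` instead of rejecting.
* Alignment columns that are gaps in the reference are attributed to the
  region of the nearest preceding reference position; a k-column gap run
  counts as k variable sites and zero substitutions.
* Columns in features of a filtered-out category (tRNA by default) and in
  intergenic spacers are pooled into `excluded` / `intergenic`
  pseudo-rows, so alignment-wide totals are conserved exactly — an
  invariant the tests enforce.
* Overlapping features are rejected unless flagged; position lookups under
  permitted overlap resolve by category priority
  (protein > rRNA > at_rich > tRNA > other), ties to the earlier start.

## Validation problem sizes

The shipped test suite and the acceptance script validate with: the full
16-region published table (exact reproduction of sums, rates and the ten
chi-square statistics); 20 indel-free simulated pairs at full genome size
for exact ledger/pipeline count conservation; 60+ random short pairs
against the brute-force alignment oracle; 1,000 null replicates for the
2×2 type-I error calibration (observed rejection rates near 0.05 within
the [0.03, 0.07] binomial band); and 20 replicate pairs under the default
study-like parameters for rate recovery (seed-averaged per-region
estimates within a few percent of the generating rates for regions
≥ 500 bp). These sizes were chosen so the whole suite runs in about a
minute while keeping every stochastic bound at least ~3 standard errors
wide.

## Known limitations

* Codon-position and amino-acid-level analyses (dN/dS) are out of scope.
* No multiple-testing correction is applied — the battery mirrors the
  field's reporting convention of raw per-test p-values.
* κ here is the raw count ratio, not a likelihood-based (K2P/GTR)
  estimate; it is not corrected for multiple hits and is only meaningful
  for closely related pairs.
* The strand tests condition on the published two-strand gene assignment;
  genomes with different gene arrangements need their own annotation
  tables.
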