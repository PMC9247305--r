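---
title: "Methods: cross-country herdbook linkage and population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-country herdbook linkage and population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Joint (across-country) genomic evaluation of livestock — here modelled on
Alpine and Saanen dairy goat populations recorded in four national
herdbooks — is only worthwhile when the populations are connected.
Connection has two faces:

* **administrative connectedness**: the same animals registered in several
  national pedigrees, and foreign-sired progeny in each pedigree;
* **genomic relatedness**: shared linkage disequilibrium (LD) structure, a
  consistent gametic phase across populations, overlapping clusters in a
  relationship-matrix PCA, and shared ancestral components in an
  admixture decomposition.

`herdlink` implements both strands plus a fully specified simulator, so
that every stage can be exercised, and checked against known truth,
without access to industry data (which are typically private).

## Canonical identifiers and record linkage

Animals are keyed by a fixed 23-character identifier: 3-letter breed,
3-letter registration country, 1-letter sex, and a 16-character core made
of the 2-letter *birth* country code plus the zero-padded local number
(`standardize_id()`).  An exported animal is registered separately in
each country, so its identifiers differ in the registration field but
share breed, sex and core; linkage therefore compares identifiers
registration-invariantly.

`link_pedigrees()` resolves the foreign-born animals of a target pedigree
against the source country's pedigree through four tiers: exact identity,
alias identity, unique trailing-digit suffix (at least 5 digits — shorter
suffixes collide in large pedigrees), and fuzzy matching by normalized
Levenshtein similarity on the 16-character core (0–100 scale, candidates
restricted to the same birth country).  Fuzzy candidates at or above the
threshold (default 90, i.e. at most one edit on a 16-character core) are
*never* auto-accepted: they carry status `review`, mirroring the manual
verification such matches require in practice.  Within a tier each source
identifier is consumed at most once.  Animals that remain `review` or
`unmatched` are reported as *missing in the local pedigree*; we make no
attempt to adjudicate them automatically.

## Pedigree inbreeding

`pedigree_inbreeding()` implements the Meuwissen & Luo (1992) sweep:
for each animal the ancestor path coefficients $L$ accumulate
$A_{ii} = \sum_j L_{ij}^2 D_j$ with Mendelian-sampling variance
$D_j = \tfrac12 - \tfrac14 (F_s + F_d)$, using the $F = -1$ convention
for unknown parents so the identity holds on incomplete pedigrees.  An
unknown parent side contributes nothing ($F = 0$ for such animals);
unknown-parent groups and metafounders are deliberately out of scope.
The tabular relationship-matrix recursion serves as an independent test
oracle (agreement to $10^{-12}$ on random 220-animal pedigrees).

## Genotype QC and pruning

`qc_filter()` applies, in order: sample call rate, then SNP call rate
(computed after sample removal), then MAF — all strict (`<`) so markers
exactly on a threshold (defaults 0.90 / 0.90 / 0.01) are retained.  The
order is a documented convention, configurable in the pipeline; the SNP
call rate is computed after sample removal.  `merge_datasets()`
intersects SNP sets, reconciles swapped allele labels (A/B-coded data;
real chip TOP/BOT strand logic is out of scope), and re-runs QC on the
merged matrix.  `ld_prune()` mirrors `--indep`-style variance-inflation
pruning (window 50 SNPs, step 5, VIF limit 2 by default); perfect
collinearity is handled with a ridge-stabilized inverse so duplicated
SNPs show up as huge finite VIFs, and ties remove the later SNP so the
retained set is deterministic.

## LD and the gametic phase

For two loci, $D = p_{AB} - p_A p_B$ and
$r^2 = D^2 / \big(p_A(1-p_A)\,p_B(1-p_B)\big)$.  The haplotype frequency
$p_{AB}$ is counted directly when phase is available (the simulator keeps
it as ground truth) and otherwise estimated by the standard two-locus EM
over the double-heterozygote ambiguity, started at linkage equilibrium
and iterated to $|\Delta p_{AB}| < 10^{-10}$ (cap 1000 iterations);
individuals missing either call are excluded, and allele frequencies are
taken from the same complete-case set so $D$ is internally consistent.
`ld_decay()` averages $r^2$ over all within-chromosome pairs up to 1 Mb
in 50 classes of 20 kb, labelling each class by the median realized pair
distance (empty classes get the midpoint and a flag).

The *consistency of the gametic phase* between two populations is the
Pearson correlation, per distance class, of $\mathrm{sign}(D)\sqrt{r^2}$
over the SNP pairs polymorphic in both.  Nine classes are used: (0,1],
(1,10], (10,20], (20,40], (40,60], (60,100], (100,200], (200,500],
(500,1000] kb.  Because the sign of $D$ is meaningless unless both files
orient alleles identically, `phase_consistency()` first recodes
population B to population A's allele labels and then orients both to the
pooled major allele.  Whether the original analyses oriented on merged or
per-country frequencies is not documented anywhere we could check; the
pooled-major choice is ours and is stated here rather than asserted as
theirs (any common orientation gives the same correlation).

## Genomic relationships, PCA, genomic inbreeding

`grm()` is VanRaden method 1: $G = ZZ'/(2\sum_j p_j(1-p_j))$ with
$Z$ the calls centred at $2p_j$ (missing calls impute to $2p_j$, i.e.
zero after centring) and frequencies from the analysed sample;
monomorphic SNPs are excluded.  `pca_grm()` eigendecomposes $G$, scales
eigenvectors by $\sqrt{\lambda}$, reports $\lambda_k / \mathrm{tr}(G)$
as variance shares, and fixes each component's sign so its
largest-magnitude loading is positive — coordinates are then
reproducible across runs and platforms.

Genomic inbreeding is reported primarily as homozygosity excess,
$F_{het} = (O_{hom} - E_{hom})/(L - E_{hom})$ with
$E_{hom} = \sum_j (1 - 2p_j(1-p_j))$ over the animal's non-missing
pruned SNPs (plug-in frequencies, no small-sample correction — the
estimator is deliberately the simple one, and the GRM diagonal minus one
is reported alongside as a secondary column).  Published tool families
expose several "ibc" variants whose exact definitions differ; numeric
parity with any particular one is not claimed.  Animals with fewer than
100 informative pruned SNPs are flagged low-confidence.

## Admixture

`admixture_em()` fits the classical admixture (frappe) likelihood
$\sum_{ij} g_{ij}\log\pi_{ij} + (2-g_{ij})\log(1-\pi_{ij})$,
$\pi_{ij} = \sum_c q_{ic} f_{cj}$, by alternating exact EM updates of Q
and F — slower than accelerated quasi-Newton schemes but simple and
provably monotone, which the tests assert on every trace.  Q starts from
a symmetric Dirichlet(1) draw, F from sample frequencies plus uniform
(−0.1, 0.1) noise; iteration stops when the log-likelihood gains less
than $10^{-4}$ (cap 2000).  F is clipped to [0.01, 0.99] each step.
Missing entries drop their likelihood terms (an observation mask) rather
than being imputed; this is what makes the cross-validation in
`choose_k()` leak-free: each fold masks a random 10% of observed entries,
refits, and scores the held-out calls by binomial deviance against the
fitted dosage $2\sum_c q_{ic} f_{cj}$.  The selected k minimises the mean
held-out deviance, ties going to the smallest k (folds default 5; the
bundled tests use 3 to keep runtimes short).

## The synthetic-data generator

No simulation model accompanies the original analyses (they ran on real
data), so the generator is this package's own design, chosen to produce
jointly the three things the downstream statistics need:

1. **Population structure** — Balding–Nichols divergence: per population
   $p$ with parameter $F$, SNP frequencies are
   $\mathrm{Beta}\big(\bar p(1-F)/F,\,(1-\bar p)(1-F)/F\big)$ around
   ancestral frequencies $\bar p \sim U(0.05, 0.95)$, clipped to
   [0.01, 0.99].  Default divergence: FRA 0.04, ITA 0.05, CHE 0.10,
   CAN 0.15 — a close FRA/ITA pair, an intermediate CHE, a distinct CAN.
2. **Distance-decaying LD** — founder haplotypes are mosaics of a finite
   pool of ancestral templates (default 8 per population, drawn
   site-independently from the population frequencies), switching
   templates between adjacent SNPs with probability
   $1 - e^{-\lambda d}$ ($\lambda = 10^{-6}$/bp by default).  The finite
   pool sets the short-range $r^2$ plateau (roughly $1/n_{templates}$)
   and the switching process makes it decay with distance.
3. **Pedigree-consistent genotypes** — gene dropping with Haldane
   recombination (Poisson crossovers at $10^{-8}$ Morgans/bp, uniform
   positions), phase retained, so pedigree-based and genomic inbreeding
   are comparable on the same animals and Mendelian consistency is
   checkable exhaustively.

Pedigrees run in discrete generations (default 5 after 40 founders per
breed-by-country population, 2 offspring per mating with deterministic
sex alternation so small populations never run out of sires).  A dam's
sire is drawn from country A with probability `export_rate[A, B]`
(defaults: FRA→ITA 0.20, FRA→CHE 0.10, FRA→CAN 0.05, CHE→ITA 0.05, rest
0 — a unilateral, France-dominated flow).  Only sires are exported by
default; dam export exists behind a flag since the observed exchange is
sire-dominated.  An exported sire gains a record in the importing
pedigree whose identifier is truncated to the trailing 5–6 digits
(probability 0.1), hit by a one-character typo (0.05), renumbered with
the true identity kept as an alias (0.1), or clean; every correspondence
goes into the truth match table.  Birth years advance 3 years per
generation from 2000, and per-country genotyping windows stagger which
cohorts are genotyped; each genotyped animal appears in exactly one
country's genotype file (its origin).  Genotype calls are masked i.i.d.
at rate 0.02 to exercise the call-rate QC; the retained phase is the
unmasked truth.

What the generator does *not* emulate: coalescent realism, mutation,
selection, real chip manifests, TOP/BOT strand coding, overlapping
generations, non-random mating within population.  Passing tests
therefore demonstrate the correctness of the statistics and the
plumbing, not that real goat data would yield any particular value.
One structural consequence worth knowing: because each population draws
its own template pool, cross-country gametic-phase consistency in the
default dataset comes from migration alone and is far below the
near-unity short-distance values seen in closely connected real
populations.  The dedicated phase-consistency analyses therefore
construct populations from a *shared* founder pool followed by
generations of separate random mating, which reproduces the
high-then-declining profile.

## Numerical choices and degenerate inputs

* Two-locus EM: equilibrium start, tolerance $10^{-10}$, cap 1000;
  monomorphic loci make a pair undefined — such pairs are skipped and
  counted, never silently zeroed.
* VIF pruning: ridge $10^{-8}$ on singular correlation matrices; ties
  remove the later SNP.
* PCA: eigenvalues clipped at zero before scaling coordinates; sign
  convention as above.
* EM clipping of F to [0.01, 0.99] can in principle cost a fraction of a
  log-likelihood unit; monotonicity is asserted with a $10^{-8}$
  relative tolerance.
* Validation never discards records: missing parents become phantom
  founders (sex inferred from role), duplicate identifiers collapse to
  the first record, cycles are broken by unlinking the offending parent
  link; everything is counted in the report.
* The YAML run configuration round-trips losslessly; one master seed
  drives a run, with stage streams derived from it.

## Problem sizes used in tests and the acceptance script

The bundled checks run on desk-scale data chosen as the smallest sizes
at which each property is comfortably demonstrated: simulated datasets
of 2 breeds × 4 countries × 16–24 founders over 3–4 generations with
120–300 SNPs; oracle comparisons on 200-animal pedigrees and 10 × 50
genotype toys; ancestry recovery on 2 populations × 100 individuals ×
2000 SNPs ($F_{ST}$ 0.15); model selection on 4 populations × 25
individuals × 400 SNPs ($F_{ST}$ 0.2) over k = 2..8 with 3 folds;
Hudson-$F_{ST}$ recovery on 200 + 200 individuals × 5000 SNPs.  The
acceptance script reruns the same computations from scratch under a
caller-supplied seed.

## Known limitations

* Fuzzy-match scores use plain Levenshtein similarity; no keyboard or
  digit-transposition model.
* The connectedness tables classify `review` matches as missing, as the
  conservative default; a manual-review workflow would move them.
* Admixture EM is unaccelerated; for tens of thousands of SNPs and
  individuals the original quasi-Newton tools are far faster.
* The simulator's export model moves individual sires, not semen lots or
  embryo batches; counts per generation are binomial, not bursty.
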