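---
title: "Methods: cross-phenotype sharing, enrichment and colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-phenotype sharing, enrichment and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

`pleioscan` scores shared genetic architecture between pairs of traits from
GWAS summary statistics. This vignette is the package's own account of the
statistical machinery, the tunable parameters and their defaults, the
numerical choices, what the synthetic generator establishes (and what it
cannot), and the design decisions that were genuinely open.

## 1. From summary statistics to independent lead SNPs

A GWAS summary file contributes, per variant, an rsID and a p-value
(optionally chromosome, position, effect size, standard error, effect allele,
MAF). Two parsing rules matter downstream:

* **p-values are stored as natural logarithms.** Catalog entries reach
  magnitudes like 1e-195; values below ~1e-308 underflow a double. Parsing
  splits scientific notation into mantissa and exponent, so `log p` is exact
  to double precision at any magnitude, and serialization formats from the
  log representation — an output p-value is never written as `0`.
* **Duplicate rsIDs within one trait keep the record with the smallest p.**
  Merged catalogs repeat trait–SNP rows; the smallest p matches lead-signal
  semantics. The choice is recorded in the per-file parsing report because it
  is a convention, not a forced move.

Each trait is then reduced to independent lead SNPs by greedy LD clumping
with PLINK semantics: rank records by ascending p (ties broken by chromosome,
position, rsID, for reproducibility — the ordering of ties is otherwise
arbitrary); the best remaining record with `p <= p1` opens a clump and claims
every unassigned record with `p <= p2`, within `kb` of it, and with
`r^2 >= r2` against it. Defaults mirror standard practice: `p1` 1e-5 (query
traits; 5e-8 for clinical catalogs, 1e-3 to 1e-5 for molecular and cellular
GWAS where genome-wide significance is rarely reached), `p2` 1, `r2` 0.4,
`kb` 1000. Only the index SNPs feed the downstream analysis, so each record
joining at most one clump is observationally equivalent to PLINK's
multi-membership report here. SNPs absent from the LD source are treated as
being in linkage equilibrium — the conservative direction, producing more
(not fewer) independent leads — and counted in the run report. Records
without positions are clumped by LD alone.

One refusal is deliberate: when the LD source is a proxy table built with
retention cutoff 0.4 and the requested clumping `r2` is lower, the pairs
needed to clump correctly were never stored, and the operation errors rather
than silently under-clumping.

## 2. The LD reference

The reference is a phased haplotype panel (VCF, e.g. 1000 Genomes-like).
Variants with minor allele frequency below 0.01 or missingness above 0.1 are
removed; records sharing identical coordinates are merged to the first;
duplicated rsIDs keep the first occurrence. For phased haplotypes,

$$ r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}, \qquad D = p_{AB} - p_A p_B, $$

with frequencies taken over jointly observed haplotypes (missing entries
excluded pairwise); monomorphic variants have no defined correlation and are
reported as `NA`, never stored. For unphased input the package falls back to
squared genotype-dosage correlation and tags the table `dosage`, because
haplotype frequencies are not identifiable without phase.

Pairs are computed for same-chromosome variants within **both** a 1000-kb
physical window and a 10,000-SNP count window, and retained when `r2 > 0.4`.
Two knobs here were genuinely open:

* *Strict versus non-strict cutoff.* Usage in the field varies between
  "greater than" and "at or above". The comparison operator is a single
  configuration point (default strict `>`), recorded in the table metadata
  and echoed in run reports.
* *The SNP-count window.* Descriptions of windowing in base pairs versus SNP
  counts conflict in common usage; the explicit window parameters govern
  here, and both are exposed.

The store is a flat TSV with `#key=value` metadata lines plus an in-memory
keyed table; queries are symmetric (`query(a)` contains `(b, r)` exactly when
`query(b)` contains `(a, r)`), unknown rsIDs return an empty set, and
overriding the cutoff *below* the build-time retention threshold is an error
(the data are not there).

## 3. Shared loci, SNP blocks, and the enrichment test

For a trait pair, sharing is detected at two levels: **direct** — the same
lead rsID in both traits — and **indirect** — a lead of one trait has a
stored proxy (r² at or above the cutoff) that is a lead of the other. All
SNPs appearing in shared pairs are then merged into **blocks**: union–find
over identity edges, the shared pairs themselves, and every proxy edge among
those SNPs, iterated to a fixed point, so a chain a–b–c at r² just above the
cutoff is one block even if a and c are uncorrelated. `k` is the number of
blocks; a block is "direct" if it contains at least one direct match. Blocks
are labelled by their smallest-coordinate member (lexicographic rsID when
positions are unknown) for stable output ordering. Because blocks are
disjoint and each contains at least one lead of each trait, `k <= min(n1,
n2)` holds structurally; a defensive cap with a warning remains for
pathological inputs.

The sharing p-value is the one-sided upper tail

$$ p = \sum_{j \ge k} \frac{\binom{n_2}{j}\binom{N_e-n_2}{n_1-j}}{\binom{N_e}{n_1}} $$

— Fisher's exact test against the null that the two traits' leads are
independent draws from `N_e` interchangeable independent SNPs. The tail sum
(not just the point mass at `k`) is used because reported significance values
for such tests are tail probabilities; the point-mass variant is available
via `method = "pmf"` for comparison. The sum is assembled in log space from
`lchoose` terms with log-sum-exp, so `p ~ 1e-200` is exact on the log scale.
Properties tested: strict monotone decrease in `k`, symmetry in `(n1, n2)`,
and agreement with an independent rational-recurrence oracle and with
`stats::phyper` to relative error below 1e-12.

**The universe size `N_e`** is the effective number of independent common
SNPs in the ancestry group — a constant of the reference population, not of
the data. It is configuration with recorded provenance. The shipped defaults
are derived from published per-ancestry genome-wide significance thresholds
via `N_e = 0.05/alpha`: EUR 1,634,000 (alpha ≈ 3.06e-8), AFR 3,355,705
(alpha ≈ 1.49e-8), ASN 1,000,000 (alpha = 5e-8). Two remarks matter when
comparing numbers across tools. First, published per-pair significance values
from catalog-scale scans are usually BH-adjusted across millions of pairs;
a raw `fisher_enrichment` output is not comparable to such a value without
knowing the run's `m` and the pair's rank. Second, fold enrichment
`k\,N_e/(n_1 n_2)` scales linearly in `N_e`, so quoted fold enrichments
implicitly pin the constant's scale; the EUR default is consistent with
benchmark fold enrichments in the thousands for strongly shared metabolite–
disease pairs.

Similarity indices complement the p-value: Jaccard `k/(n1+n2-k)`, Sørensen
`2k/(n1+n2)`, and Chao–Sørensen `2UV/(U+V)` with `U`, `V` the shared
fractions of per-trait abundance. The plain abundance-based estimator is
used, without the rare-species correction term of the full estimator: lead
SNPs come with no replicated incidence data that the correction needs, and
under unit weights (the default) the estimator reduces *exactly* to the
Sørensen value, which is the tested contract. A weights hook exists because
the index is abundance-based in origin; its use is flagged in output
metadata.

**Multiple testing.** BH step-up (with enforced monotonicity) and Bonferroni
are computed across all pairs of the current run — matching per-run FDR
semantics of an interactive tool — with `m` overridable for whole-catalog
correction. Both are computed in log space for the same underflow reasons as
above; `stats::p.adjust` is the oracle in tests on normal-range inputs.
Significance is flagged at FDR 0.1 by default. Pairs with `k = 0` are
retained at `p = 1` (droppable by flag) so `m` is explicit, not implicit.

## 4. Colocalization

Sharing by proxy does not establish a common causal variant. For a shared
region (default: ±200 kb around a lead SNP, traits intersected on rsID), the
package computes per-SNP Wakefield approximate Bayes factors

$$ \log \mathrm{ABF} = \tfrac12\left[\log(1-r) + r z^2\right], \quad
   z = \beta/\mathrm{se}, \quad r = \frac{W}{W + \mathrm{se}^2}, $$

with prior effect standard deviation `sqrt(W)` of 0.15 for quantitative and
0.2 for case-control traits (configurable), and assembles the five
single-causal-variant hypotheses in log space: H0 (no association), H1/H2
(one trait only), H3 (two distinct causal variants; the cross-product sum
minus same-SNP terms), H4 (one shared causal variant). Priors default to
`p1 = p2 = 1e-4`, `p12 = 1e-5`. Posteriors are normalized with log-sum-exp;
per-SNP H4 contributions are normalized to 1 and the maximal contributor is
reported as the candidate causal SNP. `prior_sensitivity()` re-evaluates the
posterior over a `p12` grid while reusing the cached ABFs; PP4 is monotone
nondecreasing in `p12`.

Numerical and interface choices:

* When `beta`/`se` are missing, `z` is reconstructed from the log-scale
  p-value via the inverse normal quantile (`log.p = TRUE`, so it works at any
  magnitude) and `se` approximated from (MAF, N) — `1/sqrt{2f(1-f)N}` for a
  unit-variance quantitative trait, with an `s(1-s)` case-fraction factor for
  case-control. The result records how many SNPs used this lossier route.
* MAF gaps are backfilled from the reference panel; SNPs absent from the
  panel are dropped and counted. Existing values are never overwritten.
* `p12 = 0` forces PP4 = 0 exactly; a single-SNP region forces PP3 = 0
  exactly (H3 needs two variants).
* A units caveat: multiplying one trait's `beta` and `se` by a constant `c`
  leaves `z` unchanged but *changes* `r` and hence the posteriors, unless the
  prior `sqrt(W)` is scaled by `c` too. Posterior invariance under a units
  change therefore holds only jointly with the prior — the property tests
  assert exactly that form.
* Alleles are harmonized by rsID only; effect-sign flips between studies are
  out of scope and documented as a limitation.

## 5. The synthetic world

Every stage is exercised without downloads by a fully seeded generator.

* **Panels.** Each LD block draws a founder haplotype at a frequency away
  from the boundaries (0.25–0.75, redrawn until realized frequency is in
  0.1–0.9) and copies it into member SNPs with per-SNP flip probability
  `eps = (1 - t^{1/4})/2` for target `t`: two independently mutated copies
  of a founder have expected `r^2 = (1-2eps)^4` at the founder frequency.
  A target of 1 copies exactly; requesting exact LD together with explicit
  nonzero noise is a contract error. Blocks are mutually independent, and
  block starts are spaced so cross-block pairs fall outside the default
  window. Realized within-block mean r² is within ±0.1 of the target for
  200+ samples (tested). An optional boundary variant with MAF just below
  0.01 exercises the panel filters. Panels serialize to minimal conformant
  VCF and round-trip through the standard VCF parser.
* **Trait pairs.** Leads are planted on distinct blocks; direct overlaps
  share the identical SNP, proxy overlaps place the second trait's lead on a
  different SNP of the same block (detectable only through LD), background
  SNPs get uniform p above the index threshold on a separate chromosome. The
  truth record (expected `k`, `k_direct`, `k_indirect`) travels with the
  data, so recovery tests compare against ground truth rather than
  re-deriving expectations.

What a green synthetic suite establishes: the detection, merging, counting,
enrichment and correction machinery is correct on data whose truth is known,
across 200 seeded replicates, with exact recovery of planted counts whenever
block LD exceeds the 0.4 cutoff. What it does not establish: performance
under real LD (long-range, admixture, variable block structure), allele
mismatches between studies, winner's-curse effect sizes, or catalog-scale
trait correlations — the generator makes no attempt to emulate those.

## 6. Degenerate inputs and tie-breaks

* Empty clumping result (nothing passes `p1`): legal, warned, empty loci set.
* Empty proxy table: legal; all sharing is then direct-only.
* Monomorphic variants: `NA` r², never stored, never an edge.
* `k = 0`: enrichment is exactly 1; all similarity indices exactly 0.
* Ties in p during clumping: broken by (chromosome, position, rsID), so
  permuting input rows never changes the output (tested property).
* Worker count in the all-pairs driver never changes results: pairs are
  computed independently and assembled in a fixed order.

## 7. Known limitations

* `N_e` defaults are threshold-derived approximations; analyses intended for
  publication should set ancestry constants from their own reference and
  record the provenance string.
* Genome-build liftover, effect-allele harmonization, phasing and
  imputation are out of scope; inputs are assumed on one build.
* The colocalization model assumes at most one causal variant per trait in
  the region; multi-signal regions need conditional decomposition first.
* The greedy clumping reproduces index-SNP semantics, not PLINK's report
  files byte for byte; stepwise conditional analysis is not attempted.
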