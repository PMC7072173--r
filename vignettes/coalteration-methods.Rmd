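---
title: "Methods: snoRNA/host gene co-alteration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snoRNA/host gene co-alteration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snohost)
```

## The question

Roughly half of known small nucleolar RNAs (snoRNAs) sit inside introns of a
host gene — protein-coding or long non-coding — and are co-transcribed with
it. A somatic copy-number alteration (CNA) that hits such a locus can
therefore hit the snoRNA, the host, or both, and expression changes may or
may not track the copy number. This package quantifies that joint behavior
across tumor cohorts: given discrete copy-number calls, expression
abundances, and a table of snoRNA/host couples, it measures how often the
two members of a couple are altered together or separately, which couples
recur across cohorts, and how copy-number amplification relates to
over-expression.

## Event model

Copy-number status per gene and sample is the standard five-level discrete
code: -2 deep (homozygous) deletion, -1 shallow deletion, 0 diploid, +1
low-level gain, +2 high-level amplification. **Only the deep calls (-2, +2)
count as CNA events**; shallow codes are treated as diploid-like noise.
Each (couple, sample) cell is then one of:

* `none` — neither member carries a deep event;
* `snorna_only` / `host_only` — exactly one member is altered;
* `co_occurring` — both members are altered. Co-occurrence does **not**
  require equal signs; a sign-discordant pair (one amplified, one deleted)
  is still co-occurring, and concordance is recorded separately because
  discordant cells are biologically odd and worth surfacing rather than
  silently merging.

A cell with a missing code on either side is classed `missing` and excluded
from both numerator and denominator of every frequency (excluding rather
than imputing avoids biasing frequencies downward).

From the classified cells, per cohort:

* **cumulative CNA frequency** = altered cells / (couples x samples -
  missing cells). By default an altered cell counts once even when both
  members are hit (`event_counting = "cell"`), which keeps the statistic in
  [0, 1] for the stated denominator; `event_counting = "gene"` counts a
  co-occurring cell twice for users who want gene-level event totals.
* **per-sample rates** — counts of `snorna_only`, `host_only` and
  `co_occurring` cells divided by the number of samples.
* **amp/del breakdown** — sign counts per context. The main table counts
  the snoRNA-side sign for `snorna_only` and `co_occurring` cells and the
  host-side sign for `host_only` cells; host-side signs of co-occurring
  cells are emitted as a companion table. This is also the set of events
  whose sign is directly interpretable as the amplification/deletion mix.
* **couple-level classes** — a couple is `co_occurring` in a cohort if at
  least one of its cells is, `altered_non_co` if it is altered but never
  jointly, `absent` otherwise. Because "share of couples" can reasonably be
  taken over all couples or over altered ("mutant") couples only, both
  denominators are emitted.

Across cohorts, each couple is `never` altered, altered in `all` cohorts
analyzed, or altered in `some`. A couple measurable in no cohort (both
members absent from every matrix) is `not_evaluable` and excluded from the
percentages; a couple absent from one cohort can be at most `some`, since
`all` requires alteration in every cohort analyzed. Top-k rankings order
couples by the fraction of non-missing samples with any altered cell, with
a deterministic tie-break (descending fraction, then ascending
`snorna_symbol/host_symbol` label, then ascending snoRNA id) so that
repeated runs and golden files agree byte-for-byte.

## Expression model

Expression values are non-negative RSEM-style abundances. For each gene,
the **diploid reference** is the set of samples with copy-number code 0 for
that gene (samples lacking a copy-number code stay out of the reference
even if expression exists, because the reference is defined by diploid
status). The Z-score of sample *j* is

    z_gj = (x_gj - mean(reference_g)) / sd(reference_g)

with the unbiased (n-1) standard deviation — the common convention for
sample-based standardization; both the reference floor (`min_ref`, default
3 samples) and the denominator convention are package choices the portal
definition of diploid-referenced Z-scores leaves open, and `min_ref` is
configurable. Genes with fewer
than `min_ref` reference samples or zero reference spread get all cells
flagged `undefined`. A call is `up` if z > 2 and `down` if z < -2 — both
strict inequalities, so z = 2 exactly is `normal`. Z-scores are invariant
under positive affine rescaling of a gene's row, so library-size or unit
changes that act linearly per gene do not move calls.

Only samples present in both matrices are scored, which keeps copy-number
and expression calls aligned for the concordance statistics. A couple
counts as up-regulated in a sample if **either** member is up (counted
once, with the driving member recorded); the couple-level rule is a package
choice, with per-member counts retained so the host-only or snoRNA-only
readings remain recoverable. snoRNA rows in the expression matrix are
scored like any other row; a log line reminds the user that short-RNA
library protocols can under-detect snoRNAs, but no correction is attempted.

## Association testing

Independence of "snoRNA altered" and "host altered" across samples is
tested per couple with a Fisher exact test written from first principles:
conditioning on the margins, the top-left count is hypergeometric, with
probabilities computed via log-space factorials (stable to totals around
1e6). The two-sided p-value follows the probability method — the total
probability of tables with the same margins whose probability is at most
that of the observed table, using a relative tolerance of 1e-7 on the tie
comparison, matching the default behavior of the major statistics
ecosystems. A zero margin leaves a single admissible table and p = 1 by
convention. Odds ratios use the cross-product, with the Haldane 0.5
correction (flagged) when any cell is zero. Because 295 couples are tested
per cohort, Benjamini-Hochberg adjusted p-values are reported next to the
raw ones; raw values are kept so single-test behavior remains recoverable.

The test suite verifies exactness by exhaustive enumeration over every 2x2
table with total at most 12 (integer-arithmetic oracle, tolerance 1e-10)
and cross-checks larger random tables against the reference implementation
in `stats`. One calibration subtlety is worth stating: an exact conditional
test is *conservative* under discreteness, so its realized type-I error at
nominal 0.05 sits below 0.05 (around 0.035 at margins of ~40/400). The
sound guarantee — the rejection rate under independence does not exceed the
nominal level — is asserted in the test suite.

## The synthetic generator

Real TCGA/cBioPortal extracts drift across database snapshots, so all
validation runs on a seeded generator whose parameters are the quantities
the pipeline estimates. Per (couple, sample) cell: an alteration occurs
with probability `p_alt` (scalar, or per-couple vector); given one, both
members are hit with probability `p_co`, otherwise one member (the snoRNA
with probability `p_sno_given_single`); each event is an amplification
with probability `p_amp`; a joint event is sign-concordant with
probability `p_sign_concord`, otherwise the host takes the sign opposite
the snoRNA's. Diploid cells pick up spurious shallow codes at rate
`p_shallow` — pure nuisance that exercises the deep-event restriction —
and copy-number cells can be masked at rate `p_missing` (default 0) to
exercise the exclusion rules. Expression is log-normal per gene
(baseline `mu_g ~ N(expr_log_location, expr_log_scale)`) with
multiplicative noise `exp(N(0, noise_sd))` and a dosage multiplier:
`f_amp` for amplified cells, `f_del` for deeply deleted ones; the
log-normal form guarantees non-negativity and the right-skew of RSEM-style
abundances. `f_amp = 1` and `f_del = 1` are allowed so the dosage effect
can be switched off for null checks.

Defaults (295 couples, `p_alt` 0.05, `p_co` 0.5, `p_amp` 0.7,
`p_sign_concord` 0.9, `p_shallow` 0.1, `f_amp` 4, `f_del` 0.25, `noise_sd`
0.5, baseline location log(1000), scale 1) encode the broad regime the
cohorts under study display: a few percent of cells altered,
co-occurrence for about half of the altered couples, amplifications
outnumbering deep deletions. Three presets bracket the cohort extremes:
`kirc_like` (`p_alt` 0.02, `p_co` 0.75 — co-occurring cells outnumber
single-member cells 3:1 in expectation), `ov_like` (`p_alt` 0.15, high
burden) and `brca_like` (`p_alt` 0.08, `p_co` 0.3, mostly decoupled).

What the generator does **not** emulate: genomic positions and
segment-level correlation between neighboring loci, tumor purity and
subclonality, couple-to-couple heterogeneity in alteration rates under the
scalar default (with a uniform `p_alt` every couple is eventually altered
in every large cohort, so the never/all/some split degenerates to "all";
pass a per-couple `p_alt` vector with a mass at zero to emulate a
realistic split), and the short-RNA library bias that suppresses snoRNA
read counts. Passing tests on this generator therefore demonstrates the
*counting and inference machinery* is correct under known truth — not that
any particular biological frequency will be reproduced on real extracts.

## Validation problem sizes

The package validates itself at sizes chosen to make binomial standard
errors informative while keeping the default test run fast: counting
operations against an independent nested-loop reference on 100 random
cohorts of 20 couples x 30 samples; exact-test enumeration to n = 12;
type-I calibration with 295 couples x 400 samples x 200 replicates;
parameter recovery per preset at 1000 samples (3 binomial SE bands);
dosage-effect checks at 100 couples x 400 samples. End-to-end determinism
is asserted byte-for-byte on a full simulate-run-report cycle; the run
manifest records versions, settings and input checksums (keyed by file
name, not path, so identical inputs give identical manifests anywhere).

## Known limitations

* The cell-level vs gene-level event-counting ambiguity is resolved by a
  documented default and a switch, not by divination; tables record which
  mode produced them.
* The `all`/`never` categories are sensitive to couple coverage: a couple
  dropped from one cohort's matrices can never be `all`.
* Undefined Z genes (small or constant diploid reference) are excluded
  from expression-rate numerators; cohorts dominated by such genes will
  report low rates with a large logged undefined count rather than an
  error.
* The Fisher test's conservatism under discreteness is inherent to exact
  conditional inference, not an implementation artifact; users who need
  nominal-size behavior at these margins would have to move to mid-p or
  unconditional tests, which are out of scope here.
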