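---
title: "mirseed: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirseed: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseed)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the parameters that matter and why their
defaults are what they are, what the synthetic-data generators emulate (and
what they do not), and the numerical choices made where the design was
genuinely open.

## The biological setting

A mature miRNA represses mRNAs mainly through its **seed**, nucleotides 2–7
of the ~22-nt guide. For a deeply conserved, tissue-dominant miRNA such as
miR-122 in the vertebrate liver, the seed is identical across species even
when the rest of the precursor drifts, so a species with sparse genome
annotation can still get a credible species-specific target list: take
whatever annotated 3′UTRs exist, and keep those containing a perfect match
to the seed's reverse complement. `mirseed` packages that workflow —
precursor conservation profiling, UTR seed scanning, ortholog transfer,
gene-set enrichment of the resulting targets, design of a seed-anchored
antisense inhibitor, and the qPCR/metabolite statistics of the resulting
in vivo experiment — with simulators that generate every input with known
ground truth.

## Sequence model and coordinates

Sequences are uppercase strings over `A,C,G,T,U,N` with an explicit DNA/RNA
alphabet; `coerce_alphabet` is the T↔U isomorphism, so a DNA qPCR primer
can stand in for the mature miRNA it amplifies. All coordinates everywhere
are 1-based and inclusive on the given (sense) strand — the same convention
as "nucleotides 2–7". Two rules are deliberate:

* lowercase input (soft-masking in UTR databases) is uppercased with a
  warning, not an error — masking is irrelevant to exact seed matching;
* `N` is allowed but never matches any site position, a conservative
  choice: an ambiguous base cannot certify a perfect site.

## Conservation profiling

Hairpin ortholog families (70–90 nt, a dozen or two species) are aligned
with a center-star progressive aligner built on a Needleman–Wunsch core
(match +1, mismatch −1, linear gap −2 by default, configurable). At this
scale a heavyweight MSA program adds nothing, and an internal aligner is
deterministic and fully testable: traceback ties prefer diagonal, then a
gap in the second sequence; the center is the sequence with the smallest
summed 3-mer distance to the rest, and remaining sequences merge in
increasing distance order under "once a gap, always a gap". Degapping any
row must reproduce its input exactly — that invariant is property-tested,
and pairwise scores are checked against an independent aligner.

The per-column score is the **modal non-gap residue fraction** — the
fraction of aligned species agreeing on the most common residue — because
the question asked of such figures is "conserved or not", not "how many
bits"; a normalized-entropy alternative is available via
`conservation_profile(..., metric = "entropy")`. Columns with gap fraction
above 0.5 are flagged; all-gap columns are undefined and excluded from
region means. Region scores project mature/star/loop coordinates, defined
once on a reference sequence, through that sequence's aligned row. The
expected signature for a conserved miRNA family is a frozen mature arm
(score 1.0), a nearly frozen star arm, and a drifting loop.

## Target prediction

`site_sequence` builds the UTR-strand match string per site class: the
6mer is the DNA reverse complement of mature 2–7 (`CACTCC` for miR-122),
7mer-m8 extends pairing to position 8, and 7mer-A1/8mer append an `A`
opposite position 1 (the 3′ side of the site read 5′→3′). The default is
**6mer only**: presence of one perfect seed match makes a UTR a predicted
target, site counts are reported but not used for selection, and only the
given strand is scanned (a 3′UTR is single-stranded transcript). The wider
classes are opt-in extensions. Overlapping occurrences are all reported
(lookahead matching), which matters for tandem sites.

Ortholog transfer is a user-supplied two-column table — no live database
queries, for reproducibility — with first-occurrence-wins on duplicate
source ids. `conserved_fraction` reports `100 × overlap / n_targets` with
half-up rounding to a whole percent; with 9 conserved genes over 83
predicted targets that is 10.84…%, reported as 11%. The denominator is the
predicted-target count (83-style bookkeeping) rather than the mapped-homolog
count; since both conventions exist, the function also accepts an explicit
numeric denominator.

Under a uniform base composition the expected 6mer count in a UTR of
length L is (L−5)/4⁶ ≈ 0.24 sites for L = 1000, which is what makes a
*perfect* seed match a usable single filter at the scale of ~10³ UTRs; the
scanner is tested against this analytic rate and against a brute-force
window oracle.

## Gene-set (sub-network) enrichment

Each gene set is scored against the rest of the universe by a two-sided
Mann–Whitney U test on per-gene scores, the statistic used by sub-network
enrichment tools built on curated interaction databases. Because those
databases are proprietary, the module consumes ordinary GMT collections —
the statistics are identical, the set definitions are the user's. Choices:

* **background = universe minus set members** (competitive, disjoint
  groups); the construction inside commercial tools is not published, so
  the standard one is used and documented rather than guessed;
* two-sided by default, sidedness configurable;
* exact p by enumeration when n₁+n₂ ≤ 12 with no ties (feasible and exact),
  tie-corrected normal approximation with continuity correction otherwise;
* gene-id matching is case-insensitive after trimming (human-symbol noise);
* significance is flagged on the raw p < α (0.05) to mirror the filtering
  convention of those tools, with BH-adjusted q-values reported alongside
  for anyone screening many sets;
* a hypergeometric upper-tail companion is computed when scores are binary
  target membership.

Type-I calibration (fraction of null sets with p < 0.05 over 2000 simulated
sets within 3 standard errors of 0.05) is asserted in the test suite.

## Inhibitor design and verification

The design rule is pure Watson–Crick complementarity: the oligo is the DNA
reverse complement of mature positions `[anchor, anchor+L−1]`. The default
anchor is position 2 — the seed start — because isomiRs of one family share
their 5′ core and differ at the 3′ end; a seed-anchored oligo therefore
binds all of them. A 13-nt oligo anchored at 2 covers positions 2–14 and,
for the bundled miR-122 family, is `ATTGTCACACTCC`. No LNA chemistry,
melting temperature or dosing is modeled: the sequence rule is the design.

`verify_inhibitor` searches all (start, length) windows for the longest
contiguous mature stretch whose reverse complement is an oligo substring —
exhaustive at these lengths, and checked against an independent exhaustive
oracle in tests. `offtarget_screen` flags panel miRNAs whose entire seed is
complementary to some oligo window: the condition for unintended
sequestration. The bundled isomiR family uses synthetic 3′ variants
(truncated/extended) around the mature working sequence, since exact
sequenced isomiR 3′ ends are not published; they are labelled as stand-ins.

## qPCR and downstream statistics

Relative expression uses the efficiency-corrected ratio
`E_t^(Ct̄_cal,t − Ct_s,t) / E_ref^(Ct̄_cal,ref − Ct_s,ref)` with the
calibrator Ct̄ the mean over the control group, because per-gene
amplification factors (E between ~1.8 and 2.2 from dilution curves, i.e.
90–110% efficiency in the `100·E/2` display convention; `100·(E−1)` is also
supported) are the norm in this field; a ΔΔCt mode with E forced to 2 is
provided. Technical replicates are averaged at the Ct level before ratios —
the standard treatment, and the one that keeps downstream ANOVA from
pseudo-replication. By construction the calibrator group's geometric mean
ratio is 1. `E ≤ 1` is rejected (a non-amplifying assay cannot be
quantified).

Assumption checks are Shapiro–Wilk on group-mean-centered residuals and
Levene's test (mean-centered, the classical form); failure of either at
0.05 triggers a log₁₀ recommendation and an automatic re-check on the
transformed data. The module records whether a transform was triggered per
endpoint rather than presuming any particular historical choice.

One-way ANOVA is the classical decomposition (df = k−1 and N−k; three
groups of six give df = (2, 15)). The post-hoc is **Student–Newman–Keuls**:
ordered means, the range spanning r means tested against
`qtukey(1−α, r, df_within)`, working inward, with any accepted range
shielding its interior (the classical protection rule); standard errors use
the Tukey–Kramer form so mild imbalance is handled. The compact letter
display assigns letters over descending means so that sharing a letter ⟺
not separated; on a control-vs-two-equal-doses design the expected pattern
is one letter for both doses and another for the control — the
"irrespective of dose" signature. SNK is at least as anticonservative as
Tukey HSD at the same α; the rejection-superset relation and the
letters/rejection round-trip are asserted in tests.

## What the simulators emulate — and what they do not

Every generator is a pure function of (configuration, seed), restores the
caller's RNG stream, and emits a truth record beside its data.

* `simulate_utrs` — a UTR pool with planted sites. Defaults: 1059 UTRs,
  planted target fraction 83/1059, one site per target, uniform base
  composition, lengths uniform 200–1200 nt (a plausible span for annotated
  UTRs; the true length distribution of any particular database is not
  modeled). Non-target UTRs are rejection-sampled to be site-free so recall
  and precision are exact by construction — a deliberate idealization; the
  `"natural"` mode (no rejection) exists for the analytic background-rate
  property. Real UTRs have composition bias, repeats and masking; passing
  the recovery tests therefore certifies the scanner's logic, not its
  behaviour on biased genomic sequence.
* `simulate_family` — star-phylogeny i.i.d. substitutions at per-region
  rates, defaults μ_mature = 0, μ_star = 0.05, μ_loop = 0.3 on a 72-nt
  hairpin (flanks drift at the loop rate). No indels, no GTR-style rate
  structure, no real tree — enough to plant a conservation gradient, not a
  realistic evolutionary model.
* `simulate_geneset_universe` — standard-normal gene scores; planted sets'
  members shifted by log₂(enrichment factor), so factor 1 is the exact
  null; null sets draw from non-planted genes to keep calibration clean.
* `simulate_assay` — Ct values normal around per-gene baselines (biological
  SD 0.25 cycles, technical SD 0.1, duplicates), fold change f mapped to a
  ΔCt of −log_E(f); reference genes (`u6`, `ef1a`) are effect-free by
  construction. Metabolites are lognormal with CV 10% (plausible for plasma
  chemistry) around control mean × (1 + effect). The default effect map
  encodes the structure of a miR-122 inhibition experiment at n = 6 per
  group (saline / low dose / high dose): miR-122 isomiRs strongly down in
  both dose groups, non-targeted miRNAs flat, de-repressed targets up,
  glucose up 62%/67%, triglycerides −36% and free fatty acids −46% at the
  high dose, cholesterol −20% at both.

At n = 6 and CV 10% a planted +67% group-mean change is estimated only to
within several percentage points (the tests allow ±8); at n = 600 the same
estimator lands within ±1 point. That pair of checks is the honest
statement about the wet-lab arm: simulated recovery demonstrates estimator
consistency and null calibration, not reproduction of any particular
in vivo dataset.

## Numerical and scale choices

Deterministic tie-breaks (alignment traceback; result ordering by p then
set id), half-up percent rounding, exact-vs-approximate MWU switch at
n₁+n₂ = 12, and qtukey-based SNK critical values are stated above. Problem
sizes in the test suite — 500-UTR oracle comparisons, 10⁴-UTR background
calibration at L = 1000, 2000-set and 2000-analyte null calibrations,
20-replicate conservation orderings, n = 600 recovery — were chosen as the
smallest scales at which the asserted 3·SE bands are meaningful; the whole
suite runs in well under a minute on a laptop-class core.

## Known limitations

No thermodynamic or context scoring of sites (a perfect 6mer in a poor
context is still called), no conservation weighting of individual sites, no
wobble pairing in inhibitor verification, no mixed models or multi-gene
normalization (geNorm) in the qPCR stage, and the aligner is not a
replacement for a general MSA tool outside the short-hairpin regime it was
built for.
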