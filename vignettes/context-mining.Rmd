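---
title: "Mining the charge/polarity context of N-glycosylation sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining the charge/polarity context of N-glycosylation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoctx)
```

## The problem

N-linked glycosylation decorates the amide nitrogen of asparagine side
chains, canonically inside an N-X-S/T sequon (occasionally N-X-C), and
the efficiency of the transfer depends on the wider sequence
neighbourhood of the acceptor site. glycoctx asks a statistical
question about that neighbourhood: over a set of proteins with
annotated acceptor sites, which residues — and which physicochemical
*classes* of residues — are over-represented at which signed offsets
around glycosylated asparagines (N+) compared with non-glycosylated
ones (N−), and which *combinations* of such position-specific features
co-occur often enough to act as association patterns discriminating
the two classes?

The pipeline is: extract fixed-width context windows; optionally
encode them into charge/polarity classes; estimate significantly
preferred (symbol, position) items; mine maximal association patterns
of those items over a grid of support thresholds; and validate mined
rules by conformity percentages on independent peptide sets.

## Context windows

Every annotated asparagine yields a window of `2 * flank + 1` symbols
with the asparagine at signed offset 0 and `flank = 10` residues on
each side (21-mers by default). Annotations are 1-based along the
protein; window offsets are signed, downstream positive. Positions
beyond a terminus are padded with `-`; the pad is not a residue: it
can never match a mined item and is excluded from all composition
counts. Cleaning precedes everything and is idempotent: proteins with
non-standard characters are excluded entirely (their composition would
pollute the background), duplicate (protein, position) annotations
collapse to one — with the annotated modification winning when labels
conflict — and out-of-range or non-asparagine positions are dropped,
each input site counted under exactly one removal class.

Negative sites are every asparagine not annotated positive. Because
negatives outnumber positives roughly tenfold, the two classes are
balanced before mining: negatives are ordered deterministically by
(protein, position), permuted with a seeded Mersenne–Twister
generator, and the first `ratio * n_positives` taken (`1:1` by
default, `1:2` available). Reproducing the subsample outside R
requires an MT-compatible generator; within R the contract is exact.

## Charge/polarity encoding

The five side-chain classes are

| symbol | chemical nature            | residues          |
|--------|----------------------------|-------------------|
| P      | positively charged         | K, R, H           |
| N      | negatively charged         | D, E              |
| L      | polar, uncharged           | S, T, C, M, N, Q  |
| O      | non-polar, aliphatic       | G, A, V, L, I     |
| A      | aromatic                   | F, Y, W           |

These cover 19 of the 20 standard residues. Proline belongs to no
class; rather than silently fold it into the aliphatic group, the
default scheme maps it to a reserved symbol `X` that can never become
a mined item, keeping the omission visible in every encoded window
(`default_scheme(proline = "O")` reassigns it if a user prefers). Note
the deliberate alphabet split: the class symbol `N` (acidic D/E) is
unrelated to the residue letter `N` (asparagine) — encoded and raw
strings live in separate namespaces and are never mixed. The centre
asparagine always encodes to `L`.

## Preference estimation

For a class of windows, the observed count of symbol *s* at offset
*p* ≠ 0 is tested against a background rate with a one-sided exact
binomial test: `P(X >= x | n_p, bg_s)`, where `n_p` is the *non-pad
occupancy* of offset *p* (so terminal windows dilute nothing) and
`bg_s` is the pooled frequency of *s* over all non-pad, non-centre
positions of the same window set. An item is *preferred* iff it is
enriched (`observed > background`) and significant at `alpha = 0.05`.
Choices worth stating:

* **Background** is the class's own pooled flank composition, not an
  external proteome table — the analysis is self-contained and the
  question is positional: "is *s* more common at +2 than anywhere
  else", not "more common than in some reference proteome".
* **No multiple-testing correction by default.** Classical PTM-context
  preference tables are permissive by design; the preferred items are
  not end results but *candidates* handed to the miner, whose support
  threshold does the real filtering. Benjamini–Hochberg is available
  (`correction = "BH"`) for users who want the table itself to control
  FDR.
* The test is monotone in the count at fixed background, and one-sided:
  a depleted symbol is never preferred.

```{r preference-example}
windows <- c(rep("CANAS", 9), "GANAT")
pref <- suppressWarnings(preferred_items(windows))
pref[pref$preferred, c("item", "count", "n", "p_value")]
```

## Association mining

Items are written `<symbol,offset>`, e.g. `<L,2>`. For a pattern (a
set of items):

* **support** = percentage of *consequent-class* windows containing
  every item — the only definition consistent with a near-universal
  `<L,2>` at very high support levels while multi-item patterns
  appear only at low ones;
* **confidence** = among all windows of the *balanced two-class* set
  containing the pattern, the percentage belonging to the consequent
  class — 50% means no discrimination, and complementary patterns in
  the N+/N− tables have confidences summing to 100%.

Mining runs level-wise (Apriori, exact supports, downward-closure
pruning) at every threshold of a support grid, 5–95% in steps of 5 by
default. At each threshold only **maximal** frequent itemsets are
reported (no frequent proper superset) unless `maximal_only = FALSE`;
maximal-only reporting is what produces the characteristic cascade in
which a three-item pattern is emitted at low support and its
higher-support sub-patterns take over as the threshold rises past the
superset's support. Itemsets recurring at several thresholds are
merged, keeping the set of thresholds where each was emitted; both the
total emitted count (with repetitions) and the unique count are
reported, since published pattern tallies have used either convention.
Output order is deterministic: items sort by offset then symbol within
a pattern, rules by highest emission threshold then pattern string.

## Validation

A peptide *conforms* to a rule set when it contains at least one
pattern. Conformity percentages are rounded half-up to integers —
the convention of the published validation tables, whose four printed
matched/total pairs (216/229, 378/642, 195/229, 397/642) reproduce
exactly as 94, 59, 85 and 62 under this rounding. Sequon classes are
assigned from the residue at +2 alone (S → NXS, T → NXT, C → NXC,
anything else non-canonical), with a flag recording proline at +1.
Printed motif tables (4-mer sequons) are validated by embedding each
sequon at offsets 0..3 of an otherwise-pad window, encoding it, and
matching rules whose items all lie within the covered offsets; rules
reaching outside are skipped and reported rather than counted as
failures. External predictor output is consumed, never recomputed: a
plain TSV of (protein, position, predicted) splits the asparagines
into predicted/non-predicted peptide sets, and a tolerant parser for
the common server text report is provided as a convenience.

## The synthetic generator

`synthetic_config()` defaults describe the assembled study conditions
the generator stands in for: 1,117 proteins, 2,909 positive sites, at
least a ten-fold excess of negative asparagines (the assembled ratio
is ≈10.7), protein lengths uniform on 300–900 (chosen so a uniform
residue background yields that excess), and the two headline context
structures planted — `<L,2>` in 95% of positives and `<O,1><L,2>` in
30%, the support levels at which those patterns dominate the published
tables. Positive sites sit on non-overlapping window slots, at least
`flank` residues from the termini by default (`avoid_terminal =
FALSE` exercises padding).

Planting semantics deserve care. Each positive site, for each spec
independently, *fires* with probability *q*; on firing every item
offset receives a uniformly chosen member of the item's class (the
literature gives no within-class frequencies). Under plain overlay
planting the realized pattern rate would exceed *q* — with a uniform
background, `O` occupies +1 in 25% of unplanted windows, so a pattern
planted at 30% would be *present* in ~47%. Since the generator's
purpose is parameter recovery ("was the planted rate recovered as the
mined support?"), the default `enforce_absence = TRUE` makes the
planted fraction the ground truth: where a spec did not fire but the
full pattern happens to be present, one spec offset not controlled by
any *fired* spec is rewritten from outside the item's class. Offsets
written by a fired spec are never touched, so a pattern genuinely
implied by a fired superset spec remains — planting `<O,1><L,2>` at
30% alongside `<L,2>` at 95% leaves `<L,2>` present in ≈96.5% of
positives, as it should be. `enforce_absence = FALSE` restores plain
overlay. Specs are enforced in list order; configs with overlapping
offsets should list supersets last.

What the generator deliberately does **not** emulate: real proteome
composition (background is exchangeable across positions), ordering or
correlation between sites, genuine sequon biochemistry, disorder or
structural context, or predictor scores. Passing recovery tests on
synthetic data therefore shows that the *statistical machinery* is
correct and calibrated — not that any particular biological conclusion
transfers to real proteomes.

```{r recovery, eval = FALSE}
cfg <- synthetic_config(seed = 1)
rec <- end_to_end_recovery(cfg)
rec$recovery
#>     pattern    q recovered support_pct support_error
#> 1     <L,2> 0.95      TRUE    96.56239     1.5623926
#> 2 <O,1><L,2> 0.30      TRUE    30.18219     0.1821932
```

## Calibration, determinism, and numerical choices

* **Null calibration.** Preferred items selected from unstructured
  windows appear at no more than the nominal alpha rate. For mined
  *rules* a subtlety matters: because items are selected for
  enrichment in the positives, their in-sample confidence is biased
  above 50% even with nothing planted (winner's curse) — this is a
  property of the selection, not an implementation defect. The
  package's calibration suite therefore evaluates mined rules on
  *fresh* unplanted data, where their confidences centre on 50% and no
  rule is family-wise significant against one half.
* **Determinism.** Every stochastic step takes an explicit seed and
  runs in a locally scoped RNG; identical configs and seeds give
  byte-identical FASTA, site tables and result bundles. The pipeline
  manifest records input and output hashes so reruns can be diffed.
* **Ties and degenerate inputs.** Support comparisons use an epsilon
  of 1e-9 against the threshold so exact rational supports are never
  lost to floating point; an empty eligible-item set mines an empty
  rule set (not an error); confidence of a pattern matching no window
  is an explicit error rather than 0/0; a pattern can never include
  offset 0, the pad, or the unclassified symbol.
* **Test problem sizes.** The correctness suite runs the miner against
  exhaustive enumeration on 200 random small instances (≤6 symbols,
  windows ≤7, ≤50 windows), recovery on 50 seeds of 2,000 positives,
  and null calibration on 200 unplanted replicates of 1,000 balanced
  pairs — sizes at which the binomial tolerances quoted in the tests
  are tight.

## Limitations

The preference test treats window positions as independent samples of
a pooled background, ignoring residue autocorrelation along real
sequences; the background is the class's own composition, so strong
global compositional shifts between classes would surface as many
weakly preferred items rather than a flagged composition effect; and
the miner's item space is restricted to presence items at fixed
offsets — absence constraints ("not proline at +1") and gapped or
degenerate motifs are out of scope. Published headline tables derived
from a specific annotation snapshot are treated as inputs for
arithmetic and motif validation, not as quantities the pipeline can
regenerate without that snapshot.
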