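---
title: "Methods: spectral-count enrichment discovery for nucleosome AP-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-count enrichment discovery for nucleosome AP-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucenrich)
```

## The experiment this package models

Affinity purification of mononucleosomes through a Flag-tagged histone
bait — here the variant H2A.Z — pulls down, together with the nucleosome,
whatever proteins were bound to it. Two reference pull-downs make the
readout interpretable: a canonical-histone comparator (Flag-H2A) that
shares everything generic about nucleosome binding, and a tag-only control
(Flag-GFP) that captures the background of the affinity resin and the tag.
Each condition is analysed in triplicate LC-MS/MS runs. The question the
pipeline answers is: *which proteins prefer the H2A.Z nucleosome* — over
the background, and over the canonical nucleosome?

The input is not spectra but peptide-spectrum matches (PSMs): per run, a
table of (spectrum, peptide, score, mapped accessions) as produced by any
database search engine that was run against a concatenated target/decoy
protein database. The pipeline is deliberately a deterministic filter
cascade, not a statistical model: with triplicate label-free runs and
spectral counts as the abundance proxy, fold thresholds with a
replicate-presence requirement are the field's standard first-pass ranking
for candidate selection, and every verdict is auditable by hand.

## Stage 1: PSM confidence by target/decoy FDR

Scores follow expectation-value semantics (lower is better; a switch
covers the opposite convention). With an equal-size reversed-sequence
decoy database, the number of decoy PSMs at or better than a score cut
estimates the number of false target PSMs there, so the false-discovery
proportion is estimated as

$$\widehat{\mathrm{FDR}}(t) \;=\; \frac{\#\{\text{decoy PSMs} \le t\}}
{\max\!\big(\#\{\text{target PSMs} \le t\},\,1\big)},$$

with the $2D/(T+D)$ variant available for users who prefer to treat decoy
hits as part of the accepted population. `select_threshold()` scans every
observed score as an inclusive cut and keeps the most permissive one whose
estimate is at or below the nominal level (default 0.5%, the pipeline's
reference operating point). Ties at the threshold are accepted; if no cut
reaches the nominal level (e.g. every PSM is a decoy) the function fails
loudly rather than guessing. Tightening the nominal level provably never
enlarges the accepted set, and decoy PSMs are excluded from everything
downstream regardless of score.

The FDR is controlled at PSM level. The estimator is calibrated in the
package's own tests: on labelled simulations of roughly 10,000 PSMs per
seed with 20% incorrect identifications, the median realized
false-discovery proportion among accepted targets at nominal 1% falls
between 0.5% and 2% over 20 seeds — the calibration rests only on the
exchangeability of incorrect-target and decoy scores, not on the shapes of
the simulated score distributions.

## Stage 2: parsimony protein inference

Shared peptides make protein identity ambiguous; parsimony resolves the
ambiguity by explaining all confident peptides with as few proteins as
possible. `group_proteins()` proceeds in three steps:

1. **Indistinguishable merge.** Proteins with identical peptide sets are
   merged into one meta-protein; the lexicographically smallest accession
   becomes the representative.
2. **Essential-first greedy cover.** Any protein that is the sole
   explainer of some peptide must be in every cover, so these essential
   proteins are selected outright. The remaining peptides are covered
   greedily: repeatedly select the protein explaining the most
   still-uncovered peptides, breaking ties by larger total peptide set,
   then lexicographically smaller accession. The essential pre-pass is
   always optimality-preserving and removes the classic greedy overshoot
   on instances where a large protein's peptides are all explained by
   forced proteins; on 200 random small instances the result matches an
   exhaustive-search minimum cover exactly (this oracle lives in the test
   suite, never in the implementation).
3. **Subsumption.** An unselected protein whose peptide set is contained
   in a selected protein's set joins that protein's group. If several
   selected groups contain it, it joins the one with the larger peptide
   set, then the lexicographically smaller representative — the same tie
   discipline as the cover itself. A protein whose peptides straddle two
   groups joins neither; its peptides are already explained.

A peptide is **unique** when it occurs in exactly one group's peptide set.
Peptides shared only among indistinguishable members of a single group
therefore count as unique — the group, not the protein, is the unit of
inference. `apply_two_peptide_rule()` then keeps only groups with at least
two unique peptides, applied once on evidence pooled across all runs of
all conditions (the rule defines which proteins are considered at all, not
a per-run detection criterion).

All orderings use C-locale (byte) comparison, so the grouping is
deterministic and invariant to the input row order and to the host locale.

## Stage 3: razor spectral counting

Spectral counts — the number of confident PSMs attributed to a group in a
run — are the abundance proxy. To avoid double counting, each PSM is
attributed to at most one group (razor assignment): a peptide belonging to
one group sends its spectra there; a peptide spanning several groups sends
them to the group with more unique peptides (ties: lexicographically
smaller representative). PSMs whose peptide survives in no group (possible
once the two-peptide rule has removed weak groups) stay uncounted. The
count matrix consequently conserves spectra: its total equals the number
of assigned PSMs.

"Detected in a run" means at least one assigned spectrum in that run. The
threshold sits at a single spectrum deliberately: detection feeds a
presence rule over replicates, and any higher cut would entangle it with
abundance, which the fold rule already handles.

## Stage 4: the two-stage enrichment cascade

Counts are amalgamated (summed) over the replicates of each condition, and
fold enrichment is the ratio of sums. The cascade is:

* **Stage 1 (bait vs control):** fold $\ge 10$ and detection in $\ge 2$
  of the 3 bait runs.
* **Stage 2 (bait vs comparator):** among stage-1 survivors, fold
  $\ge 2$ with the same bait-presence rule.

Thresholds are inclusive. Three numerical choices matter:

* **Zero denominators.** A protein absent from the control cannot be
  penalised for it: a positive-over-zero fold is $+\infty$ and passes any
  threshold. A pseudocount would instead *fail* exactly the proteins the
  control subtraction is meant to keep — low-abundance bait-specific
  binders — so none is used. A $0/0$ fold is undefined and fails every
  threshold.
* **Summing before dividing.** Folds are computed on replicate-summed
  counts, not averaged per-replicate ratios; with counts this small,
  per-replicate ratios are dominated by zeros and the amalgamated ratio is
  the stabler statistic. Replicate labels within a condition are
  exchangeable: permuting them changes no verdict.
* **Presence applies to the bait runs only.** The replicate rule asks
  whether the *bait* evidence is reproducible; requiring presence in the
  control would contradict the purpose of stage 1.

Survivor sets are monotone in both thresholds, stage 2 is a subset of
stage 1 by construction, and scaling all counts by a positive integer
changes nothing (folds are ratios; detection thresholds at one spectrum).
The candidate table orders stage-1 survivors by descending summed bait
counts (ties: representative accession) — the natural ordering for a
top-candidates heat map — and `overlap_sets()` reports the three-set Venn
partition of per-condition detected groups.

## The synthetic screen

No raw data accompany the experiment the pipeline was built for, so the
package carries a generator whose defaults *are* the reference study
conditions: triplicates of three conditions, 500 target proteins, 20
planted bait-preferring interactors, 10-fold enrichment, mean spectral
count 3 per background protein per run, 10% incorrect PSMs, a
reversed-sequence decoy database.

Rates are Poisson per protein per run (a negative-binomial option exposes
over-dispersion; spectral counts at this depth are well approximated by
Poisson noise, which is also the most transparent model for planted
ground truth). The three protein classes are:

* **background** (470 by default): rate `base_abundance` in all three
  conditions — sticky resin-binders seen everywhere;
* **planted interactors** (`n_enriched` = 20): absent from the tag-only
  control (a true nucleosome binder has nothing to bind in a GFP
  pull-down), bait rate `base_abundance * enrichment_fold`, comparator
  rate `base_abundance` — they bind the canonical nucleosome at the
  generic background level and the variant nucleosome 10-fold more, so
  their true bait/comparator fold equals `enrichment_fold`, comfortably
  above the stage-2 threshold `comparator_fold`;
* **generic nucleosome binders** (`n_generic` = 10): bait rate in both
  bait and comparator, absent from control — they populate the
  stage-1-pass/stage-2-fail branch of the funnel, as real
  nucleosome-binding proteins without variant preference would.

Setting the planted control rate to zero rather than
`bait_rate / enrichment_fold` is a deliberate design choice: with a
nonzero control rate tied to the bait rate by exactly the threshold fold,
every planted protein would sit *on* the stage-1 boundary and recovery
would be a coin flip by construction, which describes no real screen. The
enrichment the generator plants is the situation the control subtraction
exists to detect: presence on the bait, absence on the tag.

Peptide repertoires are abstract amino-acid strings (5–12 per protein,
lengths 8–15); a `shared_peptide_fraction` of each repertoire (default
10%) is borrowed from another protein, producing the degenerate peptides
that exercise grouping and razor assignment. Correct PSM scores are drawn
as $10^{U(-8,-4)}$, incorrect and decoy scores as $10^{U(-3,1)}$ with the
mapped accession uniform over the target+decoy database — what matters
for calibration is only that incorrect-target and decoy hits are
exchangeable. Protein FASTA sequences are the concatenated repertoires;
decoys are their reversals, so decoy entries are length-matched to their
targets. Everything derives from one integer seed, end to end: the same
seed reproduces the candidate table byte for byte.

What the generator does **not** emulate: retention times, precursor
masses and spectra; correlated (batch) run effects; peptide
detectability differences (flyability); modified peptides (peptide
identity is the bare sequence); protein length effects on counts. Passing
the recovery tests therefore shows the *procedure* is implemented
correctly and behaves sensibly under Poisson count noise — not that the
thresholds are optimal for any particular instrument or depth.

## Problem sizes in the tests

The test suite runs 200 parsimony instances (up to 8 proteins, 15
peptides) against an exhaustive oracle; 20-seed FDR calibration at roughly
10,000 PSMs per seed; 20-seed recovery and null screens at the full
default size (500 proteins, 9 runs, roughly 18,000 PSMs per seed); 500
randomized matrices for the monotonicity properties; and a byte-level
determinism check of the simulate-then-run path. These sizes keep the
whole suite around a minute on one core while leaving each property
statistically meaningful.

## Known limitations

* The cascade is a filter, not a test: it reports no error control on the
  candidate list itself (SAINT-style interaction scoring is out of
  scope by design).
* FDR control is at PSM level; no protein-level FDR is computed.
* Spectral counts are not length- or run-normalised (no NSAF); the
  within-experiment comparisons the cascade makes do not require it, but
  counts should not be compared across proteins.
* Charge states and modifications do not differentiate peptides.
* With very few replicates the presence rule is coarse; `min_runs` is
  configurable but the defaults assume triplicates.
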