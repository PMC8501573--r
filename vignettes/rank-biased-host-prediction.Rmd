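---
title: "Rank-biased overlap for phage–host prediction: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-biased overlap for phage-host prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbohost)
```

## The model

Direct phage-to-host sequence similarity is a weak predictor of infection:
many phages share no detectable sequence with their host, and when they do,
the strongest alignment frequently points at a close relative of the true
host instead. `rbohost` sidesteps the direct comparison. Both the phage and
every candidate host are queried against the *same* reference database of
prokaryotic genomes, and each result table is reduced to a ranked list of
prokaryotic species. The phage–host interaction score is then the
rank-biased overlap (RBO) of the two lists,

$$\mathrm{RBO}(S,T,p) = (1-p)\sum_{d=1}^{n} p^{\,d-1} A(S,T,d), \qquad
A(S,T,d) = \frac{|S_{:d} \cap T_{:d}|}{|S_{:d} \cup T_{:d}|},$$

with $S_{:d}$ the species present in the first $d$ ranks and $n$ the larger
of the two rank counts. The intuition: a phage and its host inhabit the
same genomic neighbourhood, so the *top* of their reference rankings should
agree even when the sequences themselves barely align.

Four properties of real similarity-search rankings shape the definition,
and the `ranked_list` container enforces them:

1. top ranks matter more — handled by the geometric weights $p^{d-1}$;
2. lists need not contain the same species (non-conjoint);
3. lists differ in length — a prefix past a list's end saturates at the
   whole list, so short virus lists compare cleanly against long host
   lists;
4. species with exactly equal scores are tied — a whole tied rank enters
   the prefix at its rank's depth (depth counts ranks, not items).

### From hit tables to ranked lists

`parse_blast_tab()` keeps, per query, each subject once at its maximum
bit-score (the per-subject score is the best single HSP bit-score, not a
sum over HSPs — the conservative reading of how pairwise scores are
reported). `collapse_to_ranks()` then maps genomes to species and keeps
each species at its *first* appearance before grouping exactly equal
scores into ties. The order matters: dedup-then-group means a species'
lower-scored duplicate genome can never drag it into a tie with another
species. Ties are exact score equality with no epsilon — bit-scores are
discrete, and an epsilon would silently merge distinct ranks. Subjects
absent from the species map fall back to their own label with a warning;
this keeps the expanded-reference ("+viruses") mode — where viral sequences
sit in the reference set and link phage to host through shared similarity
to *other* phages — uniform: it changes only list content, never code path
(`score_all()` is agnostic).

Mash distance tables (`parse_mash_dist()`) follow the same route with
ascending distances; `collapse_to_ranks(ascending = TRUE)` treats equal
distances as ties.

## Tunable parameters

* **`p` (persistence, default 0.75, unitless, in (0,1))** — the weight of
  depth $d$ is $(1-p)p^{d-1}$. `weight_mass(p, k)` gives the cumulative
  share of the first $k$ ranks via the closed-form RBO weight function;
  at `p = 0.75`, `r round(100 * weight_mass(0.75, 10), 2)`\% of the weight
  sits in the first 10 ranks, so the score is effectively decided by the
  top ten species — deep, noisy tail ranks cannot swamp it. Smaller `p`
  approaches "top rank only" (as $p \to 0$ the normalized score tends to
  the depth-1 Jaccard); larger `p` spreads weight down the lists.
* **`normalize` (default `TRUE`)** — the finite sum reaches at most
  $1-p^n$, so identical finite lists would score below 1 under the raw
  formula. The default divides by the identically-accumulated total mass,
  making `rbo(S, S)` *exactly* 1 in floating point and preserving the
  stated 0–1 endpoint contract; `normalize = FALSE` exposes the raw
  truncated sum. Which convention a reference implementation uses is not
  observable from the endpoint contract alone; providing both keeps either
  comparison possible. Disjoint lists score 0 in both modes, and a pair of
  empty lists scores 0 so score matrices stay total for queries without
  hits.
* **`n`** — taken as the *maximum* of the two rank counts, so all content
  of both lists can contribute; taking the minimum would discard the tail
  of the longer list entirely.

## Evaluation protocol

`predict_hosts()` returns *all* hosts tied at a row maximum (exact
equality). `accuracy_at_level()` counts a virus correct when any predicted
host shares the level's taxon with any of its known hosts — for multi-host
viruses we accept a match to any known host, the natural extension of the
"correct if among the predictions" tie rule. Missing lineage entries never
match (and are reported), rather than erroring a whole evaluation.

For ROC/PR metrics, every virus–host pair absent from the truth set is a
negative — benchmark collections count non-interacting pairs this way, and
at desk scale there is no need to subsample them. `roc_auc()` uses the
Mann–Whitney formulation (ties count half), identical to trapezoidal ROC
integration but exact. `pr_aupr()` sums the precision–recall curve
stepwise with no linear interpolation — interpolated PR area flatters
classifiers on imbalanced data, and the stepwise sum is reproducible
bit-for-bit. `best_f1_threshold()` scans the distinct observed scores plus
one value above the maximum (the "predict nothing" cut), breaking F1 ties
toward the higher, more conservative threshold; specificity is reported at
the chosen cut but never drives the selection.

## The synthetic universe: what it emulates, what it does not

`make_planted_universe()` builds the desk-scale stand-in for a real
benchmark: each of `n_hosts` hosts gets a random tie-structured ranked
list over a shared label pool; each virus copies its (single, planted)
true host's list and corrupts it — every position is resampled from the
pool with probability `noise`, and adjacent ranks merge with probability
`noise/2`, so noise perturbs both content and tie structure. Replacements
draw from the whole pool minus labels already placed: at `noise = 1` a
virus list is a uniform random list, statistically unrelated to its host,
and species-level recovery falls to the chance level $1/\texttt{n\_hosts}$
(at `noise = 0` recovery is exactly 100%). The taxonomy nests hosts
dyadically (pairs share a genus, quadruples a family, ...), every host its
own species, so level accuracy is monotone from species to phylum by
construction.

Defaults — `pool_size = 500`, `list_len = 20`, `tie_prob = 0.15` — mirror
the working regime of real searches: reference sets far larger than any
one result list, list depths at which essentially all RBO weight (98.6% by
rank 10) is covered, and occasional exact-score ties. All draws flow from
one Mersenne–Twister generator seeded per universe, so universes are
bit-reproducible across platforms.

What the generator does *not* emulate: phylogenetic correlation between
host lists (real sister taxa have correlated neighbourhoods; here host
lists are independent), prophage-driven extreme top-rank agreement, shared
mobile elements, or database redundancy beyond the species map. Passing
recovery tests on planted universes therefore demonstrates the machinery —
ranking, scoring, tie handling, metric arithmetic — not field accuracy on
real genomes, which depends on reference completeness and true biological
signal.

One property-test detail: the chance-level check at `noise = 1` uses a
small pool (30 labels for 10 hosts) so that random lists still overlap and
scores are generically distinct. With a huge pool, every score is 0, all
hosts tie at the top, and the tie rule marks every virus "correct" — a
degenerate regime that says nothing about recovery.

`subsample_contigs()` supports the incomplete-sequence protocol: uniform
random fixed-length substrings (defaults 20/10/5/3/1 kb, 10 replicates,
overlaps allowed since replicates are independent draws; 0-based start
recorded in the contig name), with `exclude_parent()` removing a contig's
own full-length genome from ranked lists before re-scoring, shifting ranks
up when a rank empties. Runs of ambiguous bases are not filtered — only a
warning flags non-ACGT content.

## Numerical choices and degenerate inputs

* Identity at 1: the normalization denominator is accumulated by the same
  loop as the numerator, so their ratio cancels exactly for identical
  lists; clamping to $[0,1]$ then guards the last-ulp cases.
* Exact-equality ties throughout (scores, row maxima): no tolerance
  parameters exist to tune.
* Empty lists, empty rank files, queries without hits: legal everywhere,
  scoring 0 against everything.
* `score_all()` output is identical for any worker count (rows are
  independent), and the matrix TSV uses 17 significant digits, the
  shortest round-trip for doubles, so downstream evaluation is bit-stable.
* Problem sizes in the test suite (universes up to 50 hosts × 200 viruses,
  an oracle sweep of 10,000 random list pairs with ≤ 6 labels) were chosen
  as the smallest sizes at which every claimed property is exercised with
  comfortable statistical margin; all complete in well under a minute
  each.

## Known limitations

* Within-rank tie weighting is the whole-rank prefix convention; the
  conjoint-list RBO extrapolation term and per-item fractional tie weights
  are deliberately out of scope.
* Scoring is $O(\text{viruses} \times \text{hosts})$ dense; fine for
  desk- and benchmark-scale, not for millions-by-millions screens.
* The species map is trusted as given; no taxonomy validation is
  performed beyond the six-level table shape.
* Accuracy depends on reference databases through the input hit tables;
  the package never runs BLAST or Mash itself.
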