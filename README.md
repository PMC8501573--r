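# rbohost

Predicting which prokaryote a phage infects from sequence similarity alone
is hard: most phages share little or no direct sequence with their host, and
the best direct BLAST hit is often a near-relative of the true host rather
than the host itself. `rbohost` implements a ranking-based alternative (the
Phirbo approach): instead of asking *"how similar is the phage to each
host?"*, it asks *"how similar are the phage's and the host's neighbourhoods
in a shared reference database?"*.

For a phage *P* and a candidate host *H*, two similarity searches against
the same reference set *D* of prokaryotic genomes yield two hit lists. Each
list is collapsed into a ranked list of prokaryotic **species** — every
species kept at its first (best bit-score) appearance, species with exactly
equal scores tied at one rank — and the interaction score is the
**rank-biased overlap** (RBO) of the two lists *S* and *T*:

```
RBO(S, T, p) = (1 - p) * Σ_{d=1}^{n}  p^(d-1) * A(S, T, d)
A(S, T, d)   = | S_:d ∩ T_:d | / | S_:d ∪ T_:d |      (Jaccard at depth d)
```

where `S_:d` is the set of species in the first *d* ranks (saturating at
the list's end), *n* is the longer list's rank count, and the persistence
parameter `p ∈ (0, 1)` sets how steeply weight decays with depth. At the
default `p = 0.75`, about 98.6 % of the weight falls on the first 10 ranks
(`weight_mass(0.75, 10)` = 0.985808). Scores lie in [0, 1]: 0 exactly when
the lists share no species, 1 (in the default normalized mode) exactly when
they agree in content and order. The measure is tie-aware, handles
non-conjoint lists and uneven lengths, and is symmetric.

The package is aimed at viromics / phage-ecology analysts who already have
BLAST tabular (`-outfmt 6/7`) or `mash dist` output and want host
predictions plus the standard benchmark metrics.

## What's inside

* `parse_blast_tab()`, `parse_mash_dist()`, `collapse_to_ranks()`,
  `read_species_map()` — turn raw search tables into tie-aware ranked lists
  (plain-text format: one rank per line, ties comma-separated;
  `read_ranklist_dir()` / `write_ranklist_dir()`).
* `rbo()`, `jaccard_at_depth()`, `weight_mass()`, `rbo_params()` — the
  score itself.
* `score_all()` — the all-vs-all virus × host score matrix (TSV I/O,
  optional forked workers); `exclude_parent()` for the incomplete-contig
  protocol, where a contig must not match its own full-length genome.
* `predict_hosts()`, `accuracy_at_level()`, `roc_auc()`, `pr_aupr()`,
  `best_f1_threshold()`, `evaluate_interactions()` — the evaluation
  protocol: top-score host calls with tie semantics, accuracy at species
  through phylum, Mann–Whitney AUC, stepwise AUPR, F1-optimal threshold.
* `make_planted_universe()`, `emit_blast_like_table()`,
  `subsample_contigs()` — synthetic benchmarks with a planted true host
  per virus, BLAST-like tables for end-to-end exercises, and random
  fixed-length contig subsampling (20/10/5/3/1 kb ladder by default).
* A thin CLI (`inst/cli/rbohost.R`) with `convert`, `score`, `predict`,
  `evaluate` and `simulate` subcommands.

## Worked example

A phage whose best direct hit would be ambiguous is resolved by comparing
neighbourhoods:

```r
library(rbohost)

phage <- ranked_list(list("Yersinia enterocolitica",
                          c("Yersinia rohdei", "Yersinia ruckeri"),  # tied
                          "Escherichia coli"), query_id = "phage_P")
hostA <- ranked_list(list("Yersinia enterocolitica", "Shigella dysenteriae",
                          "Escherichia coli", "Erwinia toletana"),
                     query_id = "Y_enterocolitica")
hostB <- ranked_list(list("Erwinia toletana", "Escherichia coli",
                          "Bacillus subtilis"), query_id = "E_toletana")

m <- score_all(list(phage_P = phage),
               list(Y_enterocolitica = hostA, E_toletana = hostB))
round(unclass(m), 4)
#>         Y_enterocolitica E_toletana
#> phage_P            0.568     0.0405

predict_hosts(m)$phage_P
#> $top_hosts [1] "Y_enterocolitica"   $top_score [1] 0.568
```

The phage's list and *Y. enterocolitica*'s list agree at the top rank and
overlap further down, giving RBO 0.568; the overlap with *E. toletana* is
confined to a deep, lightly-weighted rank (0.0405). The predicted host is
the row maximum; had several hosts tied exactly, all would be returned and
downstream accuracy would count the virus correct if any tied host matches
the known host at the taxonomic level under evaluation.

From the shell, the same pipeline is:

```sh
Rscript inst/cli/rbohost.R convert --hits blast.tsv --species-map map.tsv --out lists/
Rscript inst/cli/rbohost.R score --viruses vlists/ --hosts hlists/ --p 0.75 --out matrix.tsv
Rscript inst/cli/rbohost.R evaluate --matrix matrix.tsv --truth truth.tsv \
        --taxonomy tax.tsv --out report.json
```

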