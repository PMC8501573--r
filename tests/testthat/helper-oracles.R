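# Independent oracles, kept deliberately naive: plain set arithmetic and
# exhaustive enumeration, sharing no code with the implementation.

# brute-force rank-biased overlap: materialize both prefix sets at every
# depth and sum the geometric series term by term
rbo_brute <- function(S_ranks, T_ranks, p, normalize = TRUE) {
  n <- max(length(S_ranks), length(T_ranks))
  if (n == 0) return(0)
  total <- 0
  for (d in seq_len(n)) {
    ps <- unique(unlist(S_ranks[seq_len(min(d, length(S_ranks)))]))
    pt <- unique(unlist(T_ranks[seq_len(min(d, length(T_ranks)))]))
    A <- if (length(union(ps, pt)) == 0) 0 else
      length(intersect(ps, pt)) / length(union(ps, pt))
    total <- total + (1 - p) * p^(d - 1) * A
  }
  if (normalize) total <- total / (1 - p^n)
  total
}

# random tie structure built directly as a list of label vectors (not via
# the package's generator)
random_tied_ranks <- function(pool, max_labels = 6) {
  k <- sample.int(min(max_labels, length(pool)), 1)
  labs <- sample(pool, k)
  if (k == 1) return(list(labs))
  grp <- cumsum(c(TRUE, sample(c(TRUE, FALSE), k - 1, replace = TRUE)))
  unname(split(labs, grp))
}

# exhaustive AUC: proportion of positive-negative pairs won, ties half
auc_brute <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  wins <- 0
  for (a in pos) for (b in neg)
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# exhaustive F1 scan over candidate thresholds (distinct scores + one above)
f1_brute <- function(scores, labels) {
  labels <- as.logical(labels)
  cand <- c(max(scores) + 1, sort(unique(scores), decreasing = TRUE))
  best <- NULL
  for (t in cand) {
    pred <- scores >= t
    tp <- sum(pred & labels)
    prec <- if (sum(pred) == 0) 0 else tp / sum(pred)
    rec <- tp / sum(labels)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    if (is.null(best) || f1 > best$f1) best <- list(threshold = t, f1 = f1)
  }
  best
}

# first-appearance dedup then equal-score grouping, written as a direct
# re-statement of the rule (reference for collapse_to_ranks)
collapse_brute <- function(subjects, scores, species) {
  sp <- unname(species[subjects])
  sp[is.na(sp)] <- subjects[is.na(sp)]
  seen <- character(0); keep_sp <- character(0); keep_sc <- numeric(0)
  for (i in seq_along(sp)) {
    if (sp[i] %in% seen) next
    seen <- c(seen, sp[i])
    keep_sp <- c(keep_sp, sp[i]); keep_sc <- c(keep_sc, scores[i])
  }
  ranks <- list()
  for (i in seq_along(keep_sp)) {
    if (i > 1 && keep_sc[i] == keep_sc[i - 1])
      ranks[[length(ranks)]] <- c(ranks[[length(ranks)]], keep_sp[i])
    else ranks[[length(ranks) + 1]] <- keep_sp[i]
  }
  ranks
}
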