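#' Taxonomic levels used by the benchmark
#'
#' Host lineages are evaluated at six levels, species (narrowest) through
#' phylum (broadest).
#' @export
TAX_LEVELS <- c("species", "genus", "family", "order", "class", "phylum")

#' Top-score host prediction with tie semantics
#'
#' For each query virus, the predicted hosts are all hosts attaining the
#' row maximum of the score matrix (exact equality). A row of all-equal
#' scores therefore predicts every host — downstream accuracy scores such a
#' virus correct only if its true host is among the tied set.
#'
#' @param mat a `score_matrix` from [score_all()] (viruses x hosts).
#' @return Named list, one element per virus: `list(top_hosts = <character
#'   vector>, top_score = <number>)`.
#' @export
predict_hosts <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L)
  if (ncol(mat) < 1L) stop("score matrix has no hosts", call. = FALSE)
  hosts <- colnames(mat)
  out <- lapply(seq_len(nrow(mat)), function(i) {
    s <- mat[i, ]
    m <- max(s)
    list(top_hosts = hosts[s == m], top_score = unname(m))
  })
  stats::setNames(out, rownames(mat))
}

#' Host prediction accuracy at a taxonomic level
#'
#' The percentage of viruses whose predicted host(s) share the level's
#' taxon with any of their known hosts. A virus with a tied prediction set
#' counts as correct if *any* predicted host matches *any* known host at
#' the level; a missing lineage entry (empty/NA) never matches and is
#' reported via a message.
#'
#' @param predictions output of [predict_hosts()].
#' @param truth data frame of known interactions with columns `virus_id`,
#'   `host_id` (one row per known pair); every predicted virus needs at
#'   least one known host.
#' @param taxonomy data frame with column `host_id` plus the six
#'   [TAX_LEVELS] columns (empty string or NA = missing).
#' @param level one of [TAX_LEVELS].
#' @return Accuracy as a percentage in \[0, 100\].
#' @export
accuracy_at_level <- function(predictions, truth, taxonomy, level) {
  if (!level %in% TAX_LEVELS)
    stop("'level' must be one of: ", paste(TAX_LEVELS, collapse = ", "),
         call. = FALSE)
  stopifnot(all(c("virus_id", "host_id") %in% names(truth)),
            all(c("host_id", level) %in% names(taxonomy)))
  vids <- names(predictions)
  known <- split(truth$host_id, truth$virus_id)
  if (!all(vids %in% names(known)))
    stop("no known host for virus: ",
         paste(setdiff(vids, names(known)), collapse = ", "), call. = FALSE)

  lev <- stats::setNames(as.character(taxonomy[[level]]), taxonomy$host_id)
  lev[!is.na(lev) & !nzchar(lev)] <- NA_character_
  n_missing <- 0L

  correct <- vapply(vids, function(v) {
    pred_tax <- lev[predictions[[v]]$top_hosts]
    true_tax <- lev[known[[v]]]
    n_missing <<- n_missing + sum(is.na(pred_tax)) + sum(is.na(true_tax))
    any(!is.na(pred_tax) & pred_tax %in% true_tax[!is.na(true_tax)])
  }, TRUE)
  if (n_missing > 0L)
    message(n_missing, " host(s) without a ", level,
            " annotation treated as non-matching")
  100 * mean(correct)
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen interacting pair outscores a
#' randomly chosen non-interacting pair, with ties counted half
#' (Mann-Whitney formulation; identical to trapezoidal integration of the
#' ROC curve).
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) vector, `TRUE` for interacting pairs.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("roc_auc needs at least one positive and one negative", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (stepwise)
#'
#' Precision and recall are computed at every distinct score threshold
#' (predict interacting when score >= threshold) and the area is the
#' interpolation-free step sum `sum (R_i - R_(i-1)) * P_i` over thresholds
#' in decreasing order. With all scores equal the curve is the single point
#' (recall 1, precision = prevalence), so the area equals the positive
#' prevalence — the floor a random scorer attains on an imbalanced
#' benchmark.
#'
#' @inheritParams roc_auc
#' @return AUPR in \[0, 1\].
#' @export
pr_aupr <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  if (n_pos == 0L) stop("pr_aupr needs at least one positive", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- cumsum(rle(s)$lengths)        # index of last item at each threshold
  tp <- cumsum(y)[last]
  n_at <- last                          # predictions made at each threshold
  prec <- tp / n_at
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' F1-maximizing score threshold
#'
#' Scans every distinct observed score, plus one value above the maximum
#' (the "predict nothing" cut), classifying a pair as interacting when its
#' score >= threshold, and returns the threshold maximizing
#' F1 = 2PR/(P + R). Ties between thresholds are broken toward the higher
#' (more conservative) threshold. Specificity at the chosen cut is reported
#' alongside but never drives the selection.
#'
#' @inheritParams roc_auc
#' @return List with `threshold`, `f1`, `precision`, `recall`,
#'   `specificity`.
#' @export
best_f1_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L)
    stop("best_f1_threshold needs at least one positive", call. = FALSE)

  cand <- sort(unique(scores), decreasing = TRUE)
  cand <- c(cand[1] + 1, cand)          # allow predicting nothing
  best <- list(threshold = cand[1], f1 = -1)
  for (t in cand) {
    pred <- scores >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    rec <- tp / n_pos
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    if (f1 > best$f1)                   # strict: ties keep higher threshold
      best <- list(threshold = t, f1 = f1, precision = prec, recall = rec,
                   specificity = if (n_neg == 0L) NA_real_
                                 else sum(!pred & !labels) / n_neg)
  }
  best
}

#' Full benchmark evaluation of a score matrix
#'
#' Runs the complete protocol: every virus-host pair not in the truth set
#' is a non-interacting negative; AUC, stepwise AUPR and the F1-optimal
#' threshold are computed over all pairs, and top-score host predictions
#' (with tie semantics) are scored for accuracy at each of the six
#' taxonomic levels.
#'
#' @param mat a `score_matrix` (viruses x hosts).
#' @param truth data frame `virus_id`, `host_id` of known pairs (see
#'   [read_truth()]).
#' @param taxonomy data frame `host_id` + six level columns (see
#'   [read_taxonomy()]).
#' @return An `eval_report` list: `auc`, `aupr`, `threshold`, `f1`,
#'   `precision`, `recall`, `specificity`, `accuracy_by_level` (named
#'   percentages), `n_pos`, `n_neg`.
#' @export
evaluate_interactions <- function(mat, truth, taxonomy) {
  stopifnot(is.matrix(mat))
  bad_v <- setdiff(truth$virus_id, rownames(mat))
  bad_h <- setdiff(truth$host_id, colnames(mat))
  if (length(bad_v) || length(bad_h))
    stop("truth refers to ids absent from the score matrix: ",
         paste(c(bad_v, bad_h), collapse = ", "), call. = FALSE)

  pos <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  pos[cbind(match(truth$virus_id, rownames(mat)),
            match(truth$host_id, colnames(mat)))] <- TRUE

  scores <- as.vector(mat); labels <- as.vector(pos)
  thr <- best_f1_threshold(scores, labels)
  preds <- predict_hosts(mat)
  preds <- preds[names(preds) %in% truth$virus_id]
  acc <- vapply(TAX_LEVELS, function(l)
    accuracy_at_level(preds, truth, taxonomy, l), 0)

  structure(list(auc = roc_auc(scores, labels),
                 aupr = pr_aupr(scores, labels),
                 threshold = thr$threshold, f1 = thr$f1,
                 precision = thr$precision, recall = thr$recall,
                 specificity = thr$specificity,
                 accuracy_by_level = acc,
                 n_pos = sum(labels), n_neg = sum(!labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Benchmark evaluation (", x$n_pos, "interacting /", x$n_neg,
      "non-interacting pairs )\n")
  cat(sprintf("  AUC  %.4f   AUPR %.4f\n", x$auc, x$aupr))
  cat(sprintf("  F1-optimal threshold %.6g: F1 %.4f  P %.4f  R %.4f  Sp %.4f\n",
              x$threshold, x$f1, x$precision, x$recall, x$specificity))
  cat("  Accuracy (%):",
      paste(sprintf("%s %.1f", names(x$accuracy_by_level),
                    x$accuracy_by_level), collapse = "  "), "\n")
  invisible(x)
}

#' Write an evaluation report
#'
#' `write_eval_report()` writes the scalar metrics plus per-level
#' accuracies as JSON, and (optionally) the per-level accuracies as a
#' two-column TSV.
#'
#' @param report an `eval_report` from [evaluate_interactions()].
#' @param json_path output JSON file.
#' @param tsv_path optional TSV of per-level accuracies.
#' @return Invisibly, `json_path`.
#' @export
write_eval_report <- function(report, json_path, tsv_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(tsv_path)) {
    df <- data.frame(level = names(report$accuracy_by_level),
                     accuracy_pct = as.numeric(report$accuracy_by_level))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}

#' Read known virus-host interactions
#'
#' Two-column TSV `virus_id <TAB> host_id`, one row per known pair.
#' @param path TSV file.
#' @return Data frame with columns `virus_id`, `host_id` (unique pairs).
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          colClasses = "character", comment.char = "#")
  if (ncol(df) != 2L)
    stop("truth table must have exactly 2 tab-separated columns",
         call. = FALSE)
  names(df) <- c("virus_id", "host_id")
  df$virus_id <- trimws(df$virus_id); df$host_id <- trimws(df$host_id)
  unique(df)
}

#' Read a host taxonomy table
#'
#' Seven-column TSV: `host_id` then the six [TAX_LEVELS] (species first);
#' an empty field means the lineage is missing at that level.
#' @param path TSV file.
#' @return Data frame `host_id` + six level columns.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          colClasses = "character", comment.char = "#")
  if (ncol(df) != 7L)
    stop("taxonomy table must have 7 tab-separated columns (host_id + ",
         paste(TAX_LEVELS, collapse = ", "), ")", call. = FALSE)
  names(df) <- c("host_id", TAX_LEVELS)
  df[] <- lapply(df, trimws)
  df
}
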