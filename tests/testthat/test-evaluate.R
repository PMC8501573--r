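mkmat <- function(rows, vids, hids) {
  m <- matrix(rows, nrow = length(vids), byrow = TRUE,
              dimnames = list(vids, hids))
  structure(m, class = c("score_matrix", class(m)))
}

test_that("predict_hosts returns every host tied at the row maximum", {
  m <- mkmat(c(0.2, 0.9, 0.9,
               0.0, 0.0, 0.0,
               0.5, 0.1, 0.3), c("v1", "v2", "v3"), c("h1", "h2", "h3"))
  p <- predict_hosts(m)
  expect_equal(p$v1$top_hosts, c("h2", "h3"))
  expect_equal(p$v1$top_score, 0.9)
  expect_equal(p$v2$top_hosts, c("h1", "h2", "h3"))  # degenerate all-equal
  expect_equal(p$v2$top_score, 0)
  expect_equal(p$v3$top_hosts, "h1")

  single <- predict_hosts(mkmat(0.5, "v1", "h1"))
  expect_equal(single$v1$top_hosts, "h1")
  expect_error(predict_hosts(m[, 0, drop = FALSE]), "no hosts")
})

test_that("level accuracy counts a virus correct if any tied host matches any known host", {
  tax <- data.frame(host_id = c("h1", "h2", "h3"),
                    species = c("s1", "s2", "s3"),
                    genus = c("gA", "gA", "gB"),
                    family = c("fA", "fA", "fA"),
                    order = c("oA", "oA", "oA"),
                    class = c("cA", "cA", "cA"),
                    phylum = c("pA", "pA", "pA"))
  truth <- data.frame(virus_id = c("v1", "v2"), host_id = c("h3", "h1"))

  # v1 ties h2/h3 and h3 is its true host -> correct at species level;
  # v2 predicts h3 (wrong species, wrong genus, same family)
  m <- mkmat(c(0.1, 0.8, 0.8,
               0.2, 0.2, 0.7), c("v1", "v2"), c("h1", "h2", "h3"))
  preds <- predict_hosts(m)
  expect_equal(accuracy_at_level(preds, truth, tax, "species"), 50)
  expect_equal(accuracy_at_level(preds, truth, tax, "genus"), 50)
  expect_equal(accuracy_at_level(preds, truth, tax, "family"), 100)

  # a single untied exact-host call is correct at species level
  m2 <- mkmat(c(0.9, 0.1, 0.1), "v2", c("h1", "h2", "h3"))
  expect_equal(accuracy_at_level(predict_hosts(m2), truth, tax, "species"),
               100)

  expect_error(accuracy_at_level(preds, truth, tax, "kingdom"), "level")
  expect_error(accuracy_at_level(preds, truth[1, ], tax, "species"), "v2")

  # missing lineage entries never match and are reported
  tax_na <- tax; tax_na$genus[3] <- ""
  m3 <- mkmat(c(0.1, 0.1, 0.9), "v1", c("h1", "h2", "h3"))
  expect_message(
    acc <- accuracy_at_level(predict_hosts(m3), truth, tax_na, "genus"),
    "without a genus")
  expect_equal(acc, 0)
})

test_that("accuracy never increases when narrowing phylum -> species", {
  set.seed(21)
  u <- make_planted_universe(16, 40, pool_size = 60, list_len = 12,
                             noise = 0.4, seed = 99)
  m <- score_all(u$virus_lists, u$host_lists)
  preds <- predict_hosts(m)
  acc <- vapply(TAX_LEVELS, function(l)
    accuracy_at_level(preds, u$truth, u$taxonomy, l), 0)
  expect_true(all(diff(acc) >= 0))   # species first, phylum last
})

test_that("roc_auc equals the exhaustive pairwise win probability", {
  expect_equal(roc_auc(c(0.9, 0.1), c(TRUE, FALSE)), 1)
  expect_equal(roc_auc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)
  expect_error(roc_auc(c(0.5, 0.4), c(TRUE, TRUE)), "negative")

  set.seed(17)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    scores <- round(runif(n), 2)                  # rounded scores force ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels), auc_brute(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with an independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(19)
  scores <- c(runif(30, 0.3, 1), runif(40, 0, 0.7))
  labels <- rep(c(TRUE, FALSE), c(30, 40))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("stepwise AUPR matches hand-enumerated curves", {
  # perfect separation
  expect_equal(pr_aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # all scores equal: the single curve point is (R = 1, P = prevalence)
  expect_equal(pr_aupr(rep(0.5, 10), rep(c(1, 0), c(3, 7))), 0.3)
  # {0.9+, 0.8-, 0.7+}: thresholds 0.9, 0.8, 0.7 give
  # (R, P) = (1/2, 1), (1/2, 1/2), (1, 2/3); step area = 1/2 * 1 + 1/2 * 2/3
  expect_equal(pr_aupr(c(0.9, 0.8, 0.7), c(1, 0, 1)), 0.5 + 0.5 * 2 / 3)
  expect_error(pr_aupr(c(0.5, 0.4), c(0, 0)), "positive")
})

test_that("best_f1_threshold equals an exhaustive threshold scan", {
  # perfectly separated: F1 = 1 at the positive class boundary
  sep <- best_f1_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$f1, 1)
  expect_equal(sep$threshold, 0.8)

  # {0.9+, 0.8+, 0.7-, 0.6+}: cut at 0.6 wins with F1 = 6/7
  hand <- best_f1_threshold(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 1))
  expect_equal(hand$threshold, 0.6)
  expect_equal(hand$f1, 6 / 7)
  expect_equal(hand$precision, 3 / 4)
  expect_equal(hand$recall, 1)
  expect_equal(hand$specificity, 0)

  # P = R = 0.5 at the best cut gives F1 = 0.5 (harmonic mean of equals):
  # cut at 0.8 captures 1 of 2 positives and 1 false positive, and every
  # deeper cut drowns in the 6 negatives
  pr5 <- best_f1_threshold(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2),
                           c(0, 1, 0, 0, 0, 0, 1, 0))
  expect_equal(pr5$f1, 0.5)
  expect_equal(pr5$precision, 0.5)
  expect_equal(pr5$recall, 0.5)
  expect_equal(pr5$threshold, 0.8)

  set.seed(23)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), 2)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels)) next
    got <- best_f1_threshold(scores, labels)
    ref <- f1_brute(scores, labels)
    expect_equal(got$f1, ref$f1, tolerance = 1e-12)
    expect_equal(got$threshold, ref$threshold)
  }
})

test_that("evaluate_interactions assembles a consistent full report", {
  u <- make_planted_universe(10, 30, pool_size = 80, list_len = 10,
                             noise = 0.05, seed = 42)
  m <- score_all(u$virus_lists, u$host_lists)
  rep <- evaluate_interactions(m, u$truth, u$taxonomy)
  expect_s3_class(rep, "eval_report")
  expect_gte(rep$auc, 0.9)               # near-noiseless universe separates
  expect_gte(rep$aupr, 0.8)
  expect_true(all(rep$accuracy_by_level >= 0 & rep$accuracy_by_level <= 100))
  expect_equal(rep$n_pos + rep$n_neg, length(m))
  expect_equal(unname(rep$accuracy_by_level["species"]),
               accuracy_at_level(predict_hosts(m), u$truth, u$taxonomy,
                                 "species"))
  expect_error(evaluate_interactions(m, data.frame(virus_id = "zz",
                                                   host_id = "h1"),
                                     u$taxonomy), "zz")

  f <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(rep, f, ft)
  back <- jsonlite::read_json(f)
  expect_equal(back$auc, rep$auc, tolerance = 1e-12)
  expect_equal(nrow(utils::read.delim(ft)), 6)
})
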