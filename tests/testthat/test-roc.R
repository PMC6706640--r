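# helper: matrix holding given scores for a labelled toy screen
toy_matrix <- function(scores, proteins = "p1",
                       metabolites = sprintf("m%d", seq_along(scores))) {
  build_matrix(data.frame(protein_id = proteins,
                          metabolite_id = metabolites,
                          delta_rf = scores),
               unique(proteins), metabolites)
}

test_that("confusion counts conserve positives and negatives", {
  scores <- c(0.4, 0.2, 0.3, 0.1, 0.05)
  im <- toy_matrix(scores)
  ref <- reference_set(data.frame(protein_id = "p1",
                                  metabolite_id = c("m1", "m2"),
                                  type = "regulatory"))
  cc <- confusion_at_cutoff(im, ref, 0.25)
  expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(1, 1, 2, 1))
  expect_equal(cc$tp + cc$fn, 2)
  expect_equal(cc$fp + cc$tn, 3)
  # degenerate cutoffs
  hi <- confusion_at_cutoff(im, ref, 1)
  expect_equal(c(hi$tp, hi$fp), c(0, 0))
  lo <- confusion_at_cutoff(im, ref, -1)
  expect_equal(c(lo$fn, lo$tn), c(0, 0))
  # reference outside rosters
  bad <- reference_set(data.frame(protein_id = "ghost", metabolite_id = "m1",
                                  type = "catalytic"))
  expect_error(confusion_at_cutoff(im, bad, 0.2), "outside")
})

test_that("missing cells are excluded by default but can count as non-detections", {
  im <- toy_matrix(c(0.4, NA, 0.05))
  ref <- reference_set(data.frame(protein_id = "p1",
                                  metabolite_id = c("m1", "m2"),
                                  type = "regulatory"))
  ex <- confusion_at_cutoff(im, ref, 0.2)
  expect_equal(ex$tp + ex$fn, 1)      # the missing known pair drops out
  expect_equal(ex$n_missing, 1)
  nd <- confusion_at_cutoff(im, ref, 0.2, missing = "nondetect")
  expect_equal(nd$tp + nd$fn, 2)      # counted as an undetected known
  expect_equal(nd$fn, 1)
})

test_that("the ROC matches exhaustive threshold enumeration", {
  scores <- c(0.4, 0.2, 0.3, 0.1, 0.05)
  known <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  im <- toy_matrix(scores)
  ref <- reference_set(data.frame(protein_id = "p1",
                                  metabolite_id = c("m1", "m2"),
                                  type = "regulatory"))
  roc <- roc_curve(im, ref)
  oracle <- brute_roc(scores, known, roc$cutoff)
  expect_equal(roc$tpr, oracle$tpr)
  expect_equal(roc$fpr, oracle$fpr)
  # monotone non-increasing in the cutoff
  expect_true(all(diff(roc$tpr) <= 0))
  expect_true(all(diff(roc$fpr) <= 0))

  # cutoff selection by brute force: smallest cutoff obeying the bound
  sel <- select_cutoff(roc, 0.34)
  expect_equal(sel$cutoff, 0.1)
  expect_equal(sel$tpr, 1)
  expect_equal(sel$fpr, 1 / 3)
  # target 0 forces a cutoff above every unknown-pair score
  sel0 <- select_cutoff(roc, 0)
  expect_true(sel0$cutoff >= 0.3)
  # target 1 admits the minimal candidate cutoff
  sel1 <- select_cutoff(roc, 1)
  expect_equal(sel1$cutoff, min(roc$cutoff))

  # degenerate: all pairs known
  all_known <- reference_set(data.frame(protein_id = "p1",
                                        metabolite_id = sprintf("m%d", 1:5),
                                        type = "regulatory"))
  expect_error(roc_curve(im, all_known), "degenerate")
})

test_that("ROC invariants hold over random score matrices", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 30
    scores <- round(rnorm(n, 0.1, 0.15), 2)  # ties likely
    im <- toy_matrix(scores)
    ref_ids <- sample(sprintf("m%d", 1:n), 8)
    ref <- reference_set(data.frame(protein_id = "p1", metabolite_id = ref_ids,
                                    type = "regulatory"))
    roc <- roc_curve(im, ref)
    expect_true(all(diff(roc$tpr) <= 0))
    expect_true(all(diff(roc$fpr) <= 0))
    cc <- confusion_at_cutoff(im, ref, sample(scores, 1))
    expect_equal(cc$tp + cc$fn, 8)
    expect_equal(cc$fp + cc$tn, n - 8)
  }
})

test_that("AUC equals the rank-statistic on small problems and agrees with pROC", {
  set.seed(55)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    scores <- round(rnorm(n, 0.2, 0.1), 2)
    known <- seq_len(n) %in% sample(n, 4)
    im <- toy_matrix(scores)
    ref <- reference_set(data.frame(protein_id = "p1",
                                    metabolite_id = sprintf("m%d", which(known)),
                                    type = "regulatory"))
    roc <- roc_curve(im, ref)
    # Mann-Whitney count with ties = 1/2, by full enumeration
    pos <- scores[known]; neg <- scores[!known]
    mw <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(roc), mw, tolerance = 1e-12)
    expect_equal(roc_auc(roc),
                 as.numeric(suppressMessages(
                   pROC::auc(pROC::roc(known, scores, direction = "<")))),
                 tolerance = 1e-12)
  }
  # perfect separation
  im <- toy_matrix(c(0.5, 0.4, 0.1, 0.05))
  ref <- reference_set(data.frame(protein_id = "p1",
                                  metabolite_id = c("m1", "m2"),
                                  type = "regulatory"))
  expect_equal(roc_auc(roc_curve(im, ref)), 1)
})

test_that("screen summary arithmetic reproduces itself from headline counts", {
  rs <- recovery_summary(n_proteins = 29, n_metabolites = 55, n_known = 72,
                         n_detected = 98, n_known_detected = 22,
                         n_interacting_metabolites = 28)
  expect_equal(rs$total_pairs, 1595)
  expect_equal(rs$tp + rs$fn, 72)
  expect_equal(rs$fp + rs$tn, 1523)
  expect_equal(rs$tpr, 22 / 72)
  expect_equal(rs$fpr, 76 / 1523)
  expect_equal(rs$n_novel, 76)
  expect_equal(rs$mean_partners_per_interacting_metabolite, 3.5)
})
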