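test_that("binding modes follow the similarity threshold exactly", {
  det <- data.frame(protein_id = c("Pta", "Zwf", "Zwf", "FbaA"),
                    metabolite_id = c("TRP", "ATP", "IMP", "PEP"),
                    delta_rf = c(0.3, 0.25, 0.2, 0.4))
  sim <- data.frame(protein_id = c("Pta", "Zwf", "Zwf"),
                    metabolite_id = c("TRP", "ATP", "IMP"),
                    max_similarity = c(0.06, 0.60, 0.5))
  cl <- classify_binding_mode(det, sim)
  expect_equal(cl$mode,
               c("allosteric_candidate",   # 0.06 < 0.5
                 "competitive_candidate",  # 0.60 >= 0.5
                 "competitive_candidate",  # exactly 0.5 is competitive
                 "unclassified"))          # no similarity available
  s <- attr(cl, "summary")
  # classification partitions the detections
  expect_equal(s$n_allosteric + s$n_competitive + s$n_unclassified, nrow(det))
  expect_equal(s$mean_similarity, mean(c(0.06, 0.60, 0.5)))
})

test_that("classification partition holds over random inputs", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 40
    det <- data.frame(protein_id = sprintf("p%d", sample(5, n, TRUE)),
                      metabolite_id = sprintf("m%d", seq_len(n)))
    have_sim <- runif(n) < 0.8
    sim <- data.frame(protein_id = det$protein_id[have_sim],
                      metabolite_id = det$metabolite_id[have_sim],
                      max_similarity = round(runif(sum(have_sim)), 2))
    cl <- classify_binding_mode(det, sim)
    s <- attr(cl, "summary")
    expect_equal(s$n_allosteric + s$n_competitive + s$n_unclassified, n)
    expect_equal(s$n_unclassified, sum(!have_sim))
  }
})

test_that("pathway summaries count, filter and average correctly", {
  pathways <- data.frame(protein_id = c("e1", "e2", "e3"),
                         pathway = c("tca", "tca", "glycolysis"))
  det <- data.frame(protein_id = c("e1", "e2", "e2", "e2", "e3"),
                    metabolite_id = c("m1", "m1", "m2", "m3", "m1"))
  ps <- pathway_summary(det, pathways)
  expect_equal(ps$per_pathway$mean_detections[ps$per_pathway$pathway == "tca"],
               2)  # (1 + 3) / 2
  # conservation: means times group sizes recover the detection total
  expect_equal(sum(ps$per_pathway$mean_detections * ps$per_pathway$n_proteins),
               nrow(det))

  # purely catalytic knowns are removed; type "both" survives the filter
  ref <- reference_set(data.frame(
    protein_id = c("e1", "e2", "e2"), metabolite_id = c("m1", "m1", "m2"),
    type = c("catalytic", "both", "catalytic")))
  ps2 <- pathway_summary(det, pathways, reference = ref,
                         exclude_catalytic = TRUE)
  # e1 loses its only detection; e2 keeps m1 (both) and m3, drops m2
  expect_equal(ps2$per_protein$n_detections,
               c(0L, 2L, 1L))
  expect_error(pathway_summary(data.frame(protein_id = "ghost",
                                          metabolite_id = "m1"),
                               pathways), "unannotated")
})

test_that("a planted pathway effect is recovered within sampling error", {
  set.seed(99)
  pathways <- data.frame(protein_id = sprintf("e%02d", 1:40),
                         pathway = rep(c("A", "B"), each = 20))
  counts <- c(rpois(20, 1), rpois(20, 3))
  det <- do.call(rbind, lapply(seq_len(40), function(i) {
    k <- counts[i]
    if (k == 0) return(NULL)
    data.frame(protein_id = sprintf("e%02d", i),
               metabolite_id = sprintf("m%d", seq_len(k)))
  }))
  ps <- pathway_summary(det, pathways)
  mA <- ps$per_pathway$mean_detections[ps$per_pathway$pathway == "A"]
  mB <- ps$per_pathway$mean_detections[ps$per_pathway$pathway == "B"]
  expect_lt(abs(mA - 1), 3 * sqrt(1 / 20))
  expect_lt(abs(mB - 3), 3 * sqrt(3 / 20))
  # and the group difference is significant by the unequal-variance t test
  wt <- welch_t_test(ps$per_protein$n_detections[1:20],
                     ps$per_protein$n_detections[21:40])
  expect_lt(wt$p, 0.01)
})

test_that("the unequal-variance t test behaves like its definition", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  wt <- welch_t_test(a, b)
  expect_equal(wt$t, 0)
  expect_equal(wt$p, 1)
  # swapping groups negates t, preserves the two-tailed p
  x <- c(1, 1, 2, 1); y <- c(3, 3, 4, 3)
  expect_equal(welch_t_test(x, y)$t, -welch_t_test(y, x)$t)
  expect_equal(welch_t_test(x, y)$p, welch_t_test(y, x)$p)
  # one-tailed halves the symmetric two-tailed p here
  expect_equal(welch_t_test(x, y, tails = "one")$p,
               welch_t_test(x, y)$p / 2)
  expect_error(welch_t_test(c(1, 1), c(1, 1)), "zero variance")
  expect_error(welch_t_test(1, c(1, 2)), "at least two")
})

test_that("the t test p-value agrees with a permutation oracle", {
  set.seed(123)
  a <- c(1, 0, 2, 1, 1, 0)
  b <- c(3, 4, 2, 5, 3, 4)
  wt <- welch_t_test(a, b)
  pooled <- c(a, b)
  n <- length(a)
  tstat <- function(i) {
    ga <- pooled[i]; gb <- pooled[-i]
    (mean(ga) - mean(gb)) / sqrt(var(ga) / n + var(gb) / length(gb))
  }
  perm <- replicate(10000, tstat(sample(length(pooled), n)))
  p_perm <- mean(abs(perm) >= abs(wt$t))
  expect_lt(abs(wt$p - p_perm), 0.02)
})

test_that("count correlation is the squared Pearson coefficient", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_counts(x, 2 * x + 1), 1)
  # hand-computed five-point case via the covariance formula
  y <- c(2, 1, 4, 3, 7)
  r2_hand <- (sum((x - mean(x)) * (y - mean(y))))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate_counts(x, y), r2_hand)
  set.seed(42)
  xn <- rnorm(2000); yn <- rnorm(2000)
  expect_lt(correlate_counts(xn, yn), 0.01)
  expect_error(correlate_counts(x, c(1, 1, 1, 1, 1)), "zero variance")
  expect_error(correlate_counts(1:2, 1:2), "at least 3")
})
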