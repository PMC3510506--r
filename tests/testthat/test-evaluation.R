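test_that("AUC handles perfect separation, ties and the pair-count case", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  # 2 true (0.9, 0.4), 2 false (0.8, 0.1): 3 of 4 concordant pairs
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.1),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "undefined")
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  set.seed(51)
  for (k in 1:25) {
    n <- sample(6:20, 1)
    scores <- round(rnorm(n), 1)  # coarse values force ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    pos <- scores[labels]; neg <- scores[!labels]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(scores, labels)$auc, mean(pairs))
  }
})

test_that("random scores give AUC centred at one half", {
  set.seed(52)
  aucs <- replicate(1000, {
    roc_auc(rnorm(130), rep(c(TRUE, FALSE), c(30, 100)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("ROC points trace sensitivity against 1-specificity", {
  r <- roc_auc(c(0.9, 0.7, 0.7, 0.2), c(TRUE, FALSE, TRUE, FALSE))$roc
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("AUC significance behaves like a calibrated Z-test", {
  null <- auc_significance(0.5, 30, 70)
  expect_equal(null$z, 0)
  expect_equal(null$p, 1)
  p_seq <- vapply(c(0.55, 0.65, 0.75, 0.9),
                  function(a) auc_significance(a, 30, 70)$p, 0)
  expect_true(all(diff(p_seq) < 0))
  # permutation null comparison on a 30/70 instance
  set.seed(53)
  labels <- rep(c(TRUE, FALSE), c(30, 70))
  scores <- rnorm(100) + 0.8 * labels
  obs <- roc_auc(scores, labels)$auc
  perm <- replicate(1e4, roc_auc(scores, sample(labels))$auc)
  z_perm <- (obs - 0.5) / sd(perm)
  z_hm <- auc_significance(obs, 30, 70)$z
  expect_lt(abs(z_hm - z_perm) / max(abs(z_perm), 0.2), 0.15)
})

test_that("F2 and MCC match hand-computed confusion arithmetic", {
  u <- 10
  truth <- rep(FALSE, u); truth[1:4] <- TRUE
  pred <- rep(FALSE, u); pred[c(1, 2, 3, 5)] <- TRUE
  m <- binary_metrics(pred, truth)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$fn, 1); expect_equal(m$tn, 5)
  expect_equal(m$f2, 15 / 20)
  expect_equal(m$mcc, 14 / sqrt(4 * 4 * 6 * 6))
  perfect <- binary_metrics(truth, truth)
  expect_equal(perfect$f2, 1); expect_equal(perfect$mcc, 1)
  empty <- binary_metrics(rep(FALSE, u), truth)
  expect_equal(empty$f2, 0); expect_equal(empty$mcc, 0)
})

test_that("pooled AUC equals AUC of concatenated per-stage instances", {
  nets <- dcm_infer(bench_samp, cfg = dcm_config(
    n_bootstrap_groups = 25, n_repetitions = 1, seed = 3))
  met <- evaluate_networks(nets, bench_net)
  sc <- c(); lab <- c()
  for (s in 1:4) {
    co <- abs(nets$coefficients[[s]]); off <- row(co) != col(co)
    sc <- c(sc, co[off])
    lab <- c(lab, (bench_net$strengths[[s]] != 0)[off])
  }
  expect_equal(met$auc[met$stage == "overall"], roc_auc(sc, lab)$auc)
})

test_that("enrichment reproduces the 52-gene baseline arithmetic", {
  p <- 52
  genes <- sprintf("g%02d", 1:p)
  pairs <- expand.grid(regulator = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  expect_equal(nrow(pairs), 2652)
  set.seed(54)
  known <- pairs[sample(nrow(pairs), 610), ]
  res <- enrichment(known, known, n_genes = p, directed = TRUE)
  expect_equal(res$universe_size, 2652)
  expect_equal(round(res$baseline, 4), 0.23)
  expect_equal(res$n_hits, 610)
  expect_equal(res$ratio, 1 / res$baseline)
  expect_lt(res$p_value, 1e-10)
  # disjoint prediction: zero ratio, vacuous upper tail
  other <- pairs[!paste(pairs$regulator, pairs$target) %in%
                   paste(known$regulator, known$target), ][1:50, ]
  res0 <- enrichment(other, known, n_genes = p, directed = TRUE)
  expect_equal(res0$ratio, 0)
  expect_equal(stats::phyper(-1, 610, 2042, 50, lower.tail = FALSE), 1)
  expect_error(enrichment(pairs[0, ], known, p), "empty")
})

test_that("hypergeometric tail agrees with Monte-Carlo sampling", {
  set.seed(55)
  n_known <- 40; universe <- 380; n_pred <- 60
  draws <- replicate(1e5, sum(sample(universe, n_pred) <= n_known))
  for (h in c(5, 8, 12)) {
    mc <- mean(draws >= h)
    exact <- stats::phyper(h - 1, n_known, universe - n_known, n_pred,
                           lower.tail = FALSE)
    se <- sqrt(mc * (1 - mc) / 1e5)
    expect_lt(abs(mc - exact), 3 * se + 1e-6)
  }
})

test_that("undirected matching counts either orientation", {
  known <- data.frame(regulator = "a", target = "b")
  pred <- data.frame(regulator = "b", target = "a")
  expect_equal(enrichment(pred, known, 5, directed = FALSE)$n_hits, 1)
  expect_equal(enrichment(pred, known, 5, directed = TRUE)$n_hits, 0)
})
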