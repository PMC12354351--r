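# Ranking metrics against hand examples and brute-force double-loop oracles.

# O(n^2) all-pairs AUC oracle, ties counted 1/2.
auc_loop <- function(scores, pos) {
  s_p <- scores[pos]; s_n <- scores[!pos]
  tot <- 0
  for (a in s_p) for (b in s_n) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s_p) * length(s_n))
}

random_preds <- function(n, V = 20L, max_labels = 4L) {
  lapply(seq_len(n), function(i) {
    ranked_prediction(i, sample.int(V),
                      label_set = sample.int(V, sample.int(max_labels, 1)))
  })
}

test_that("hand-computed examples evaluate exactly", {
  # ranks [1, 2, 4] over three single-label samples
  preds <- list(
    ranked_prediction(1, c(9, 2, 3, 4), label_set = 9),
    ranked_prediction(2, c(1, 9, 3, 4), label_set = 9),
    ranked_prediction(3, c(1, 2, 3, 9), label_set = 9)
  )
  expect_equal(mean_rank(preds), 7 / 3, tolerance = 1e-9)
  expect_equal(mrr(preds), (1 + 1 / 2 + 1 / 4) / 3, tolerance = 1e-9)
  expect_equal(mrr(preds), 0.5833333333, tolerance = 1e-9)
  # labels {a,b,c,d} with {a,b} in the top 10 -> hits@10 = 0.5
  p <- ranked_prediction(4, c(1, 2, 11:28, 3, 4), label_set = 1:4)
  expect_equal(hits_at_k(p, 10), 0.5)
  p2 <- ranked_prediction(5, 1:12, label_set = c(1, 2))
  expect_equal(hits_at_k(p2, 10), 1.0)
  expect_equal(hits_at_k(p2, 12), 1.0)   # k >= vocab size
  # unit hit rate, N = 2: position-1 hit for one sample only
  u <- unit_hit_rate(list(ranked_prediction(1, 1:10, label_set = 1),
                          ranked_prediction(2, 1:10, label_set = 5)), 10)
  expect_equal(unname(u[1]), 0.5)
  expect_equal(unname(u[5]), 0.5)
})

test_that("AUC handles separation, ties and errors as documented", {
  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(auc_score(rep(0.5, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(auc_score(1:3, c(TRUE, TRUE, TRUE)), "positive and one negative")
})

test_that("metrics match brute-force double-loop oracles on random instances", {
  set.seed(77)
  for (trial in 1:150) {
    n <- sample(5:60, 1)
    scores <- round(stats::runif(n), 2)          # rounding forces ties
    pos <- stats::runif(n) > 0.6
    if (!any(pos) || all(pos)) next
    expect_identical(auc_score(scores, pos), auc_loop(scores, pos))

    preds <- random_preds(sample(2:20, 1))
    k <- sample(1:10, 1)
    expect_equal(hits_at_k_mean(preds, k),
                 mean(vapply(preds, function(p)
                   length(intersect(p$label_set,
                                    p$ranked_elements[seq_len(k)])) /
                     length(p$label_set), numeric(1))))
    # per-position loop oracle for the unit hit rate
    u <- unit_hit_rate(preds, 10)
    for (kk in c(1L, 5L, 10L)) {
      hits <- 0
      for (p in preds) hits <- hits + (p$ranked_elements[kk] %in% p$label_set)
      expect_equal(unname(u[kk]), hits / length(preds))
    }
    # mean rank / MRR loop oracle over (sample, label) units
    ranks <- unlist(lapply(preds, function(p) match(p$label_set, p$ranked_elements)))
    expect_equal(mean_rank(preds), mean(ranks))
    expect_equal(mrr(preds), mean(1 / ranks))
  }
})

test_that("hits@k is non-decreasing in k and degrades when a rank worsens", {
  set.seed(5)
  preds <- random_preds(25L)
  h <- vapply(1:15, function(k) hits_at_k_mean(preds, k), numeric(1))
  expect_true(all(diff(h) >= -1e-12))
  # worsening one sample's rank lowers MRR
  p <- list(ranked_prediction(1, 1:10, label_set = 2))
  p_bad <- list(ranked_prediction(1, c(1, 3, 4, 2, 5:10), label_set = 2))
  expect_lt(mrr(p_bad), mrr(p))
})

test_that("uniform random rankings give unit hit rate near 1/V per position", {
  set.seed(99)
  V <- 12L
  preds <- lapply(seq_len(10000L), function(i)
    ranked_prediction(i, sample.int(V), label_set = sample.int(V, 1)))
  u <- unit_hit_rate(preds, 10)
  expect_true(all(abs(u - 1 / V) < 3 * sqrt((1 / V) * (1 - 1 / V) / 10000)))
})

test_that("labels absent from a ranking get the flagged worst rank", {
  p <- ranked_prediction(1, 1:10, label_set = c(2L, 42L))
  expect_warning(r <- mean_rank(list(p)), "absent from the ranking")
  expect_equal(r, (2 + 11) / 2)
})

test_that("a perfect model yields the metric floor/ceiling and hits_avg identity", {
  s <- tiny_setup(seed = 31L)
  preds <- oracle_predictions(s$spec, s$split$test, s$vocabs)
  # replace each ranking by one that puts the true labels first
  perfect <- lapply(preds, function(p) {
    rest <- setdiff(p$ranked_elements, p$label_set)
    ranked_prediction(p$sample_id, c(p$label_set, rest), label_set = p$label_set)
  })
  expect_equal(hits_at_k_mean(perfect, 10), 1.0)
  expect_equal(mean(vapply(perfect, function(p) min(match(p$label_set, p$ranked_elements)),
                           numeric(1))), 1.0)
  expect_equal(mrr(perfect, unit = "best"), 1.0)
  rep <- metric_report(perfect)
  expect_equal(rep$hits_avg, mean(rep$unit_hit_rate[1:3]), tolerance = 1e-12)
})

test_that("evaluate_ranking agrees with recomputation from its own rankings", {
  s <- tiny_setup(seed = 33L)
  m <- build_model(s$vocabs, s$config, kind = "mlp", prior = s$prior)
  rep <- evaluate_ranking(m, s$split$test)
  preds <- predict_ranking(m, s$split$test)
  expect_equal(rep$hits_at_10, hits_at_k_mean(preds, 10))
  expect_equal(rep$mean_rank, mean_rank(preds))
  expect_equal(rep$mrr, mrr(preds))
  expect_equal(rep$hits_avg, mean(rep$unit_hit_rate[1:3]))
  expect_equal(unname(rep$unit_hit_rate), unname(unit_hit_rate(preds, 10)))
})

test_that("the paired bootstrap utility reports sane difference summaries", {
  set.seed(3)
  a <- stats::rnorm(40, mean = 0.6, sd = 0.05)
  b <- a - 0.2
  out <- paired_bootstrap(a, b, n_boot = 500L, seed = 4L)
  expect_equal(out$mean_diff, mean(a - b))
  expect_lt(out$p_value, 0.05)
  same <- paired_bootstrap(a, a + stats::rnorm(40, 0, 1e-3), n_boot = 500L, seed = 4L)
  expect_gt(same$p_value, 0.05)
})
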