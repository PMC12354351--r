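# The planted-corpus generator and the Bayes-optimal ranking oracle.

test_that("generation is deterministic and respects the spec invariants", {
  spec <- synthetic_spec(n_symptoms = 15L, n_elements = 12L, n_scenes = 2L,
                         n_diseases = 4L, seed = 3L)
  for (g in seq_len(spec$n_scenes))
    expect_true(all(abs(rowSums(spec$conditional[[g]]) - 1) < 1e-9))
  expect_length(spec$category_of, 12L)
  expect_true(all(spec$category_of %in% c("a", "b", "c", "d", "e")))

  g1 <- generate_corpus(spec, 50L, seed = 4L)
  g2 <- generate_corpus(spec, 50L, seed = 4L)
  expect_identical(g1$cases, g2$cases)
  g3 <- generate_corpus(spec, 50L, seed = 5L)
  expect_false(identical(g1$cases, g3$cases))

  for (cs in g1$cases) {
    expect_gte(length(cs$symptoms), min(spec$symptoms_per_case))
    expect_lte(length(cs$symptoms), max(spec$symptoms_per_case))
    expect_gte(length(cs$elements), min(spec$elements_per_case))
    expect_lte(length(cs$elements), max(spec$elements_per_case))
    expect_identical(anyDuplicated(cs$elements), 0L)
    expect_identical(cs$element_categories,
                     spec$category_of[match(cs$elements, spec$element_tokens)])
  }
  # n_cases = 0: empty corpus, spec retained
  g0 <- generate_corpus(spec, 0L, seed = 1L)
  expect_length(g0$cases, 0L)
  expect_identical(g0$spec, spec)
})

test_that("an invalid spec is rejected before any generation", {
  spec <- synthetic_spec(n_symptoms = 5L, n_elements = 8L, n_scenes = 1L, seed = 1L)
  spec$conditional[[1]][1, ] <- 2 * spec$conditional[[1]][1, ]
  expect_error(generate_corpus(spec, 10L, seed = 1L), "sum to 1")
  spec2 <- synthetic_spec(n_symptoms = 5L, n_elements = 8L, n_scenes = 2L, seed = 1L)
  spec2$conditional <- spec2$conditional[1]
  expect_error(generate_corpus(spec2, 10L, seed = 1L), "one conditional table")
})

test_that("a point-mass conditional is always expressed in generated cases", {
  spec <- synthetic_spec(n_symptoms = 8L, n_elements = 10L, n_scenes = 1L,
                         n_diseases = 3L, symptoms_per_case = 2:3,
                         elements_per_case = 3:5, seed = 6L)
  s_star <- 4L; e_star <- 7L
  for (g in seq_len(spec$n_scenes)) {
    spec$conditional[[g]][s_star, ] <- 0
    spec$conditional[[g]][s_star, e_star] <- 1
  }
  gc <- generate_corpus(spec, 400L, seed = 7L)
  tok_s <- spec$symptom_tokens[[s_star]]; tok_e <- spec$element_tokens[[e_star]]
  with_s <- Filter(function(cs) tok_s %in% cs$symptoms, gc$cases)
  expect_gt(length(with_s), 10L)
  for (cs in with_s) expect_true(tok_e %in% cs$elements)
})

test_that("empirical statistics recover the planted conditionals as n grows", {
  spec <- synthetic_spec(n_symptoms = 10L, n_elements = 12L, n_scenes = 1L,
                         n_diseases = 3L, symptoms_per_case = 1L,
                         elements_per_case = 1L, sharpness = 2,
                         scene_heterogeneity = 0, seed = 8L)
  err_at <- function(n) {
    gc <- generate_corpus(spec, n, seed = 9L)
    st <- build_association_stats(gc$cases)
    s_tok <- spec$symptom_tokens[[2L]]
    e_idx <- which.max(spec$conditional[[1]][2L, ])
    abs(rule_confidence(st, s_tok, spec$element_tokens[[e_idx]]) -
          spec$conditional[[1]][2L, e_idx])
  }
  e1k <- err_at(1000L); e10k <- err_at(10000L)
  expect_lt(e10k, 0.03)
  # error shrinks roughly like 1/sqrt(n): allow generous slack
  expect_lt(e10k, max(e1k * 1.5, 0.02))
})

test_that("the Bayes oracle ranks by the planted mixture", {
  spec <- synthetic_spec(n_symptoms = 6L, n_elements = 9L, n_scenes = 2L,
                         n_diseases = 3L, seed = 10L)
  # single symptom: ranking equals that symptom's conditional row sorted desc
  r <- bayes_optimal_ranking(spec, spec$symptom_tokens[[3L]], "dept_2")
  row <- spec$conditional[[2]][3L, ]
  expect_identical(r$ranked_ids, order(-row, seq_along(row), method = "radix"))
  # two symptoms with identical rows: same ranking as either alone
  spec$conditional[[1]][2L, ] <- spec$conditional[[1]][1L, ]
  r1 <- bayes_optimal_ranking(spec, spec$symptom_tokens[[1L]], 1L)
  r12 <- bayes_optimal_ranking(spec, spec$symptom_tokens[1:2], 1L)
  expect_identical(r1$ranked_ids, r12$ranked_ids)
  # unknown symptom contributes uniformly, flagged
  expect_warning(ru <- bayes_optimal_ranking(spec, c(spec$symptom_tokens[[1L]],
                                                     "nope"), 1L),
                 "unknown symptom")
  expect_length(ru$ranked_ids, spec$n_elements)
  expect_error(bayes_optimal_ranking(spec, spec$symptom_tokens[[1L]], "dept_9"),
               "unknown scene")
})

test_that("scene-aware oracles beat scene-blind oracles under heterogeneity", {
  spec <- synthetic_spec(n_symptoms = 25L, n_elements = 18L, n_scenes = 4L,
                         n_diseases = 5L, scene_heterogeneity = 1,
                         sharpness = 3, seed = 11L)
  gc <- generate_corpus(spec, 600L, seed = 12L)
  vb <- build_vocabularies(gc$cases)
  orc <- oracle_predictions(spec, gc$cases, vb)
  blind_spec <- spec
  avgP <- Reduce(`+`, spec$conditional) / spec$n_scenes
  for (g in seq_len(spec$n_scenes)) blind_spec$conditional[[g]] <- avgP
  blind <- oracle_predictions(blind_spec, gc$cases, vb)
  expect_gt(hits_at_k_mean(orc, 10), hits_at_k_mean(blind, 10))
})
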