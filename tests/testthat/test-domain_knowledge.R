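# Sexagenary calendar, age-gender staging, diagnosis labels, symptom priors.

# Published sexagenary anchors used as an independent oracle: year, stem,
# branch (standard cycle, 1984 = Jia-Zi).
SEXAGENARY_ANCHORS <- data.frame(
  year = c(1984L, 1985L, 1924L, 2044L, 1900L, 1911L, 1949L, 2000L, 2023L, 1864L),
  stem = c("Jia", "Yi", "Jia", "Jia", "Geng", "Xin", "Ji", "Geng", "Gui", "Jia"),
  branch = c("Zi", "Chou", "Zi", "Zi", "Zi", "Hai", "Chou", "Chen", "Mao", "Zi"),
  stringsAsFactors = FALSE
)

test_that("stem-branch assignment matches the published cycle", {
  for (i in seq_len(nrow(SEXAGENARY_ANCHORS))) {
    p <- stem_branch_features(sprintf("%d-06-15", SEXAGENARY_ANCHORS$year[i]))
    expect_identical(p$year_stem, SEXAGENARY_ANCHORS$stem[i],
                     label = paste("stem", SEXAGENARY_ANCHORS$year[i]))
    expect_identical(p$year_branch, SEXAGENARY_ANCHORS$branch[i])
  }
  p84 <- stem_branch_features("1984-03-01")
  expect_identical(p84$stem_element, "wood")
  expect_identical(p84$fortune_polarity, "excess")
  p85 <- stem_branch_features("1985-03-01")
  expect_identical(p85$stem_element, "wood")
  expect_identical(p85$fortune_polarity, "deficit")
})

test_that("stem/branch repeat with period 60 over 120 consecutive years", {
  for (y in 1900:1959) {
    a <- stem_branch_features(sprintf("%d-01-15", y))
    b <- stem_branch_features(sprintf("%d-01-15", y + 60L))
    expect_identical(a$year_stem, b$year_stem)
    expect_identical(a$year_branch, b$year_branch)
    expect_identical(a$stem_element, b$stem_element)
  }
  # within the window, consecutive years never share a stem-branch pair
  pairs <- vapply(1900:1959, function(y) {
    p <- stem_branch_features(sprintf("%d-01-15", y))
    paste(p$year_stem, p$year_branch)
  }, character(1))
  expect_identical(anyDuplicated(pairs), 0L)
})

test_that("missing or out-of-range birth dates are handled explicitly", {
  p <- stem_branch_features(NA)
  expect_true(p$missing)
  expect_true(is.na(p$year_stem))
  expect_error(stem_branch_features("1700-01-01"), "out of supported range")
})

test_that("age-gender codes reproduce all four printed anchors", {
  expect_identical(age_gender_code("female", 5L)$code, "001")
  expect_identical(age_gender_code("female", 8L)$code, "002")
  expect_identical(age_gender_code("male", 5L)$code, "101")
  expect_identical(age_gender_code("male", 10L)$code, "102")
  # boundaries of the seven/eight-year stages
  expect_identical(age_gender_code("female", 0L)$stage, 1L)
  expect_identical(age_gender_code("female", 7L)$stage, 1L)
  expect_identical(age_gender_code("female", 14L)$stage, 2L)
  expect_identical(age_gender_code("male", 8L)$stage, 1L)
  expect_identical(age_gender_code("male", 9L)$stage, 2L)
  expect_identical(age_gender_code("male", 16L)$stage, 2L)
  expect_warning(capped <- age_gender_code("female", 120L), "capping")
  expect_identical(capped$stage, 13L)
  expect_error(age_gender_code("male", -1L), "non-negative")
})

test_that("diagnosis labels use the configured dictionaries and refuse to guess", {
  cfg <- default_knowledge_config()
  cfg$acute_diseases <- c("flu")
  cfg$chronic_diseases <- c("diabetes")
  expect_identical(diagnosis_labels("flu", config = cfg)$acute_chronic, 0L)
  expect_identical(diagnosis_labels("diabetes", config = cfg)$acute_chronic, 1L)
  expect_identical(diagnosis_labels("mystery", config = cfg)$acute_chronic,
                   "unlabeled")
  cfg$western_classes <- list(endocrine = c("diabetes"))
  expect_identical(diagnosis_labels("x", "diabetes", cfg)$western_class,
                   "endocrine")
})

test_that("knowledge config files merge over the defaults", {
  tmp <- tempfile(fileext = ".yml")
  yaml::write_yaml(list(acute_diseases = c("only-this"), top_m = 7L), tmp)
  cfg <- load_knowledge_config(tmp)
  expect_identical(cfg$acute_diseases, "only-this")
  expect_identical(cfg$top_m, 7L)
  expect_identical(cfg$chronic_diseases,
                   default_knowledge_config()$chronic_diseases)
})

test_that("symptom priors rank by pair count with the documented tie-break", {
  st <- build_association_stats(fixture_corpus())
  v <- build_vocabularies(fixture_corpus())
  pr <- symptom_prior_features("white moss", st, top_m = 1L,
                               category_of = v$element_category_of)
  p <- pr$priors[["white moss"]]
  # all seven co-elements tie at count 1; C-locale order puts "Wei" first
  expect_identical(p$common_elements, "Wei")
  expect_identical(p$common_element_freq, 1L)
  expect_identical(p$common_element_category, "a")
  # top_m beyond the distinct co-elements returns all, no padding
  pr2 <- symptom_prior_features("white moss", st, top_m = 50L)
  expect_length(pr2$priors[["white moss"]]$common_elements, 7L)
  # unseen symptom -> empty prior, flagged
  pr3 <- symptom_prior_features("no-such", st, top_m = 2L)
  expect_identical(pr3$unseen, "no-such")
  expect_length(pr3$priors[["no-such"]]$common_elements, 0L)
})

test_that("priors are invariant under corpus permutation", {
  cs <- random_corpus(20L, seed = 21L)
  st1 <- build_association_stats(cs)
  st2 <- build_association_stats(structure(rev(cs), class = "tcm_corpus"))
  s <- cs[[1]]$symptoms[[1]]
  p1 <- symptom_prior_features(s, st1, top_m = 3L)$priors[[s]]
  p2 <- symptom_prior_features(s, st2, top_m = 3L)$priors[[s]]
  expect_identical(p1, p2)
})

test_that("derived features are pure functions of their inputs", {
  expect_identical(stem_branch_features("1962-03-14"),
                   stem_branch_features("1962-03-14"))
  expect_identical(age_gender_code("male", 53L), age_gender_code("male", 53L))
})
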