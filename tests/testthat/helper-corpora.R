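# Shared test fixtures, built in code.

fixture_corpus <- function() example_cases()

# A small random corpus with the same record shape as the packaged fixture;
# tokens are synthetic identifiers. Used by brute-force oracle comparisons.
random_corpus <- function(n_cases, n_symptoms = 12L, n_elements = 8L,
                          seed = 1L) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sym <- sprintf("sym%02d", seq_len(n_symptoms))
  ele <- sprintf("ele%02d", seq_len(n_elements))
  cats <- sample(c("a", "b", "c", "d", "e"), n_elements, replace = TRUE)
  cases <- lapply(seq_len(n_cases), function(i) {
    s <- sample(sym, sample(2:5, 1))
    e <- sample(ele, sample(2:4, 1))
    list(case_id = sprintf("r%04d", i), physician = "dr", department = "dept",
         patient_sex = sample(c("female", "male"), 1),
         birth_date = as.Date("1980-01-01"), age_years = 41L,
         consult_date = as.Date("2021-06-01"), consult_season = "summer",
         symptoms = s, syndrome = "syn", elements = e,
         element_categories = cats[match(e, ele)], disease_name = "dis")
  })
  structure(cases, class = "tcm_corpus")
}

# Brute-force single-pass scan oracle for the association statistics:
# independent of the package implementation (plain loops over raw lists).
scan_count_pair <- function(cases, a, b) {
  sum(vapply(cases, function(cs) a %in% cs$symptoms && b %in% cs$elements,
             logical(1)))
}
scan_count_any <- function(cases, a) {
  sum(vapply(cases, function(cs)
    a %in% cs$symptoms && length(cs$elements) > 0, logical(1)))
}
scan_count_itemset <- function(cases, items) {
  if (length(items) == 0L) return(length(cases))
  sum(vapply(cases, function(cs)
    all(items %in% c(cs$symptoms, cs$elements)), logical(1)))
}
scan_doc_freq <- function(cases, tok) {
  sum(vapply(cases, function(cs)
    tok %in% c(cs$symptoms, cs$elements), logical(1)))
}

# A tiny synthetic training setup shared by network/training tests.
tiny_setup <- function(seed = 2L, n_cases = 60L) {
  spec <- synthetic_spec(n_symptoms = 20L, n_elements = 15L, n_scenes = 3L,
                         n_diseases = 5L, symptoms_per_case = 3:5,
                         elements_per_case = 3:6, seed = seed)
  gc <- generate_corpus(spec, n_cases, seed = seed + 1L)
  sp <- split_dataset(gc$cases, 0.2, seed = seed + 2L)
  vb <- build_vocabularies(sp$train)
  st <- build_association_stats(sp$train)
  pr <- prior_feature_matrix(vb, st)
  cfg <- model_config(embed_dim = 8L, n_heads = 2L, expert_dim = 12L,
                      meta_dim = 4L, tower_dim = 12L, tower_depth = 2L,
                      senet_hidden = 4L, seed = seed + 3L)
  list(spec = spec, split = sp, vocabs = vb, stats = st, prior = pr,
       config = cfg)
}
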