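# Synthetic TCM-like case corpora with planted symptom-to-element structure.
#
# Generative model per case: draw a scene (department), demographics, and a
# symptom set; elements are drawn from the scene's symptom-conditional
# distributions -- first one draw per symptom from that symptom's own row
# (so a point-mass conditional is always expressed when the target element
# count allows it), then top-up draws without replacement from the uniform
# mixture of the case's symptom rows until the target element count is
# reached. The ground-truth spec is retained alongside the corpus, enabling
# parameter-recovery tests and the Bayes-optimal ranking oracle.

#' Specification of a synthetic corpus
#'
#' Defines vocabulary sizes, the five-way element category partition, the
#' per-scene conditional tables P(element | symptom), per-case size
#' distributions and demographic samplers.
#'
#' Conditional tables are built as row-softmaxes of
#' `sharpness * ((1 - scene_heterogeneity) * base + scene_heterogeneity *
#' scene_deviation)` with standard-normal base and deviation logits:
#' `scene_heterogeneity = 0` gives identical tables in every scene, `1`
#' independent tables (maximally scene-specific). `sharpness` concentrates
#' the rows.
#'
#' @param n_symptoms,n_elements,n_diseases,n_scenes vocabulary sizes.
#' @param category_props proportions of elements in categories a-e;
#'   default weighted toward c (disease evil) and d (pathological state).
#' @param symptoms_per_case,integers sampled uniformly for the per-case
#'   symptom count (default 3..9).
#' @param elements_per_case target per-case element count (default 3..8).
#' @param sharpness conditional-row concentration (default 3).
#' @param scene_heterogeneity in \[0, 1\]; how different the per-scene
#'   tables are (default 0.5).
#' @param birth_years range of birth years sampled uniformly.
#' @param seed seed for the planted tables.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_symptoms = 500L, n_elements = 150L,
                           n_diseases = 20L, n_scenes = 5L,
                           category_props = c(a = 0.2, b = 0.15, c = 0.25,
                                              d = 0.3, e = 0.1),
                           symptoms_per_case = 3:9,
                           elements_per_case = 3:8,
                           sharpness = 3, scene_heterogeneity = 0.5,
                           birth_years = c(1940L, 2005L), seed = 1L) {
  stopifnot(n_symptoms >= 1, n_elements >= max(elements_per_case),
            n_scenes >= 1, length(category_props) == 5,
            scene_heterogeneity >= 0, scene_heterogeneity <= 1)
  props <- category_props / sum(category_props)
  bounds <- round(cumsum(props) * n_elements)
  sizes <- diff(c(0L, bounds))
  category_of <- rep(CATEGORY_CODES, times = sizes)

  wd <- max(3L, nchar(as.character(n_symptoms)))
  we <- max(3L, nchar(as.character(n_elements)))
  spec <- with_seed(seed, {
    base <- matrix(stats::rnorm(n_symptoms * n_elements), n_symptoms, n_elements)
    conditional <- lapply(seq_len(n_scenes), function(g) {
      dev <- matrix(stats::rnorm(n_symptoms * n_elements), n_symptoms, n_elements)
      logits <- sharpness * ((1 - scene_heterogeneity) * base +
                               scene_heterogeneity * dev)
      softmax_rows(logits)
    })
    list(conditional = conditional)
  })

  structure(list(
    n_symptoms = as.integer(n_symptoms), n_elements = as.integer(n_elements),
    n_diseases = as.integer(n_diseases), n_scenes = as.integer(n_scenes),
    symptom_tokens = sprintf(paste0("s%0", wd, "d"), seq_len(n_symptoms)),
    element_tokens = sprintf(paste0("e%0", we, "d"), seq_len(n_elements)),
    disease_tokens = sprintf("disease_%02d", seq_len(n_diseases)),
    scene_tokens = sprintf("dept_%d", seq_len(n_scenes)),
    category_of = category_of,
    conditional = spec$conditional,
    scene_probs = rep(1 / n_scenes, n_scenes),
    symptoms_per_case = as.integer(symptoms_per_case),
    elements_per_case = as.integer(elements_per_case),
    sharpness = sharpness, scene_heterogeneity = scene_heterogeneity,
    birth_years = as.integer(birth_years), seed = as.integer(seed)
  ), class = "synthetic_spec")
}

validate_spec <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(spec$conditional) != spec$n_scenes)
    stop("spec invalid: need one conditional table per scene")
  for (g in seq_len(spec$n_scenes)) {
    P <- spec$conditional[[g]]
    if (!all(dim(P) == c(spec$n_symptoms, spec$n_elements)))
      stop("spec invalid: conditional table ", g, " has wrong dimensions")
    if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
      stop("spec invalid: conditional table ", g,
           " rows must be nonnegative and sum to 1")
  }
  if (length(spec$category_of) != spec$n_elements ||
      !all(spec$category_of %in% CATEGORY_CODES))
    stop("spec invalid: category partition must cover all elements with codes a-e")
  invisible(spec)
}

month_season <- function(m) {
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[m]
}

#' Generate a synthetic corpus
#'
#' Deterministic given (spec, n_cases, seed). See the package vignette for
#' the generative model; the planted spec is retained in the result for
#' oracle evaluation.
#'
#' @param spec a `synthetic_spec`.
#' @param n_cases number of cases (0 allowed).
#' @param seed RNG seed.
#' @return a `generated_corpus`: list with `cases` (a `tcm_corpus`) and
#'   `spec`.
#' @export
generate_corpus <- function(spec, n_cases, seed) {
  validate_spec(spec)
  cases <- with_seed(seed, lapply(seq_len(n_cases), function(i) generate_case(spec, i)))
  structure(list(cases = structure(cases, class = "tcm_corpus"), spec = spec),
            class = "generated_corpus")
}

generate_case <- function(spec, i) {
  g <- sample.int(spec$n_scenes, 1L, prob = spec$scene_probs)
  P <- spec$conditional[[g]]
  m_s <- if (length(spec$symptoms_per_case) == 1L) spec$symptoms_per_case
         else sample(spec$symptoms_per_case, 1L)
  m_s <- min(m_s, spec$n_symptoms)
  sym <- sample.int(spec$n_symptoms, m_s)
  m_e <- if (length(spec$elements_per_case) == 1L) spec$elements_per_case
         else sample(spec$elements_per_case, 1L)

  # one draw per symptom from its own conditional row, then mixture top-up
  seeds <- unique(vapply(sym, function(s)
    sample.int(spec$n_elements, 1L, prob = P[s, ]), integer(1)))
  ele <- if (length(seeds) > m_e) sample(seeds, m_e) else seeds
  if (length(ele) < m_e) {
    mix <- colMeans(P[sym, , drop = FALSE])
    mix[ele] <- 0
    extra <- sample.int(spec$n_elements, m_e - length(ele), prob = mix)
    ele <- c(ele, extra)
  }

  sex <- sample(c("female", "male"), 1L)
  by <- sample(spec$birth_years[1]:spec$birth_years[2], 1L)
  bm <- sample.int(12L, 1L); bd <- sample.int(28L, 1L)
  cm <- sample.int(12L, 1L); cd <- sample.int(28L, 1L)
  list(
    case_id = sprintf("syn%06d", i),
    physician = sprintf("dr_%d", sample.int(8L, 1L)),
    department = spec$scene_tokens[[g]],
    patient_sex = sex,
    birth_date = as.Date(sprintf("%04d-%02d-%02d", by, bm, bd)),
    age_years = 2021L - by,
    consult_date = as.Date(sprintf("2021-%02d-%02d", cm, cd)),
    consult_season = month_season(cm),
    symptoms = spec$symptom_tokens[sym],
    syndrome = paste(spec$element_tokens[ele], collapse = " "),
    elements = spec$element_tokens[ele],
    element_categories = spec$category_of[ele],
    disease_name = spec$disease_tokens[[sample.int(spec$n_diseases, 1L)]]
  )
}

#' @export
print.generated_corpus <- function(x, ...) {
  cat("<generated_corpus> ", length(x$cases), " cases; ",
      x$spec$n_symptoms, " symptoms, ", x$spec$n_elements, " elements, ",
      x$spec$n_scenes, " scenes (heterogeneity ",
      x$spec$scene_heterogeneity, ")\n", sep = "")
  invisible(x)
}

#' Bayes-optimal element ranking under the planted model
#'
#' Ranks all elements by their true mixture probability given the case's
#' symptom set and scene: the mean of the scene's conditional rows over the
#' case's symptoms. Unknown symptoms contribute a uniform row (flagged).
#' This is the performance ceiling for any model trained on corpora drawn
#' from the same planted distributions.
#'
#' @param spec a `synthetic_spec`.
#' @param symptom_set character vector of symptom tokens.
#' @param scene scene token (e.g. `"dept_1"`) or 1-based scene index.
#' @return list with `scores` (named by element token, in mixture-probability
#'   order), `ranked_tokens`, `ranked_ids` (spec element indices).
#' @export
bayes_optimal_ranking <- function(spec, symptom_set, scene) {
  g <- if (is.character(scene)) match(scene, spec$scene_tokens) else as.integer(scene)
  if (is.na(g) || g < 1L || g > spec$n_scenes) stop("unknown scene: ", scene)
  sid <- match(symptom_set, spec$symptom_tokens)
  if (anyNA(sid)) {
    warning(sum(is.na(sid)), " unknown symptom(s); contributing uniform rows")
  }
  rows <- lapply(sid, function(s) {
    if (is.na(s)) rep(1 / spec$n_elements, spec$n_elements)
    else spec$conditional[[g]][s, ]
  })
  p <- Reduce(`+`, rows) / length(rows)
  ord <- order(-p, seq_along(p), method = "radix")
  list(scores = stats::setNames(p[ord], spec$element_tokens[ord]),
       ranked_tokens = spec$element_tokens[ord],
       ranked_ids = ord)
}

#' Oracle ranked predictions for generated cases
#'
#' Applies [bayes_optimal_ranking()] to each case and expresses the ranking
#' in a model vocabulary's element ids so the result is directly comparable
#' with [predict_ranking()] under the same metrics. Elements absent from
#' the vocabulary are dropped from the ranking; labels unknown to the
#' vocabulary are dropped from the label set.
#'
#' @param spec a `synthetic_spec`.
#' @param cases list of generated case records.
#' @param vocabs a `tcm_vocab` (e.g. built from the training split).
#' @return list of `ranked_prediction`.
#' @export
oracle_predictions <- function(spec, cases, vocabs) {
  lapply(cases, function(cs) {
    r <- bayes_optimal_ranking(spec, cs$symptoms, cs$department)
    ids <- token_ids(vocabs$element_vocab, r$ranked_tokens)
    keep <- ids > 0L
    labs <- token_ids(vocabs$element_vocab, cs$elements)
    ranked_prediction(cs$case_id, ids[keep],
                      unname(r$scores)[keep], labs[labs > 0L])
  })
}
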