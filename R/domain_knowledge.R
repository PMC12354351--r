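# TCM domain-knowledge features derived from demographics, dates and
# diagnoses: sexagenary (stem-branch) calendar features with five-element
# correspondences, female-seven/male-eight age-gender stage codes,
# acute/chronic diagnosis labels, and per-symptom common-element priors.
#
# All tables here are data, not claims: they encode the standard doctrine
# correspondences and are overridable through the knowledge config.

HEAVENLY_STEMS <- c("Jia", "Yi", "Bing", "Ding", "Wu", "Ji",
                    "Geng", "Xin", "Ren", "Gui")
EARTHLY_BRANCHES <- c("Zi", "Chou", "Yin", "Mao", "Chen", "Si",
                      "Wu", "Wei", "Shen", "You", "Xu", "Hai")
FIVE_ELEMENTS <- c("wood", "fire", "earth", "metal", "water")

# canonical stem -> element pairing (two stems per element, in cycle order)
STEM_ELEMENT <- c(Jia = "wood", Yi = "wood", Bing = "fire", Ding = "fire",
                  Wu = "earth", Ji = "earth", Geng = "metal", Xin = "metal",
                  Ren = "water", Gui = "water")
# canonical branch -> element pairing
BRANCH_ELEMENT <- c(Zi = "water", Chou = "earth", Yin = "wood", Mao = "wood",
                    Chen = "earth", Si = "fire", Wu = "fire", Wei = "earth",
                    Shen = "metal", You = "metal", Xu = "earth", Hai = "water")

#' Default knowledge configuration
#'
#' Returns the default configuration consumed by the domain-knowledge
#' features: the stem-to-element table, acute/chronic disease dictionaries,
#' the constitution lookup keyed by (year stem, birth month), and the number
#' of prior elements per symptom (`top_m`). Any entry can be overridden by
#' supplying a YAML/JSON file to [load_knowledge_config()].
#'
#' The constitution lookup is a coarse default: the innate constitution is
#' taken as the stem's element, shifted one step along the generative cycle
#' for months 7-12. The doctrine source gives no algorithm for this
#' projection, so the table is explicitly configuration, not doctrine.
#'
#' @return named list of configuration tables.
#' @export
default_knowledge_config <- function() {
  gen_cycle <- c(wood = "fire", fire = "earth", earth = "metal",
                 metal = "water", water = "wood")
  constitution <- list()
  for (st in HEAVENLY_STEMS) {
    el <- STEM_ELEMENT[[st]]
    constitution[[st]] <- c(rep(el, 6L), rep(gen_cycle[[el]], 6L))  # months 1..12
  }
  list(
    stem_element = STEM_ELEMENT,
    branch_element = BRANCH_ELEMENT,
    acute_diseases = c("Vomiting", "Stomach ache"),
    chronic_diseases = c("Cataract", "Tachycardia", "Liver accumulation"),
    tcm_disease_list = c("Stomach ache", "Vomiting", "Liver accumulation",
                         "Tachycardia", "Cataract"),
    western_classes = list(),
    constitution_lookup = constitution,
    top_m = 3L
  )
}

#' Load a knowledge configuration file
#'
#' Reads a YAML or JSON file and merges it over
#' [default_knowledge_config()]: keys present in the file replace the
#' defaults, absent keys keep them.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return merged configuration list.
#' @export
load_knowledge_config <- function(path) {
  stopifnot(file.exists(path))
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_knowledge_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg
}

#' Sexagenary-calendar features of a birth date
#'
#' Assigns the Heavenly Stem and Earthly Branch of the Gregorian birth year
#' (standard 60-year cycle anchored at 1984 = Jia-Zi, so stem index =
#' (year - 4) mod 10 and branch index = (year - 4) mod 12), the five-element
#' correspondence of each, the year-fortune polarity (excess for yang stems
#' -- even stem index -- deficit for yin stems), the birth month, and the
#' configured innate-constitution lookup value. The Gregorian year boundary
#' is used throughout; no lunar-calendar conversion is attempted, a known
#' simplification for January/February births.
#'
#' @param birth_date a `Date` (or string `"YYYY-MM-DD"`); NA allowed.
#' @param config knowledge configuration, see [default_knowledge_config()].
#' @return a `stem_branch_profile` list with `year_stem`, `year_branch`,
#'   `stem_element`, `branch_element`, `fortune_polarity`, `birth_month`,
#'   `constitution`; all-NA (flagged) when the date is missing.
#' @export
stem_branch_features <- function(birth_date, config = default_knowledge_config()) {
  if (!inherits(birth_date, "Date")) birth_date <- parse_date_or_na(as.character(birth_date))
  if (is.na(birth_date)) {
    return(structure(list(year_stem = NA_character_, year_branch = NA_character_,
                          stem_element = NA_character_, branch_element = NA_character_,
                          fortune_polarity = NA_character_, birth_month = NA_integer_,
                          constitution = NA_character_, missing = TRUE),
                     class = "stem_branch_profile"))
  }
  year <- as.integer(format(birth_date, "%Y"))
  if (year < 1850L) stop("birth year ", year, " out of supported range (>= 1850)")
  month <- as.integer(format(birth_date, "%m"))
  si <- (year - 4L) %% 10L          # 0-based stem index; even = yang
  bi <- (year - 4L) %% 12L
  stem <- HEAVENLY_STEMS[[si + 1L]]
  branch <- EARTHLY_BRANCHES[[bi + 1L]]
  structure(list(
    year_stem = stem,
    year_branch = branch,
    stem_element = unname(config$stem_element[[stem]]),
    branch_element = unname(config$branch_element[[branch]]),
    fortune_polarity = if (si %% 2L == 0L) "excess" else "deficit",
    birth_month = month,
    constitution = unname(config$constitution_lookup[[stem]][[month]]),
    missing = FALSE
  ), class = "stem_branch_profile")
}

#' Age-gender stage code (female-seven / male-eight doctrine)
#'
#' Encodes sex and life stage as a 3-character code: sex prefix (0 female,
#' 1 male) followed by the zero-padded stage number. Female stages advance
#' every 7 years and male stages every 8, with age 0 folded into stage 1:
#' stage = floor((age - 1) / width) + 1 for age >= 1. This reproduces the
#' canonical anchors 001 = female 0-7, 002 = female 8-14, 101 = male 0-8,
#' 102 = male 9-16. Stages are capped at 13 (with a warning).
#'
#' @param sex `"female"` or `"male"`.
#' @param age_years non-negative integer age.
#' @return an `age_gender_code` list with `code`, `sex_prefix`, `stage`.
#' @export
age_gender_code <- function(sex, age_years) {
  sex <- match.arg(sex, c("female", "male"))
  if (is.na(age_years) || age_years < 0) stop("age_years must be non-negative")
  width <- if (sex == "female") 7L else 8L
  stage <- if (age_years == 0) 1L else (age_years - 1L) %/% width + 1L
  if (stage > 13L) {
    warning("age ", age_years, " exceeds stage 13; capping")
    stage <- 13L
  }
  prefix <- if (sex == "female") 0L else 1L
  structure(list(code = sprintf("%d%02d", prefix, stage),
                 sex_prefix = prefix, stage = stage),
            class = "age_gender_code")
}

#' Diagnosis-derived labels
#'
#' Maps a TCM and/or Western diagnosis to: an acute/chronic flag (0 acute,
#' 1 chronic, `"unlabeled"` when in neither configured list), membership in
#' the configured TCM disease list, and the Western classification bucket.
#' Unknown names are reported as `"unlabeled"`, never guessed.
#'
#' @param tcm_diagnosis TCM disease name (NA allowed).
#' @param western_diagnosis Western disease name (NA allowed).
#' @param config knowledge configuration.
#' @return list with `acute_chronic` (0, 1 or "unlabeled"),
#'   `in_tcm_disease_list` (logical), `western_class` (string or "unlabeled").
#' @export
diagnosis_labels <- function(tcm_diagnosis, western_diagnosis = NA,
                             config = default_knowledge_config()) {
  name_in <- function(x, lst) !is.na(x) && x %in% lst
  acute_chronic <-
    if (name_in(tcm_diagnosis, config$acute_diseases) ||
        name_in(western_diagnosis, config$acute_diseases)) 0L
    else if (name_in(tcm_diagnosis, config$chronic_diseases) ||
             name_in(western_diagnosis, config$chronic_diseases)) 1L
    else "unlabeled"
  wc <- "unlabeled"
  if (!is.na(western_diagnosis) && length(config$western_classes)) {
    for (cls in names(config$western_classes)) {
      if (western_diagnosis %in% config$western_classes[[cls]]) { wc <- cls; break }
    }
  }
  list(acute_chronic = acute_chronic,
       in_tcm_disease_list = name_in(tcm_diagnosis, config$tcm_disease_list),
       western_class = wc)
}

#' Common-element priors for a symptom list
#'
#' For every input symptom, the `top_m` elements most often co-occurring
#' with it (by presence-based pair count), ties broken by C-locale
#' lexicographic token order; each with its count and category code. A
#' symptom unseen in the statistics yields an empty prior and is flagged.
#'
#' @param symptoms character vector of symptom tokens.
#' @param stats an `assoc_stats` from [build_association_stats()].
#' @param top_m maximum number of prior elements per symptom (>= 1).
#' @param category_of optional named map element token -> category code
#'   (e.g. `vocabs$element_category_of`); NA categories where absent.
#' @return a `symptom_prior`: per symptom, a list with `common_elements`
#'   (ranked tokens), `common_element_freq` (counts) and
#'   `common_element_category`; plus `unseen` listing flagged symptoms.
#' @export
symptom_prior_features <- function(symptoms, stats, top_m = 3L, category_of = NULL) {
  stopifnot(top_m >= 1L)
  pair_names <- names(stats$pair_count)
  parts <- strsplit(pair_names, PAIR_SEP, fixed = TRUE)
  pair_sym <- vapply(parts, `[[`, character(1), 1L)
  pair_ele <- vapply(parts, `[[`, character(1), 2L)

  unseen <- character(0)
  priors <- list()
  for (s in unique(symptoms)) {
    sel <- pair_sym == s
    if (!any(sel)) {
      unseen <- c(unseen, s)
      priors[[s]] <- list(common_elements = character(0),
                          common_element_freq = integer(0),
                          common_element_category = character(0))
      next
    }
    ele <- pair_ele[sel]
    cnt <- as.integer(stats$pair_count[sel])
    ord <- order(-cnt, ele, method = "radix")
    keep <- utils::head(ord, top_m)
    cats <- if (is.null(category_of)) rep(NA_character_, length(keep))
            else unname(category_of[ele[keep]])
    priors[[s]] <- list(common_elements = ele[keep],
                        common_element_freq = cnt[keep],
                        common_element_category = cats)
  }
  structure(list(priors = priors, unseen = unseen, top_m = as.integer(top_m)),
            class = "symptom_prior")
}

#' @export
print.symptom_prior <- function(x, ...) {
  cat("<symptom_prior> ", length(x$priors), " symptoms (top_m = ", x$top_m, ")",
      if (length(x$unseen)) paste0("; ", length(x$unseen), " unseen") else "",
      "\n", sep = "")
  invisible(x)
}
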