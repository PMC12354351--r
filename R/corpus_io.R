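# Reading, validating, splitting and serializing tokenized TCM case records.
#
# A corpus is a list of case records. Each record is a named list with the
# fields documented in `read_cases()`. Multi-token fields (symptoms, elements,
# element_categories) are stored as character vectors; scalar fields that are
# absent in the input are kept as NA, never dropped.

CASE_FIELDS <- c(
  "case_id", "physician", "department", "patient_sex", "birth_date",
  "age_years", "consult_date", "consult_season", "symptoms", "syndrome",
  "elements", "element_categories", "disease_name"
)

MULTI_FIELDS <- c("symptoms", "elements", "element_categories")
CATEGORY_CODES <- c("a", "b", "c", "d", "e")
SEASONS <- c("spring", "summer", "autumn", "winter")

#' Split a multi-token field on commas
#'
#' Fields such as symptom lists are delimited by an ASCII comma or the Chinese
#' enumeration comma; tokens are trimmed of surrounding whitespace. Internal
#' spaces are preserved (a token may be a multi-word phrase).
#'
#' @param x character scalar (or NA).
#' @return character vector of tokens; `character(0)` for NA/empty input.
#' @keywords internal
split_tokens <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(trimws(x))) return(character(0))
  toks <- trimws(strsplit(x, "[,，、]")[[1]])
  toks[nzchar(toks)]
}

join_tokens <- function(x) paste(x, collapse = ", ")

parse_date_or_na <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(x)) return(as.Date(NA))
  d <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
  d
}

#' Read tokenized TCM case records
#'
#' Reads a corpus of consultation records from either a tab-separated file
#' with a header row, or a JSON-lines file (one JSON object per line). The
#' documented schema has one row per consultation with the columns
#' `case_id, physician, department, patient_sex, birth_date, age_years,
#' consult_date, consult_season, symptoms, syndrome, elements,
#' element_categories, disease_name`. In the delimited dialect the
#' multi-token columns hold comma-separated token lists; in JSON-lines they
#' may be JSON arrays or comma-separated strings.
#'
#' Validation enforced per row: `symptoms` nonempty; `elements` nonempty when
#' `require_elements` is TRUE (training corpora); every category code one of
#' a--e; `age_years` consistent with `birth_date`/`consult_date` within one
#' year when all are present (a violation warns and keeps the stated age).
#' A malformed row fails with an error naming the row number and field.
#'
#' @param path file path.
#' @param dialect `"delimited"` (TSV) or `"json_lines"`.
#' @param require_elements require a nonempty element list per record.
#' @return a `tcm_corpus`: list of case records.
#' @export
read_cases <- function(path, dialect = c("delimited", "json_lines"),
                       require_elements = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("case file does not exist: ", path)
  rows <- switch(dialect,
    delimited = {
      tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                               colClasses = "character", check.names = FALSE,
                               quote = "", na.strings = c("NA", ""),
                               fileEncoding = "UTF-8")
      missing_cols <- setdiff(CASE_FIELDS, names(tab))
      if (length(missing_cols))
        stop("case file is missing columns: ", paste(missing_cols, collapse = ", "))
      lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, CASE_FIELDS]))
    },
    json_lines = {
      lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      lapply(seq_along(lines), function(i) {
        obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                        error = function(e)
                          stop("malformed JSON on line ", i, ": ", conditionMessage(e)))
        obj
      })
    })
  if (length(rows) == 0L) stop("empty file: ", path, " has a header but no case rows")

  cases <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    cases[[i]] <- validate_case(build_case(rows[[i]]), row = i,
                                require_elements = require_elements)
  }
  structure(cases, class = "tcm_corpus")
}

# Coerce one raw row (list of scalars/vectors) into a case record.
build_case <- function(row) {
  get <- function(f) if (!is.null(row[[f]])) row[[f]] else NA
  multi <- function(f) {
    v <- row[[f]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) return(character(0))
    if (length(v) > 1L) return(trimws(as.character(v)))
    split_tokens(as.character(v))
  }
  age <- suppressWarnings(as.integer(get("age_years")))
  list(
    case_id = as.character(get("case_id")),
    physician = as.character(get("physician")),
    department = as.character(get("department")),
    patient_sex = as.character(get("patient_sex")),
    birth_date = parse_date_or_na(as.character(get("birth_date"))),
    age_years = age,
    consult_date = parse_date_or_na(as.character(get("consult_date"))),
    consult_season = as.character(get("consult_season")),
    symptoms = multi("symptoms"),
    syndrome = as.character(get("syndrome")),
    elements = multi("elements"),
    element_categories = multi("element_categories"),
    disease_name = as.character(get("disease_name"))
  )
}

validate_case <- function(case, row, require_elements = TRUE) {
  if (length(case$symptoms) == 0L)
    stop("malformed row ", row, ": field 'symptoms' is empty")
  if (require_elements && length(case$elements) == 0L)
    stop("malformed row ", row, ": field 'elements' is empty")
  bad <- setdiff(case$element_categories, CATEGORY_CODES)
  if (length(bad))
    stop("malformed row ", row, ": field 'element_categories' has invalid code(s) ",
         paste(sQuote(bad), collapse = ", "), " (allowed: a-e)")
  if (!is.na(case$patient_sex) && !case$patient_sex %in% c("female", "male"))
    stop("malformed row ", row, ": field 'patient_sex' must be female/male, got ",
         sQuote(case$patient_sex))
  if (!is.na(case$consult_season) && !case$consult_season %in% SEASONS)
    stop("malformed row ", row, ": field 'consult_season' must be one of ",
         paste(SEASONS, collapse = "/"))
  if (!is.na(case$age_years) && case$age_years < 0L)
    stop("malformed row ", row, ": field 'age_years' is negative")
  if (!is.na(case$age_years) && !is.na(case$birth_date) && !is.na(case$consult_date)) {
    implied <- floor(as.numeric(difftime(case$consult_date, case$birth_date,
                                         units = "days")) / 365.2425)
    if (abs(implied - case$age_years) > 1L)
      warning("row ", row, ": age_years (", case$age_years,
              ") inconsistent with dates (implied ", implied, "); keeping stated age")
  }
  case
}

#' Write a corpus back to disk
#'
#' Inverse of [read_cases()]; reading the written file reproduces the corpus
#' record-by-record.
#'
#' @param cases a `tcm_corpus`.
#' @param path output path.
#' @param dialect `"delimited"` or `"json_lines"`.
#' @export
write_cases <- function(cases, path, dialect = c("delimited", "json_lines")) {
  dialect <- match.arg(dialect)
  fmt <- function(x) {
    if (inherits(x, "Date")) return(ifelse(is.na(x), NA_character_, format(x, "%Y-%m-%d")))
    as.character(x)
  }
  if (dialect == "delimited") {
    tab <- do.call(rbind, lapply(cases, function(cs) {
      vapply(CASE_FIELDS, function(f) {
        v <- cs[[f]]
        if (f %in% MULTI_FIELDS) join_tokens(v) else fmt(v)
      }, character(1))
    }))
    colnames(tab) <- CASE_FIELDS
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8", na = "NA")
  } else {
    lines <- vapply(cases, function(cs) {
      obj <- cs
      obj$birth_date <- fmt(cs$birth_date)
      obj$consult_date <- fmt(cs$consult_date)
      jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", na = "null")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Load the packaged six-case example corpus
#'
#' A small corpus of tokenized consultations (symptoms, syndrome string,
#' evidence elements and their five-way category codes, disease name) used
#' throughout the package's examples and exact-count tests. The demographic
#' columns (physician, department, dates, ages) are synthetic placeholders;
#' note that one row carries four elements but only three category codes and
#' another repeats an element token with two different codes -- both kept
#' as-is to exercise the alignment fallback in [build_vocabularies()].
#'
#' @return a `tcm_corpus` of 6 records.
#' @export
example_cases <- function() {
  read_cases(system.file("extdata", "sample_cases.tsv", package = "tcmrec"),
             dialect = "delimited")
}

#' @export
print.tcm_corpus <- function(x, ...) {
  cat("<tcm_corpus> ", length(x), " case records\n", sep = "")
  if (length(x)) {
    ns <- vapply(x, function(cs) length(cs$symptoms), integer(1))
    ne <- vapply(x, function(cs) length(cs$elements), integer(1))
    cat("  symptoms/case: ", min(ns), "-", max(ns),
        "; elements/case: ", min(ne), "-", max(ne), "\n", sep = "")
  }
  invisible(x)
}

# ---- vocabularies -----------------------------------------------------------

UNK_TOKEN <- "<unk>"

# Deterministic token ordering: frequency descending, ties by C-locale
# lexicographic order (radix sort, locale independent).
order_tokens <- function(counts) {
  toks <- names(counts)
  ord <- order(-as.integer(counts), toks, method = "radix")
  toks[ord]
}

make_vocab <- function(tokens_by_case, min_count) {
  counts <- table(unlist(tokens_by_case, use.names = FALSE))
  keep <- counts[counts >= min_count]
  toks <- if (length(keep)) order_tokens(keep) else character(0)
  ids <- seq_along(toks)           # id 0 reserved for <unk>/padding
  names(ids) <- toks
  list(tokens = c(UNK_TOKEN, toks), ids = ids)
}

#' Build token vocabularies from a corpus
#'
#' Assigns dense integer ids to symptom, element, disease and scene tokens.
#' Id 0 is reserved in every vocabulary for padding/unknown; remaining ids
#' are assigned deterministically by corpus frequency (descending), ties
#' broken by C-locale lexicographic order. Tokens seen fewer than `min_count`
#' times map to the unknown id.
#'
#' Element categories: when a record's element and category lists have equal
#' length they are aligned positionally; records where the lengths differ are
#' excluded from category evidence and flagged. Each element's category is
#' the majority vote over aligned occurrences (ties by first code in a-e
#' order); elements with no aligned evidence get NA. Flags are attached as
#' `attr(, "category_flags")`.
#'
#' @param cases a `tcm_corpus`.
#' @param min_count minimum corpus frequency; below it a token maps to id 0.
#' @param scene_field which categorical field is the scene vocabulary:
#'   `"department"` (default) or `"consult_season"`.
#' @return a `tcm_vocab` with `symptom_vocab`, `element_vocab`,
#'   `disease_vocab`, `scene_vocab` (each `$tokens`, `$ids`) and
#'   `element_category_of` (named character vector, element token -> code).
#' @export
build_vocabularies <- function(cases, min_count = 1L,
                               scene_field = c("department", "consult_season")) {
  scene_field <- match.arg(scene_field)
  stopifnot(length(cases) > 0L, min_count >= 1L)

  sym_v <- make_vocab(lapply(cases, function(cs) unique(cs$symptoms)), min_count)
  ele_v <- make_vocab(lapply(cases, function(cs) unique(cs$elements)), min_count)
  dis_v <- make_vocab(lapply(cases, function(cs) cs$disease_name), min_count)
  scn_v <- make_vocab(lapply(cases, function(cs) cs[[scene_field]]), 1L)
  if (length(sym_v$ids) == 0L)
    stop("all symptom tokens fall below min_count = ", min_count)
  if (length(ele_v$ids) == 0L)
    stop("all element tokens fall below min_count = ", min_count)

  # per-element category votes from length-consistent rows
  votes <- list()
  flagged_rows <- integer(0)
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    if (length(cs$element_categories) == 0L) next
    if (length(cs$elements) != length(cs$element_categories)) {
      flagged_rows <- c(flagged_rows, i)
      next
    }
    for (j in seq_along(cs$elements)) {
      e <- cs$elements[[j]]
      votes[[e]] <- c(votes[[e]], cs$element_categories[[j]])
    }
  }
  cat_of <- rep(NA_character_, length(ele_v$tokens))
  names(cat_of) <- ele_v$tokens
  conflicted <- character(0)
  for (e in names(votes)) {
    if (!e %in% names(cat_of)) next
    tab <- table(factor(votes[[e]], levels = CATEGORY_CODES))
    if (length(unique(votes[[e]])) > 1L) conflicted <- c(conflicted, e)
    cat_of[[e]] <- CATEGORY_CODES[[which.max(tab)]]   # majority; tie -> first in a-e
  }

  structure(
    list(symptom_vocab = sym_v, element_vocab = ele_v,
         disease_vocab = dis_v, scene_vocab = scn_v,
         scene_field = scene_field,
         element_category_of = cat_of),
    category_flags = list(misaligned_rows = flagged_rows, conflicted_elements = conflicted),
    class = "tcm_vocab")
}

#' Map tokens to vocabulary ids (0 for unknown)
#' @param vocab one sub-vocabulary (e.g. `vocabs$symptom_vocab`).
#' @param tokens character vector.
#' @return integer ids, 0 where the token is absent.
#' @export
token_ids <- function(vocab, tokens) {
  ids <- unname(vocab$ids[tokens])
  ids[is.na(ids)] <- 0L
  as.integer(ids)
}

#' Map vocabulary ids back to tokens
#' @param vocab one sub-vocabulary.
#' @param ids integer ids (0 = unknown token).
#' @return character tokens.
#' @export
id_tokens <- function(vocab, ids) vocab$tokens[ids + 1L]

#' Number of real tokens in a sub-vocabulary (excluding the reserved id 0)
#' @param vocab one sub-vocabulary.
#' @export
vocab_size <- function(vocab) length(vocab$ids)

#' @export
print.tcm_vocab <- function(x, ...) {
  cat("<tcm_vocab> symptoms:", vocab_size(x$symptom_vocab),
      " elements:", vocab_size(x$element_vocab),
      " diseases:", vocab_size(x$disease_vocab),
      " scenes:", vocab_size(x$scene_vocab),
      " (scene =", x$scene_field, ")\n")
  invisible(x)
}

# ---- train/test split -------------------------------------------------------

#' Split a corpus into train and test sets
#'
#' Membership is a deterministic function of the corpus size, fraction and
#' seed; the test size is `round(n * test_fraction)` (within one record of
#' the requested fraction), clamped so both sides are nonempty.
#'
#' @param cases a `tcm_corpus`.
#' @param test_fraction proportion in (0, 1) held out for testing.
#' @param seed integer RNG seed.
#' @return a `tcm_split` with `$train`, `$test` (both `tcm_corpus`) and
#'   `$split_seed`.
#' @export
split_dataset <- function(cases, test_fraction, seed) {
  n <- length(cases)
  if (n < 2L) stop("need at least 2 records to split, got ", n)
  stopifnot(test_fraction > 0, test_fraction < 1)
  n_test <- max(1L, min(n - 1L, as.integer(round(n * test_fraction))))
  idx <- with_seed(seed, sample.int(n, n_test))
  structure(list(
    train = structure(cases[-idx], class = "tcm_corpus"),
    test = structure(cases[sort(idx)], class = "tcm_corpus"),
    split_seed = as.integer(seed)
  ), class = "tcm_split")
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- feature store ----------------------------------------------------------

FEATURE_STORE_VERSION <- "1.0"

# Lightweight corpus fingerprint for the store manifest (not cryptographic).
corpus_fingerprint <- function(cases) {
  s <- paste(vapply(cases, function(cs)
    paste(cs$case_id, join_tokens(cs$symptoms), join_tokens(cs$elements), sep = "|"),
    character(1)), collapse = "\n")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

#' Serialize computed features to a schema-versioned store
#'
#' Writes a directory containing `manifest.json` (schema version, corpus
#' fingerprint, creation time, object index) and one JSON file per feature
#' object. Objects that carry a class (e.g. `assoc_stats`) round-trip
#' through registered encoders; plain named lists of atomic vectors
#' round-trip as-is. Loading verifies the schema version and fails loudly on
#' mismatch or corruption rather than returning a partial store.
#'
#' @param features named list of feature objects.
#' @param path directory to create/overwrite.
#' @param corpus optional `tcm_corpus` used to stamp a fingerprint.
#' @return `path`, invisibly.
#' @export
serialize_feature_store <- function(features, path, corpus = NULL) {
  stopifnot(is.list(features), !is.null(names(features)), all(nzchar(names(features))))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    schema_version = FEATURE_STORE_VERSION,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    corpus_hash = if (is.null(corpus)) NA else corpus_fingerprint(corpus),
    objects = as.list(vapply(features, function(x) class(x)[[1]], character(1)))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, null = "null", na = "null", digits = NA)
  for (nm in names(features)) {
    jsonlite::write_json(encode_feature(features[[nm]]),
                         file.path(path, paste0(nm, ".json")),
                         auto_unbox = FALSE, null = "null", na = "null", digits = NA)
  }
  invisible(path)
}

#' @rdname serialize_feature_store
#' @export
load_feature_store <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("not a feature store (no manifest.json): ", path)
  manifest <- tryCatch(jsonlite::read_json(mf_path, simplifyVector = FALSE),
                       error = function(e) stop("corrupted feature store manifest: ",
                                                conditionMessage(e)))
  if (!identical(manifest$schema_version, FEATURE_STORE_VERSION))
    stop("feature store schema version mismatch: store has ",
         manifest$schema_version %||% "<none>", ", this package reads ",
         FEATURE_STORE_VERSION)
  out <- list()
  for (nm in names(manifest$objects)) {
    fp <- file.path(path, paste0(nm, ".json"))
    raw <- tryCatch(jsonlite::read_json(fp, simplifyVector = FALSE),
                    error = function(e) stop("corrupted feature store object '", nm,
                                             "': ", conditionMessage(e)))
    out[[nm]] <- decode_feature(raw)
  }
  attr(out, "manifest") <- manifest
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# JSON-safe encoding: atomic vectors become {type, names, values}; lists
# recurse; a class tag rides along so decode restores structure exactly.
encode_feature <- function(x) {
  if (is.null(x)) return(list(kind = "null"))
  if (is.atomic(x)) {
    list(kind = "atomic", type = typeof(x),
         names = if (is.null(names(x))) NULL else as.list(names(x)),
         values = as.list(unname(x)))
  } else if (is.list(x)) {
    list(kind = "list", class = class(x),
         names = if (is.null(names(x))) NULL else as.list(names(x)),
         items = lapply(unname(x), encode_feature))
  } else stop("cannot encode feature of type ", typeof(x))
}

decode_feature <- function(x) {
  kind <- x$kind[[1]]
  if (identical(kind, "null")) return(NULL)
  if (identical(kind, "atomic")) {
    vals <- x$values
    v <- switch(x$type[[1]],
      integer = vapply(vals, function(z) if (is.null(z)) NA_integer_ else as.integer(z), integer(1)),
      double = vapply(vals, function(z) if (is.null(z)) NA_real_ else as.numeric(z), numeric(1)),
      character = vapply(vals, function(z) if (is.null(z)) NA_character_ else as.character(z), character(1)),
      logical = vapply(vals, function(z) if (is.null(z)) NA else as.logical(z), logical(1)),
      stop("unsupported atomic type ", x$type[[1]]))
    if (!is.null(x$names)) names(v) <- unlist(x$names)
    v
  } else if (identical(kind, "list")) {
    v <- lapply(x$items, decode_feature)
    if (!is.null(x$names)) names(v) <- unlist(x$names)
    cls <- unlist(x$class)
    if (!identical(cls, "list")) class(v) <- cls
    v
  } else stop("corrupted feature store object: unknown kind ", kind)
}
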