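# Symptom-element association statistics.
#
# All pair/document counts are presence-based: a token (or token pair)
# contributes at most once per case. Raw occurrence multiplicity is retained
# only for term frequency, whose documents are per-case element lists by
# default. Natural log is used for IDF; the base is a constant factor and
# preserves ordering.

PAIR_SEP <- "\x01"  # unit separator: cannot occur inside a trimmed token

#' Build association statistics from a corpus
#'
#' Single pass over the corpus collecting every count needed by the
#' co-occurrence, confidence, support and TF-IDF statistics: the number of
#' cases `n_cases`; presence-based symptom-element pair counts; per-symptom
#' counts of cases containing the symptom together with at least one element;
#' document frequencies (cases containing a token, over symptoms and
#' elements); and per-case term-frequency documents with multiplicity.
#' Per-case token sets are retained so arbitrary itemset counts can be
#' answered by [count_itemset()].
#'
#' @param cases a `tcm_corpus`.
#' @param tf_field which field forms the term-frequency documents:
#'   `"elements"` (default) or `"symptoms"`.
#' @return an `assoc_stats` object.
#' @export
build_association_stats <- function(cases, tf_field = c("elements", "symptoms")) {
  tf_field <- match.arg(tf_field)
  stopifnot(length(cases) > 0L)
  n <- length(cases)

  sym_sets <- lapply(cases, function(cs) unique(cs$symptoms))
  ele_sets <- lapply(cases, function(cs) unique(cs$elements))
  tf_docs <- lapply(cases, function(cs) cs[[tf_field]])   # multiplicity kept
  case_ids <- vapply(cases, function(cs) cs$case_id, character(1))

  # presence-based pair counts: for each case, all (symptom, element) pairs once
  pair_keys <- unlist(lapply(seq_len(n), function(i) {
    s <- sym_sets[[i]]; e <- ele_sets[[i]]
    if (!length(s) || !length(e)) return(character(0))
    as.vector(outer(s, e, function(a, b) paste(a, b, sep = PAIR_SEP)))
  }), use.names = FALSE)
  pair_count <- as_count_vec(table(pair_keys))

  has_any_element <- vapply(ele_sets, function(e) length(e) > 0L, logical(1))
  symptom_any_count <- as_count_vec(table(unlist(sym_sets[has_any_element],
                                                 use.names = FALSE)))

  union_sets <- lapply(seq_len(n), function(i) unique(c(sym_sets[[i]], ele_sets[[i]])))
  doc_freq <- as_count_vec(table(unlist(union_sets, use.names = FALSE)))

  totals <- vapply(tf_docs, length, integer(1))
  names(totals) <- case_ids

  structure(list(
    n_cases = n,
    pair_count = pair_count,
    symptom_any_count = symptom_any_count,
    doc_freq = doc_freq,
    case_token_totals = totals,
    case_ids = case_ids,
    symptom_sets = sym_sets,
    element_sets = ele_sets,
    tf_docs = tf_docs,
    tf_field = tf_field
  ), class = "assoc_stats")
}

as_count_vec <- function(tab) {
  v <- as.integer(tab)
  names(v) <- names(tab)
  v
}

# `[[` on a named vector errors for absent keys; guard via match
lookup0 <- function(vec, key) {
  i <- match(key, names(vec))
  if (is.na(i)) 0L else as.integer(vec[[i]])
}

#' @export
print.assoc_stats <- function(x, ...) {
  cat("<assoc_stats> ", x$n_cases, " cases, ",
      length(x$pair_count), " symptom-element pairs, ",
      length(x$doc_freq), " distinct tokens (tf over ", x$tf_field, ")\n", sep = "")
  invisible(x)
}

#' Count cases containing an itemset
#'
#' Number of cases whose combined symptom and element token set contains
#' every item in `items`. The empty itemset is contained in every case.
#'
#' @param stats an `assoc_stats`.
#' @param items character vector of tokens (possibly empty).
#' @return integer count.
#' @export
count_itemset <- function(stats, items) {
  items <- unique(items)
  if (length(items) == 0L) return(stats$n_cases)
  sum(vapply(seq_len(stats$n_cases), function(i) {
    all(items %in% c(stats$symptom_sets[[i]], stats$element_sets[[i]]))
  }, logical(1)))
}

#' Co-occurrence probability of an element given a symptom
#'
#' The number of cases in which symptom `a` and element `b` appear together,
#' divided by the number of cases in which `a` appears together with at
#' least one element. Returns 0 (with a warning) when the denominator is 0,
#' including for tokens never seen in the corpus.
#'
#' @param stats an `assoc_stats`.
#' @param a symptom token.
#' @param b element token.
#' @return probability in \[0, 1\].
#' @export
cooccurrence_probability <- function(stats, a, b) {
  denom <- lookup0(stats$symptom_any_count, a)
  if (denom == 0L) {
    warning("symptom ", sQuote(a), " never co-occurs with any element; returning 0")
    return(0)
  }
  lookup0(stats$pair_count, paste(a, b, sep = PAIR_SEP)) / denom
}

#' Confidence of the association rule A => B
#'
#' `count(A and B together) / count(A)` over cases. Returns 0 with a warning
#' when the antecedent never occurs.
#'
#' @param stats an `assoc_stats`.
#' @param A nonempty antecedent itemset (character vector of tokens).
#' @param B consequent itemset.
#' @return value in \[0, 1\].
#' @export
rule_confidence <- function(stats, A, B) {
  stopifnot(length(A) > 0L)
  nA <- count_itemset(stats, A)
  if (nA == 0L) {
    warning("antecedent {", paste(A, collapse = ", "), "} occurs in no case; returning 0")
    return(0)
  }
  count_itemset(stats, c(A, B)) / nA
}

#' Support of the association rule A => B
#'
#' Fraction of all cases containing both itemsets:
#' `count(A and B together) / n_cases`. With both itemsets empty this is 1.
#'
#' @inheritParams rule_confidence
#' @param A antecedent itemset (may be empty).
#' @return value in \[0, 1\].
#' @export
rule_support <- function(stats, A, B) {
  count_itemset(stats, c(A, B)) / stats$n_cases
}

#' Term frequency of a token within one case's document
#'
#' Occurrences of `token` in the case's term-frequency document (the element
#' list by default) divided by the document length, with multiplicity.
#' An empty document gives 0 with a warning.
#'
#' @param stats an `assoc_stats`.
#' @param token token.
#' @param case_id case identifier.
#' @return value in \[0, 1\].
#' @export
term_frequency <- function(stats, token, case_id) {
  i <- match(case_id, stats$case_ids)
  if (is.na(i)) stop("unknown case_id: ", case_id)
  doc <- stats$tf_docs[[i]]
  if (length(doc) == 0L) {
    warning("case ", case_id, " has an empty ", stats$tf_field, " document; tf = 0")
    return(0)
  }
  sum(doc == token) / length(doc)
}

#' Inverse document frequency of a token
#'
#' `log(N / (n_i + 1))` with the natural log, where `N` is the corpus size
#' and `n_i` the number of cases containing the token. The add-one
#' denominator is kept as defined, so a token present in every case yields a
#' small negative value.
#'
#' @param stats an `assoc_stats`.
#' @param token token.
#' @return idf value (can be negative for ubiquitous tokens).
#' @export
inverse_doc_frequency <- function(stats, token) {
  log(stats$n_cases / (lookup0(stats$doc_freq, token) + 1))
}

#' Flat symptom-element statistics table
#'
#' One row per observed (symptom, element) pair with the co-occurrence
#' probability, single-token rule confidence and support, and a TF-IDF score
#' (mean term frequency of the element over the cases containing the pair,
#' times the element's IDF). Suitable for export and inspection.
#'
#' @param stats an `assoc_stats`.
#' @return a `data.frame` with columns symptom, element, cooccurrence,
#'   confidence, support, tfidf.
#' @export
association_table <- function(stats) {
  if (length(stats$pair_count) == 0L)
    return(data.frame(symptom = character(0), element = character(0),
                      cooccurrence = numeric(0), confidence = numeric(0),
                      support = numeric(0), tfidf = numeric(0)))
  parts <- strsplit(names(stats$pair_count), PAIR_SEP, fixed = TRUE)
  sym <- vapply(parts, `[[`, character(1), 1L)
  ele <- vapply(parts, `[[`, character(1), 2L)
  n <- length(sym)
  co <- conf <- sup <- tfidf <- numeric(n)
  for (k in seq_len(n)) {
    co[k] <- suppressWarnings(cooccurrence_probability(stats, sym[k], ele[k]))
    conf[k] <- suppressWarnings(rule_confidence(stats, sym[k], ele[k]))
    sup[k] <- rule_support(stats, sym[k], ele[k])
    in_pair <- vapply(seq_len(stats$n_cases), function(i)
      sym[k] %in% stats$symptom_sets[[i]] && ele[k] %in% stats$element_sets[[i]],
      logical(1))
    tfs <- vapply(which(in_pair), function(i)
      suppressWarnings(term_frequency(stats, ele[k], stats$case_ids[[i]])), numeric(1))
    tfidf[k] <- mean(tfs) * inverse_doc_frequency(stats, ele[k])
  }
  df <- data.frame(symptom = sym, element = ele, cooccurrence = co,
                   confidence = conf, support = sup, tfidf = tfidf,
                   stringsAsFactors = FALSE)
  df[order(df$symptom, df$element, method = "radix"), , drop = FALSE]
}
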