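# The scene-conditioned multi-task meta-attention network, plus MLP and MMoE
# baselines sharing the same input pipeline.
#
# Architecture (main model): token embeddings -> multi-head self-attention +
# feed-forward over the symptom sequence (high-order patient features) ->
# squeeze-and-excitation fusion with demographic, disease, scene and dense
# statistical feature blocks -> expert group (S shared + K per-task unique
# two-layer ReLU experts) -> per-task meta-attention gate (scene-conditioned)
# -> per-task meta tower (cascaded scene-conditioned dense layers) -> one
# score vector per element-category task. Global rankings concatenate the
# per-task softmax scores (the five category vocabularies partition the
# element vocabulary, so every element receives exactly one score).
#
# Every forward pass runs on the autodiff tape in R/autodiff.R; the exported
# layer functions below (scaled_dot_attention, feed_forward, senet_fuse,
# meta_unit, meta_attention, ...) are pure-matrix implementations of the
# same equations, usable standalone and for cross-checking.

TASK_CODES <- CATEGORY_CODES   # five element-category tasks a-e

#' Model hyperparameter configuration
#'
#' @param embed_dim embedding width d for all token embeddings.
#' @param n_heads number of attention heads h; must divide `embed_dim`.
#' @param ffn_hidden hidden width of the position-wise feed-forward layer;
#'   default `embed_dim * n_heads`.
#' @param n_shared_experts S, experts visible to every task's gate.
#' @param n_unique_experts K, experts owned by each task.
#' @param expert_dim output width of each expert.
#' @param meta_dim output width of the gating meta unit.
#' @param tower_depth number of cascaded meta units per task tower (>= 1).
#' @param tower_dim width of tower layers.
#' @param senet_hidden bottleneck width of the squeeze-and-excitation gate.
#' @param senet_mode `"additive"` (fused + gate, the literal form) or
#'   `"multiplicative"` (fused * gate, canonical SE reweighting).
#' @param scene_field what conditions the meta units: `"category"` (the
#'   task id; default), `"department"` or `"consult_season"` (the record's
#'   scene id from the vocabulary).
#' @param loss `"bce"` (per-task multi-label sigmoid cross-entropy, default)
#'   or `"softmax"` (per-task softmax cross-entropy).
#' @param ranking_merge how per-task scores combine into the global element
#'   ranking: `"sigmoid"` (default; per-element sigmoid scores, comparable
#'   across tasks) or `"softmax"` (per-task softmax concatenation, which
#'   constrains every category to sum to 1).
#' @param task_weights optional numeric length-5 per-task loss weights.
#' @param mlp_hidden integer vector of hidden widths for the MLP baseline.
#' @param init_sd embedding initialization standard deviation (truncated
#'   normal at 2 sd).
#' @param seed integer seed for parameter initialization.
#' @return a `model_config` list.
#' @export
model_config <- function(embed_dim = 16L, n_heads = 2L, ffn_hidden = NULL,
                         n_shared_experts = 2L, n_unique_experts = 1L,
                         expert_dim = 32L, meta_dim = 8L,
                         tower_depth = 2L, tower_dim = 32L,
                         senet_hidden = 8L,
                         senet_mode = c("additive", "multiplicative"),
                         scene_field = c("category", "department", "consult_season"),
                         loss = c("bce", "softmax"),
                         ranking_merge = c("sigmoid", "softmax"),
                         task_weights = rep(1, 5),
                         mlp_hidden = c(64L, 32L),
                         init_sd = 0.05, seed = 42L) {
  senet_mode <- match.arg(senet_mode)
  scene_field <- match.arg(scene_field)
  loss <- match.arg(loss)
  ranking_merge <- match.arg(ranking_merge)
  if (is.null(ffn_hidden)) ffn_hidden <- embed_dim * n_heads
  stopifnot(embed_dim > 0, n_heads > 0, embed_dim %% n_heads == 0,
            ffn_hidden > 0, n_shared_experts >= 0, n_unique_experts >= 0,
            n_shared_experts + n_unique_experts >= 1,
            tower_depth >= 1, length(task_weights) == 5)
  structure(list(
    embed_dim = as.integer(embed_dim), n_heads = as.integer(n_heads),
    ffn_hidden = as.integer(ffn_hidden),
    n_shared_experts = as.integer(n_shared_experts),
    n_unique_experts = as.integer(n_unique_experts),
    n_tasks = 5L, expert_dim = as.integer(expert_dim),
    meta_dim = as.integer(meta_dim), tower_depth = as.integer(tower_depth),
    tower_dim = as.integer(tower_dim), senet_hidden = as.integer(senet_hidden),
    senet_mode = senet_mode, scene_field = scene_field, loss = loss,
    ranking_merge = ranking_merge,
    task_weights = as.numeric(task_weights),
    mlp_hidden = as.integer(mlp_hidden),
    init_sd = init_sd, seed = as.integer(seed)
  ), class = "model_config")
}

#' Read a model configuration from YAML
#' @param path YAML file whose keys override [model_config()] defaults.
#' @export
model_config_from_yaml <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(model_config, user)
}

# ---- initialization ---------------------------------------------------------

trunc_normal <- function(n, sd) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

init_embed <- function(nrow, ncol, sd) matrix(trunc_normal(nrow * ncol, sd), nrow, ncol)

init_dense <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(1 / max(nin, 1))), nin, nout)
}

# Generator for a scene-conditioned dense layer: the bias part g0 carries a
# fan-in initialized base layer; G starts near zero so scenes differentiate
# during training from a shared starting point.
init_meta_generator <- function(in_dim, out_dim, ds) {
  m <- in_dim * out_dim + out_dim
  g0 <- matrix(0, m, 1L)
  g0[seq_len(in_dim * out_dim), 1L] <- as.vector(init_dense(out_dim, in_dim))
  list(G = matrix(stats::rnorm(m * ds, 0, 0.01), m, ds), g0 = g0)
}

# ---- task partition and dense prior features --------------------------------

# Map each element id (1..Ve) to a task 1..5 by category code; elements with
# no category evidence join the corpus-majority category (flagged).
task_partition <- function(vocabs) {
  cats <- vocabs$element_category_of           # named by token, in vocab order
  toks <- vocabs$element_vocab$tokens[-1L]     # drop <unk>
  codes <- unname(cats[toks])
  known <- codes[!is.na(codes)]
  fallback <- if (length(known)) names(which.max(table(factor(known, levels = TASK_CODES))))
              else "d"
  codes[is.na(codes)] <- fallback
  task_of <- match(codes, TASK_CODES)
  list(task_of_element = task_of,
       task_elements = lapply(seq_along(TASK_CODES), function(t) which(task_of == t)),
       n_unlabeled = sum(is.na(unname(cats[toks]))))
}

#' Dense statistical prior features per symptom
#'
#' Matrix with one row per symptom id (row 1 = the unknown token) and one
#' column per element, holding the co-occurrence probability of the element
#' given the symptom. The unknown row holds the marginal element document
#' frequency. Per-case dense features are the mean over the case's symptom
#' rows.
#'
#' @param vocabs a `tcm_vocab`.
#' @param stats an `assoc_stats` built from the *training* corpus.
#' @return numeric matrix (Vs + 1) x Ve.
#' @export
prior_feature_matrix <- function(vocabs, stats) {
  Vs <- vocab_size(vocabs$symptom_vocab)
  Ve <- vocab_size(vocabs$element_vocab)
  M <- matrix(0, Vs + 1L, Ve)
  ele_toks <- vocabs$element_vocab$tokens[-1L]
  M[1L, ] <- vapply(ele_toks, function(e) lookup0(stats$doc_freq, e), numeric(1)) /
    stats$n_cases
  pair_names <- names(stats$pair_count)
  if (length(pair_names)) {
    parts <- strsplit(pair_names, PAIR_SEP, fixed = TRUE)
    sym <- vapply(parts, `[[`, character(1), 1L)
    ele <- vapply(parts, `[[`, character(1), 2L)
    si <- token_ids(vocabs$symptom_vocab, sym)
    ei <- token_ids(vocabs$element_vocab, ele)
    denom <- vapply(sym, function(s) lookup0(stats$symptom_any_count, s), numeric(1))
    keep <- si > 0L & ei > 0L & denom > 0
    M[cbind(si[keep] + 1L, ei[keep])] <- as.numeric(stats$pair_count[keep]) / denom[keep]
  }
  M
}

#' Dense statistical feature bundle for model input
#'
#' Assembles the low-order feature block fed alongside the embeddings:
#' the corpus-wide symptom-element prior of [prior_feature_matrix()], the
#' same prior computed within each scene (capturing scene-specific
#' association structure; scenes unseen at training fall back to the global
#' prior), and optionally the raw symptom multi-hot indicator. All
#' statistics must come from the training split only.
#'
#' @param vocabs a `tcm_vocab`.
#' @param train_cases the training corpus the statistics are computed from.
#' @param include_scene_priors add per-scene prior blocks (default TRUE).
#' @param include_symptom_multihot add the symptom indicator block
#'   (default TRUE).
#' @param scene_shrinkage empirical-Bayes shrinkage weight for the per-scene
#'   priors: each within-scene co-occurrence probability is estimated as
#'   `(pair count + tau * global prior) / (symptom count + tau)` with
#'   `tau = scene_shrinkage` pseudo-counts, pulling sparse scene cells
#'   toward the corpus-wide estimate (default 20).
#' @return a `dense_features` bundle consumed by [build_model()].
#' @export
dense_feature_bundle <- function(vocabs, train_cases,
                                 include_scene_priors = TRUE,
                                 include_symptom_multihot = TRUE,
                                 scene_shrinkage = 20) {
  stats <- build_association_stats(train_cases)
  global <- prior_feature_matrix(vocabs, stats)
  by_scene <- NULL
  if (include_scene_priors) {
    scene_of <- vapply(train_cases, function(cs) cs[[vocabs$scene_field]],
                       character(1))
    by_scene <- lapply(vocabs$scene_vocab$tokens[-1L], function(sc) {
      sub <- train_cases[scene_of == sc]
      if (length(sub) == 0L) return(global)
      shrunken_prior_matrix(vocabs,
                            build_association_stats(structure(sub, class = "tcm_corpus")),
                            global, scene_shrinkage)
    })
    names(by_scene) <- vocabs$scene_vocab$tokens[-1L]
  }
  Vs <- vocab_size(vocabs$symptom_vocab)
  Ve <- vocab_size(vocabs$element_vocab)
  width <- Ve + (if (include_scene_priors) Ve else 0L) +
    (if (include_symptom_multihot) Vs else 0L)
  structure(list(global = global, by_scene = by_scene,
                 symptom_multihot = include_symptom_multihot,
                 width = as.integer(width)),
            class = "dense_features")
}

# Within-scene prior with pseudo-count shrinkage toward the global prior:
# cell (s, e) = (pair_count_g + tau * global[s, e]) / (any_count_g + tau).
shrunken_prior_matrix <- function(vocabs, stats_g, global, tau) {
  Vs <- vocab_size(vocabs$symptom_vocab)
  Ve <- vocab_size(vocabs$element_vocab)
  pairs <- matrix(0, Vs + 1L, Ve)
  anyc <- numeric(Vs + 1L)
  pn <- names(stats_g$pair_count)
  if (length(pn)) {
    parts <- strsplit(pn, PAIR_SEP, fixed = TRUE)
    si <- token_ids(vocabs$symptom_vocab, vapply(parts, `[[`, character(1), 1L))
    ei <- token_ids(vocabs$element_vocab, vapply(parts, `[[`, character(1), 2L))
    keep <- si > 0L & ei > 0L
    pairs[cbind(si[keep] + 1L, ei[keep])] <- as.numeric(stats_g$pair_count[keep])
  }
  sa <- token_ids(vocabs$symptom_vocab, names(stats_g$symptom_any_count))
  anyc[sa[sa > 0L] + 1L] <- as.numeric(stats_g$symptom_any_count[sa > 0L])
  (pairs + tau * global) / (anyc + tau)
}

# Per-case dense feature rows from a bundle (or a bare prior matrix).
dense_rows <- function(bundle, b, vocabs) {
  if (is.null(bundle)) return(NULL)
  if (is.matrix(bundle))
    bundle <- structure(list(global = bundle, by_scene = NULL,
                             symptom_multihot = FALSE,
                             width = ncol(bundle)), class = "dense_features")
  B <- b$B
  mean_rows <- function(M, i) {
    n <- max(sum(b$mask[i, ]), 1L)
    rows <- b$sym_ids[i, seq_len(n)] + 1L
    colMeans(M[rows, , drop = FALSE])
  }
  out <- t(vapply(seq_len(B), function(i) {
    v <- mean_rows(bundle$global, i)
    if (!is.null(bundle$by_scene)) {
      sc <- b$scene[[i]]
      M <- if (sc >= 1L && sc <= length(bundle$by_scene))
        bundle$by_scene[[sc]] else bundle$global
      v <- c(v, mean_rows(M, i))
    }
    if (bundle$symptom_multihot) {
      Vs <- nrow(bundle$global) - 1L
      mh <- numeric(Vs)
      ids <- b$sym_ids[i, b$sym_ids[i, ] > 0L]
      mh[ids] <- 1
      v <- c(v, mh)
    }
    v
  }, numeric(bundle$width)))
  if (!is.matrix(out)) out <- matrix(out, nrow = B)
  out
}

# ---- model construction -----------------------------------------------------

#' Build a recommendation model
#'
#' Initializes all parameters of the requested architecture against a
#' vocabulary set. `prior` (from [prior_feature_matrix()]) supplies the
#' dense statistical feature block; omit it for an embeddings-only model.
#'
#' @param vocabs a `tcm_vocab`.
#' @param config a `model_config`.
#' @param kind `"meta"` (the meta-attention multi-task model), `"mlp"` or
#'   `"mmoe"`.
#' @param prior optional dense feature input: a bare prior matrix
#'   (`(Vs+1) x Ve`, from [prior_feature_matrix()]) or a `dense_features`
#'   bundle from [dense_feature_bundle()].
#' @return a `tcm_model`.
#' @export
build_model <- function(vocabs, config = model_config(),
                        kind = c("meta", "mlp", "mmoe"), prior = NULL) {
  kind <- match.arg(kind)
  part <- task_partition(vocabs)
  dims <- model_dims(vocabs, config, part, prior)
  params <- with_seed(config$seed, switch(kind,
    meta = init_params_meta(config, dims),
    mlp = init_params_mlp(config, dims),
    mmoe = init_params_mmoe(config, dims)))
  structure(list(kind = kind, config = config, vocabs = vocabs,
                 partition = part, prior = prior, dims = dims,
                 params = params),
            class = "tcm_model")
}

#' Build a baseline model (shared input pipeline)
#'
#' @param kind `"mlp"` or `"mmoe"`.
#' @inheritParams build_model
#' @export
build_baseline <- function(kind = c("mlp", "mmoe"), vocabs,
                           config = model_config(), prior = NULL) {
  kind <- match.arg(kind)
  build_model(vocabs, config, kind = kind, prior = prior)
}

model_dims <- function(vocabs, config, part, prior) {
  d <- config$embed_dim
  n_dense <- if (is.null(prior)) 0L
             else if (is.matrix(prior)) ncol(prior)
             else prior$width
  n_blocks <- 4L + (n_dense > 0L)
  list(
    Vs = vocab_size(vocabs$symptom_vocab),
    Ve = vocab_size(vocabs$element_vocab),
    Vd = vocab_size(vocabs$disease_vocab),
    Vscene = vocab_size(vocabs$scene_vocab),
    n_meta_scene = if (config$scene_field == "category") 5L
                   else vocab_size(vocabs$scene_vocab),
    n_dense = n_dense,
    fused_dim = 4L * d + n_dense,
    n_blocks = n_blocks,
    task_widths = vapply(part$task_elements, length, integer(1))
  )
}

init_embeddings <- function(config, dims) {
  d <- config$embed_dim; sd <- config$init_sd
  list(
    emb_sym = init_embed(dims$Vs + 1L, d, sd),
    emb_sex = init_embed(3L, d, sd),           # 0 unk, 1 female, 2 male
    emb_stage = init_embed(14L, d, sd),        # 0 unk, stages 1..13
    emb_season = init_embed(5L, d, sd),        # 0 unk, 4 seasons
    emb_dis = init_embed(dims$Vd + 1L, d, sd),
    emb_scene = init_embed(dims$Vscene + 1L, d, sd)
  )
}

init_experts <- function(config, dims, n_experts) {
  p <- list()
  for (i in seq_len(n_experts)) {
    p[[sprintf("exp%d_W1", i)]] <- init_dense(dims$fused_dim, config$expert_dim)
    p[[sprintf("exp%d_b1", i)]] <- matrix(0, 1L, config$expert_dim)
    p[[sprintf("exp%d_W2", i)]] <- init_dense(config$expert_dim, config$expert_dim)
    p[[sprintf("exp%d_b2", i)]] <- matrix(0, 1L, config$expert_dim)
  }
  p
}

init_heads <- function(config, dims, in_dim) {
  p <- list()
  for (t in 1:5) {
    w <- dims$task_widths[[t]]
    p[[sprintf("t%d_head_W", t)]] <- init_dense(in_dim, w)
    p[[sprintf("t%d_head_b", t)]] <- matrix(0, 1L, w)
  }
  p
}

init_params_meta <- function(config, dims) {
  d <- config$embed_dim
  p <- init_embeddings(config, dims)
  p$emb_meta_scene <- init_embed(dims$n_meta_scene + 1L, d, config$init_sd)
  p$att_Wq <- init_dense(d, d); p$att_Wk <- init_dense(d, d)
  p$att_Wv <- init_dense(d, d); p$att_WH <- init_dense(d, d)
  p$ffn_W1 <- init_dense(d, config$ffn_hidden)
  p$ffn_b1 <- matrix(0, 1L, config$ffn_hidden)
  p$ffn_W2 <- init_dense(config$ffn_hidden, d)
  p$ffn_b2 <- matrix(0, 1L, d)
  p$sen_W1 <- init_dense(dims$n_blocks, config$senet_hidden)
  p$sen_b1 <- matrix(0, 1L, config$senet_hidden)
  p$sen_W2 <- init_dense(config$senet_hidden, dims$fused_dim)
  p$sen_b2 <- matrix(0, 1L, dims$fused_dim)
  n_experts <- config$n_shared_experts + config$n_unique_experts * 5L
  p <- c(p, init_experts(config, dims, n_experts))
  de <- config$expert_dim; dm <- config$meta_dim; dt <- config$tower_dim
  for (t in 1:5) {
    g <- init_meta_generator(de, dm, d)
    p[[sprintf("t%d_att_G", t)]] <- g$G
    p[[sprintf("t%d_att_g0", t)]] <- g$g0
    p[[sprintf("t%d_V", t)]] <- init_dense(dm, 1L)
    for (l in seq_len(config$tower_depth)) {
      in_dim <- if (l == 1L) de else dt
      g <- init_meta_generator(in_dim, dt, d)
      p[[sprintf("t%d_tw%d_G", t, l)]] <- g$G
      p[[sprintf("t%d_tw%d_g0", t, l)]] <- g$g0
    }
  }
  c(p, init_heads(config, dims, dt))
}

init_params_mlp <- function(config, dims) {
  p <- init_embeddings(config, dims)
  widths <- c(dims$fused_dim, config$mlp_hidden)
  for (l in seq_along(config$mlp_hidden)) {
    p[[sprintf("mlp%d_W", l)]] <- init_dense(widths[[l]], widths[[l + 1L]])
    p[[sprintf("mlp%d_b", l)]] <- matrix(0, 1L, widths[[l + 1L]])
  }
  last <- widths[[length(widths)]]
  c(p, init_heads(config, dims, last))
}

init_params_mmoe <- function(config, dims) {
  p <- init_embeddings(config, dims)
  n_experts <- config$n_shared_experts + config$n_unique_experts
  p <- c(p, init_experts(config, dims, n_experts))
  de <- config$expert_dim; dt <- config$tower_dim
  for (t in 1:5) {
    p[[sprintf("t%d_gate_W", t)]] <- init_dense(dims$fused_dim, n_experts)
    for (l in seq_len(config$tower_depth)) {
      in_dim <- if (l == 1L) de else dt
      p[[sprintf("t%d_tw%d_W", t, l)]] <- init_dense(in_dim, dt)
      p[[sprintf("t%d_tw%d_b", t, l)]] <- matrix(0, 1L, dt)
    }
  }
  c(p, init_heads(config, dims, dt))
}

#' @export
print.tcm_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<tcm_model> kind=", x$kind, ", ", np, " parameters, tasks a-e widths: ",
      paste(x$dims$task_widths, collapse = "/"),
      ", scene = ", x$config$scene_field, "\n", sep = "")
  invisible(x)
}

# ---- batch preparation ------------------------------------------------------

season_id <- function(x) {
  i <- match(x, SEASONS)
  ifelse(is.na(i), 0L, i)
}

# Turn case records into padded id matrices, dense features and multi-hot
# label matrices (one per task).
prepare_batch <- function(cases, model) {
  vocabs <- model$vocabs
  B <- length(cases)
  lens <- vapply(cases, function(cs) length(cs$symptoms), integer(1))
  L <- max(lens, 1L)
  sym_ids <- matrix(0L, B, L)
  mask <- matrix(0, B, L)
  for (i in seq_len(B)) {
    ids <- token_ids(vocabs$symptom_vocab, cases[[i]]$symptoms)
    n <- length(ids)
    if (n) { sym_ids[i, seq_len(n)] <- ids; mask[i, seq_len(n)] <- 1 }
  }
  sex <- vapply(cases, function(cs)
    if (is.na(cs$patient_sex)) 0L else match(cs$patient_sex, c("female", "male")),
    integer(1))
  stage <- vapply(cases, function(cs) {
    if (is.na(cs$patient_sex) || is.na(cs$age_years)) 0L
    else suppressWarnings(age_gender_code(cs$patient_sex, cs$age_years)$stage)
  }, integer(1))
  season <- vapply(cases, function(cs) season_id(cs$consult_season), integer(1))
  disease <- vapply(cases, function(cs)
    token_ids(vocabs$disease_vocab, cs$disease_name), integer(1))
  scene <- vapply(cases, function(cs)
    token_ids(vocabs$scene_vocab, cs[[vocabs$scene_field]]), integer(1))

  b_partial <- list(B = B, sym_ids = sym_ids, mask = mask, scene = scene)
  dense <- dense_rows(model$prior, b_partial, vocabs)

  labels <- lapply(1:5, function(t) {
    cols <- model$partition$task_elements[[t]]
    Y <- matrix(0, B, length(cols))
    if (length(cols)) {
      for (i in seq_len(B)) {
        eids <- token_ids(vocabs$element_vocab, cases[[i]]$elements)
        hit <- match(eids[eids > 0L], cols)
        hit <- hit[!is.na(hit)]
        if (length(hit)) Y[i, hit] <- 1
      }
    }
    Y
  })
  list(B = B, L = L, sym_ids = sym_ids, mask = mask, sex = sex, stage = stage,
       season = season, disease = disease, scene = scene, dense = dense,
       labels = labels)
}

#' Embed a batch of case records
#'
#' Looks up and assembles the embedding blocks of a batch: `e_u` (patient
#' block: mean symptom embedding next to the mean of sex/age-stage/season
#' embeddings), `e_i` (disease context), `e_s` (scene), the raw dense
#' statistical features, and their concatenation.
#'
#' @param cases list of case records.
#' @param model a `tcm_model`.
#' @return list with `e_u`, `e_i`, `e_s`, `dense`, `evec`.
#' @export
embed_batch <- function(cases, model) {
  b <- prepare_batch(cases, model)
  p <- model$params
  gather <- function(tab, ids) tab[ids + 1L, , drop = FALSE]
  sym_flat <- gather(p$emb_sym, as.vector(b$sym_ids))   # position-major (B*L) x d
  pool <- matrix(0, b$B, ncol(sym_flat))
  for (l in seq_len(b$L))
    pool <- pool + b$mask[, l] * sym_flat[seq_rows(l, b$B), , drop = FALSE]
  pool <- pool / pmax(rowSums(b$mask), 1)
  demo <- (gather(p$emb_sex, b$sex) + gather(p$emb_stage, b$stage) +
             gather(p$emb_season, b$season)) / 3
  e_u <- cbind(pool, demo)
  e_i <- gather(p$emb_dis, b$disease)
  e_s <- gather(p$emb_scene, b$scene)
  evec <- cbind(e_u, e_i, e_s)
  if (!is.null(b$dense)) evec <- cbind(evec, b$dense)
  list(e_u = e_u, e_i = e_i, e_s = e_s, dense = b$dense, evec = evec)
}

# ---- exported layer operations (pure matrix form) ---------------------------

softmax_rows <- function(x) {
  if (ncol(x) == 0L) return(x)
  ex <- exp(x - apply(x, 1L, max))
  ex / rowSums(ex)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d)) V` with `d = ncol(Q)`; each softmax row sums
#' to 1.
#'
#' @param Q,K,V matrices; `ncol(Q) == ncol(K)`, `nrow(K) == nrow(V)`.
#' @return matrix `nrow(Q) x ncol(V)`.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  d <- ncol(Q)
  if (is.null(d) || d == 0L) stop("scaled_dot_attention: zero-width queries")
  stopifnot(ncol(K) == d, nrow(K) == nrow(V))
  softmax_rows(Q %*% t(K) / sqrt(d)) %*% V
}

#' Multi-head self-attention block
#'
#' Splits the projected queries/keys/values into `n_heads` column blocks,
#' applies scaled dot-product attention per head, concatenates the heads
#' and applies the output projection.
#'
#' @param X token matrix (n_tokens x d).
#' @param params list with `Wq`, `Wk`, `Wv` (d x d) and `WH` (d x d).
#' @param config a `model_config` (uses `n_heads`).
#' @return matrix n_tokens x d.
#' @export
multi_head_block <- function(X, params, config) {
  d <- ncol(X); h <- config$n_heads
  if (d %% h != 0L) stop("n_heads (", h, ") does not divide embed_dim (", d, ")")
  dh <- d %/% h
  Q <- X %*% params$Wq; K <- X %*% params$Wk; V <- X %*% params$Wv
  heads <- lapply(seq_len(h), function(i) {
    cols <- (i - 1L) * dh + seq_len(dh)
    scaled_dot_attention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                         V[, cols, drop = FALSE])
  })
  do.call(cbind, heads) %*% params$WH
}

#' Position-wise feed-forward layer
#'
#' `ReLU((x W1 + b1) W2) + b2`, with the outer ReLU placement as written.
#'
#' @param x input matrix (n x d).
#' @param params list with `W1` (d x dk), `b1` (1 x dk), `W2` (dk x d),
#'   `b2` (1 x d).
#' @return matrix n x d.
#' @export
feed_forward <- function(x, params) {
  t1 <- sweep(x %*% params$W1, 2L, params$b1[1L, ], "+")
  sweep(pmax(t1 %*% params$W2, 0), 2L, params$b2[1L, ], "+")
}

#' Squeeze-and-excitation feature fusion
#'
#' Squeezes each feature group to its per-row mean, passes the squeeze
#' vector through a bottleneck MLP, and applies the logistic gate `s` to the
#' concatenated representation: `x + s` in additive mode (the literal form)
#' or `x * s` in multiplicative mode (canonical SE reweighting).
#'
#' @param feature_groups list of matrices with equal row counts.
#' @param params list with `W1` (G x h), `b1`, `W2` (h x D), `b2` where G is
#'   the number of groups and D the total concatenated width.
#' @param mode `"additive"` or `"multiplicative"`.
#' @return list with `fused` (B x D), `gate` (B x D).
#' @export
senet_fuse <- function(feature_groups, params, mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  stopifnot(length(feature_groups) >= 1L)
  x <- do.call(cbind, feature_groups)
  z <- vapply(feature_groups, rowMeans, numeric(nrow(x)))
  if (!is.matrix(z)) z <- matrix(z, nrow = nrow(x))
  hid <- pmax(sweep(z %*% params$W1, 2L, params$b1[1L, ], "+"), 0)
  s <- 1 / (1 + exp(-sweep(hid %*% params$W2, 2L, params$b2[1L, ], "+")))
  fused <- if (mode == "additive") x + s else x * s
  list(fused = fused, gate = s)
}

#' Scene-conditioned dense layer (meta unit)
#'
#' The layer's weights and bias are generated from the scene embedding:
#' `flat = G e_scene + g0`, the first `in*out` entries reshaped
#' (column-major) into the `out x in` weight matrix and the remainder the
#' bias, then `y = ReLU(W x + b)`. With `G = 0` the layer is an ordinary
#' dense ReLU layer `(W0, b0) = reshape(g0)` for every scene.
#'
#' @param x input matrix (B x in).
#' @param scene_embedding numeric vector (the scene's embedding).
#' @param params list with `G` ((in*out+out) x ds) and `g0` ((in*out+out) x 1).
#' @param out_dim output width.
#' @param activation `"relu"` (default) or `"linear"`.
#' @return matrix B x out_dim.
#' @export
meta_unit <- function(x, scene_embedding, params, out_dim,
                      activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  in_dim <- ncol(x)
  flat <- drop(params$G %*% scene_embedding) + params$g0[, 1L]
  if (length(flat) != in_dim * out_dim + out_dim)
    stop("meta_unit: generator output length ", length(flat),
         " does not match in*out+out = ", in_dim * out_dim + out_dim)
  W <- matrix(flat[seq_len(in_dim * out_dim)], out_dim, in_dim)
  b <- flat[in_dim * out_dim + seq_len(out_dim)]
  pre <- sweep(x %*% t(W), 2L, b, "+")
  if (activation == "relu") pmax(pre, 0) else pre
}

#' Meta-attention gate over an expert group
#'
#' Scores each expert output through the task's scene-conditioned meta unit
#' followed by the projection vector `V`, then softmax-normalizes the
#' `S + K` scores per row.
#'
#' @param expert_outputs list of matrices (B x d_e), one per expert.
#' @param scene_embedding numeric vector conditioning the meta unit.
#' @param params list with `G`, `g0` (meta-unit generator, d_e -> meta_dim)
#'   and `V` (meta_dim x 1).
#' @return gate weight matrix B x n_experts, rows summing to 1.
#' @export
meta_attention <- function(expert_outputs, scene_embedding, params) {
  stopifnot(length(expert_outputs) >= 1L)
  meta_dim <- nrow(params$V)
  scores <- vapply(expert_outputs, function(E)
    drop(meta_unit(E, scene_embedding, params, meta_dim) %*% params$V),
    numeric(nrow(expert_outputs[[1L]])))
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = nrow(expert_outputs[[1L]]))
  softmax_rows(scores)
}

#' Meta tower forward pass
#'
#' Cascade of scene-conditioned meta units followed by a linear head sized
#' to the task's element vocabulary.
#'
#' @param gated_input matrix B x d_e (gated expert mixture).
#' @param scene_embedding numeric vector.
#' @param tower_params list with `layers` (list of `G`/`g0` generators),
#'   `out_dims` (integer widths per layer), `head_W`, `head_b`.
#' @return logits matrix B x task vocabulary size.
#' @export
meta_tower_forward <- function(gated_input, scene_embedding, tower_params) {
  x <- gated_input
  for (l in seq_along(tower_params$layers)) {
    x <- meta_unit(x, scene_embedding, tower_params$layers[[l]],
                   tower_params$out_dims[[l]])
  }
  sweep(x %*% tower_params$head_W, 2L, tower_params$head_b[1L, ], "+")
}

# ---- tape forward passes ----------------------------------------------------

# Shared input assembly on the tape. Returns the fused feature node (before
# SENET for baselines, which skip the transformer and use the raw mean
# symptom embedding) plus the node handles needed downstream.
tape_inputs <- function(tape, P, b, model, use_transformer = TRUE) {
  config <- model$config
  d <- config$embed_dim
  ids_flat <- as.vector(b$sym_ids)            # column-major = position-major
  Esym <- tp_embed(tape, P$emb_sym, ids_flat)
  if (use_transformer) {
    h <- config$n_heads; dh <- d %/% h
    Q <- tp_matmul(tape, Esym, P$att_Wq)
    K <- tp_matmul(tape, Esym, P$att_Wk)
    V <- tp_matmul(tape, Esym, P$att_Wv)
    heads <- lapply(seq_len(h), function(i) {
      cols <- (i - 1L) * dh + seq_len(dh)
      tp_seq_attention(tape,
                       tp_slice_cols(tape, Q, cols),
                       tp_slice_cols(tape, K, cols),
                       tp_slice_cols(tape, V, cols), b$mask)
    })
    S_out <- tp_matmul(tape, tp_concat_cols(tape, heads), P$att_WH)
    t1 <- tp_add(tape, tp_matmul(tape, S_out, P$ffn_W1), P$ffn_b1)
    hi <- tp_add(tape, tp_relu(tape, tp_matmul(tape, t1, P$ffn_W2)), P$ffn_b2)
    u <- tp_masked_mean(tape, hi, b$mask)
  } else {
    u <- tp_masked_mean(tape, Esym, b$mask)
  }
  demo <- tp_scale(tape, tp_add(tape,
            tp_add(tape, tp_embed(tape, P$emb_sex, b$sex),
                   tp_embed(tape, P$emb_stage, b$stage)),
            tp_embed(tape, P$emb_season, b$season)), 1 / 3)
  e_i <- tp_embed(tape, P$emb_dis, b$disease)
  e_s <- tp_embed(tape, P$emb_scene, b$scene)
  blocks <- list(u, demo, e_i, e_s)
  widths <- c(d, d, d, d)
  if (!is.null(b$dense)) {
    blocks <- c(blocks, list(tp_const(tape, b$dense)))
    widths <- c(widths, ncol(b$dense))
  }
  x <- tp_concat_cols(tape, blocks)
  ends <- cumsum(widths)
  groups <- lapply(seq_along(widths), function(i) (ends[i] - widths[i] + 1L):ends[i])
  list(x = x, groups = groups)
}

tape_expert <- function(tape, P, i, x) {
  h <- tp_relu(tape, tp_add(tape, tp_matmul(tape, x, P[[sprintf("exp%d_W1", i)]]),
                            P[[sprintf("exp%d_b1", i)]]))
  tp_relu(tape, tp_add(tape, tp_matmul(tape, h, P[[sprintf("exp%d_W2", i)]]),
                       P[[sprintf("exp%d_b2", i)]]))
}

# scene ids conditioning task t's meta units
meta_scene_ids <- function(model, b, t) {
  if (model$config$scene_field == "category") rep(t, b$B) else b$scene
}

forward_meta <- function(tape, P, b, model) {
  config <- model$config
  inp <- tape_inputs(tape, P, b, model, use_transformer = TRUE)
  z <- tp_group_means(tape, inp$x, inp$groups)
  hid <- tp_relu(tape, tp_add(tape, tp_matmul(tape, z, P$sen_W1), P$sen_b1))
  s <- tp_sigmoid(tape, tp_add(tape, tp_matmul(tape, hid, P$sen_W2), P$sen_b2))
  fused <- if (config$senet_mode == "additive") tp_add(tape, inp$x, s)
           else tp_mul(tape, inp$x, s)
  S <- config$n_shared_experts; K <- config$n_unique_experts
  experts <- lapply(seq_len(S + K * 5L), function(i) tape_expert(tape, P, i, fused))
  logits <- vector("list", 5L)
  gates <- vector("list", 5L)
  for (t in 1:5) {
    idx <- c(seq_len(S), if (K > 0L) S + (t - 1L) * K + seq_len(K))
    ex_t <- experts[idx]
    sids <- meta_scene_ids(model, b, t)
    scores <- lapply(ex_t, function(E)
      tp_matmul(tape,
                tp_meta_dense(tape, E, P$emb_meta_scene, sids,
                              P[[sprintf("t%d_att_G", t)]],
                              P[[sprintf("t%d_att_g0", t)]],
                              config$meta_dim),
                P[[sprintf("t%d_V", t)]]))
    w <- tp_softmax_rows(tape, tp_concat_cols(tape, scores))
    gates[[t]] <- w
    xt <- tp_weighted_sum(tape, w, ex_t)
    for (l in seq_len(config$tower_depth)) {
      xt <- tp_meta_dense(tape, xt, P$emb_meta_scene, sids,
                          P[[sprintf("t%d_tw%d_G", t, l)]],
                          P[[sprintf("t%d_tw%d_g0", t, l)]],
                          config$tower_dim)
    }
    logits[[t]] <- tp_add(tape, tp_matmul(tape, xt, P[[sprintf("t%d_head_W", t)]]),
                          P[[sprintf("t%d_head_b", t)]])
  }
  list(logits = logits, gates = gates)
}

forward_mlp <- function(tape, P, b, model) {
  config <- model$config
  inp <- tape_inputs(tape, P, b, model, use_transformer = FALSE)
  x <- inp$x
  for (l in seq_along(config$mlp_hidden)) {
    x <- tp_relu(tape, tp_add(tape, tp_matmul(tape, x, P[[sprintf("mlp%d_W", l)]]),
                              P[[sprintf("mlp%d_b", l)]]))
  }
  logits <- lapply(1:5, function(t)
    tp_add(tape, tp_matmul(tape, x, P[[sprintf("t%d_head_W", t)]]),
           P[[sprintf("t%d_head_b", t)]]))
  list(logits = logits, gates = NULL)
}

forward_mmoe <- function(tape, P, b, model) {
  config <- model$config
  inp <- tape_inputs(tape, P, b, model, use_transformer = FALSE)
  x <- inp$x
  n_experts <- config$n_shared_experts + config$n_unique_experts
  experts <- lapply(seq_len(n_experts), function(i) tape_expert(tape, P, i, x))
  logits <- vector("list", 5L); gates <- vector("list", 5L)
  for (t in 1:5) {
    w <- tp_softmax_rows(tape, tp_matmul(tape, x, P[[sprintf("t%d_gate_W", t)]]))
    gates[[t]] <- w
    xt <- tp_weighted_sum(tape, w, experts)
    for (l in seq_len(config$tower_depth)) {
      xt <- tp_relu(tape, tp_add(tape,
              tp_matmul(tape, xt, P[[sprintf("t%d_tw%d_W", t, l)]]),
              P[[sprintf("t%d_tw%d_b", t, l)]]))
    }
    logits[[t]] <- tp_add(tape, tp_matmul(tape, xt, P[[sprintf("t%d_head_W", t)]]),
                          P[[sprintf("t%d_head_b", t)]])
  }
  list(logits = logits, gates = gates)
}

tape_forward <- function(tape, P, b, model) {
  switch(model$kind,
         meta = forward_meta(tape, P, b, model),
         mlp = forward_mlp(tape, P, b, model),
         mmoe = forward_mmoe(tape, P, b, model),
         stop("unknown model kind: ", model$kind))
}

wrap_params <- function(tape, params) lapply(params, function(v) tp_param(tape, v))

#' Model forward pass
#'
#' Scores a batch of case records. Returns the per-task logits, the
#' per-task softmax score vectors, and the global score matrix assembled
#' into the element vocabulary's positions (the category tasks partition
#' the vocabulary) using the configured `ranking_merge`: per-element
#' sigmoid scores by default, or the per-task softmax concatenation.
#'
#' @param model a `tcm_model`.
#' @param cases list of case records.
#' @return list with `logits` (5 matrices), `scores` (5 softmax matrices),
#'   `global_scores` (B x Ve), `gates` (per-task gate weights or NULL).
#' @export
model_forward <- function(model, cases) {
  b <- prepare_batch(cases, model)
  tape <- new_tape()
  P <- wrap_params(tape, model$params)
  out <- tape_forward(tape, P, b, model)
  logits <- lapply(out$logits, function(nd) nd$value)
  scores <- lapply(logits, softmax_rows)
  merge <- model$config$ranking_merge %||% "sigmoid"
  gs <- matrix(0, b$B, model$dims$Ve)
  for (t in 1:5) {
    cols <- model$partition$task_elements[[t]]
    if (!length(cols)) next
    gs[, cols] <- if (merge == "softmax") scores[[t]]
                  else 1 / (1 + exp(-logits[[t]]))
  }
  list(logits = logits, scores = scores, global_scores = gs,
       gates = lapply(out$gates, function(g) if (is.null(g)) NULL else g$value))
}

# ---- loss and gradients -----------------------------------------------------

# Attach per-task losses on the tape; returns the total (weighted) loss node.
tape_loss <- function(tape, logits, labels, config) {
  total <- NULL
  per_task <- numeric(5)
  for (t in 1:5) {
    if (ncol(logits[[t]]$value) == 0L) next
    lt <- if (config$loss == "bce")
      tp_bce_mean(tape, logits[[t]], labels[[t]])
    else
      tp_softmax_xent_mean(tape, logits[[t]], labels[[t]])
    per_task[t] <- lt$value[1L, 1L]
    wt <- tp_scale(tape, lt, config$task_weights[[t]])
    total <- if (is.null(total)) wt else tp_add(tape, total, wt)
  }
  attr(total, "per_task") <- per_task
  total
}

# One forward+backward pass; returns loss value and named gradient list.
loss_and_gradients <- function(model, batch) {
  tape <- new_tape()
  P <- wrap_params(tape, model$params)
  out <- tape_forward(tape, P, batch, model)
  loss <- tape_loss(tape, out$logits, batch$labels, model$config)
  tp_backward(tape, loss)
  grads <- lapply(P, function(nd)
    if (is.null(nd$grad)) matrix(0, nrow(nd$value), ncol(nd$value)) else nd$grad)
  list(loss = loss$value[1L, 1L], per_task = attr(loss, "per_task"), grads = grads)
}

batch_loss_value <- function(model, batch) {
  tape <- new_tape()
  P <- wrap_params(tape, model$params)
  out <- tape_forward(tape, P, batch, model)
  loss <- tape_loss(tape, out$logits, batch$labels, model$config)
  loss$value[1L, 1L]
}

#' Finite-difference gradient check
#'
#' Compares backpropagated gradients against central finite differences of
#' the batch loss for a sample of entries in every parameter group.
#'
#' @param model a `tcm_model`.
#' @param cases small list of case records (e.g. 2).
#' @param n_per_group entries sampled per parameter matrix.
#' @param eps finite-difference step.
#' @param seed seed for entry sampling.
#' @return named numeric vector: max relative error per parameter group.
#' @export
gradient_check <- function(model, cases, n_per_group = 4L, eps = 1e-5, seed = 1L) {
  batch <- prepare_batch(cases, model)
  got <- loss_and_gradients(model, batch)
  errs <- with_seed(seed, {
    vapply(names(model$params), function(nm) {
      v <- model$params[[nm]]
      n <- length(v)
      idx <- if (n <= n_per_group) seq_len(n) else sample.int(n, n_per_group)
      worst <- 0
      for (j in idx) {
        m2 <- model
        m2$params[[nm]][j] <- v[j] + eps
        up <- batch_loss_value(m2, batch)
        m2$params[[nm]][j] <- v[j] - eps
        dn <- batch_loss_value(m2, batch)
        fd <- (up - dn) / (2 * eps)
        bp <- got$grads[[nm]][j]
        denom <- max(abs(fd) + abs(bp), 1e-6)
        worst <- max(worst, abs(fd - bp) / denom)
      }
      worst
    }, numeric(1))
  })
  errs
}

# ---- scene-independent degenerate forward (plain matrices) ------------------

#' Directly-built scene-independent degenerate model forward
#'
#' An independent plain-matrix forward pass of the meta model in the limit
#' where every meta-unit generator weight `G` is zero: each meta unit
#' collapses to the fixed dense layer encoded in its `g0`, and the
#' architecture degenerates to a shared-expert mixture model with
#' input-independent-scene gates. Used to verify that zeroing the generator
#' weights of the full model reproduces this construction.
#'
#' @param model a meta `tcm_model` (its `g0` vectors are used as the fixed
#'   layers; its `G` matrices are ignored).
#' @param cases list of case records.
#' @return list of 5 logits matrices.
#' @export
degenerate_meta_forward <- function(model, cases) {
  stopifnot(model$kind == "meta")
  b <- prepare_batch(cases, model)
  P <- model$params
  config <- model$config
  d <- config$embed_dim
  sym_flat <- P$emb_sym[as.vector(b$sym_ids) + 1L, , drop = FALSE]
  att <- list(Wq = P$att_Wq, Wk = P$att_Wk, Wv = P$att_Wv, WH = P$att_WH)
  # per-case attention via the exported single-sequence block
  u <- matrix(0, b$B, d)
  for (i in seq_len(b$B)) {
    n <- sum(b$mask[i, ])
    rows <- (seq_len(n) - 1L) * b$B + i
    X <- sym_flat[rows, , drop = FALSE]
    S_out <- multi_head_block(X, att, config)
    hi <- feed_forward(S_out, list(W1 = P$ffn_W1, b1 = P$ffn_b1,
                                   W2 = P$ffn_W2, b2 = P$ffn_b2))
    u[i, ] <- colMeans(hi)
  }
  demo <- (P$emb_sex[b$sex + 1L, , drop = FALSE] +
             P$emb_stage[b$stage + 1L, , drop = FALSE] +
             P$emb_season[b$season + 1L, , drop = FALSE]) / 3
  groups <- list(u, demo, P$emb_dis[b$disease + 1L, , drop = FALSE],
                 P$emb_scene[b$scene + 1L, , drop = FALSE])
  if (!is.null(b$dense)) groups <- c(groups, list(b$dense))
  fus <- senet_fuse(groups, list(W1 = P$sen_W1, b1 = P$sen_b1,
                                 W2 = P$sen_W2, b2 = P$sen_b2),
                    mode = config$senet_mode)
  x <- fus$fused
  S <- config$n_shared_experts; K <- config$n_unique_experts
  experts <- lapply(seq_len(S + K * 5L), function(i) {
    h <- pmax(sweep(x %*% P[[sprintf("exp%d_W1", i)]], 2L,
                    P[[sprintf("exp%d_b1", i)]][1L, ], "+"), 0)
    pmax(sweep(h %*% P[[sprintf("exp%d_W2", i)]], 2L,
               P[[sprintf("exp%d_b2", i)]][1L, ], "+"), 0)
  })
  fixed_layer <- function(g0, in_dim, out_dim, x) {
    flat <- g0[, 1L]
    W <- matrix(flat[seq_len(in_dim * out_dim)], out_dim, in_dim)
    bb <- flat[in_dim * out_dim + seq_len(out_dim)]
    pmax(sweep(x %*% t(W), 2L, bb, "+"), 0)
  }
  de <- config$expert_dim; dm <- config$meta_dim; dt <- config$tower_dim
  logits <- vector("list", 5L)
  for (t in 1:5) {
    idx <- c(seq_len(S), if (K > 0L) S + (t - 1L) * K + seq_len(K))
    ex_t <- experts[idx]
    sc <- vapply(ex_t, function(E)
      drop(fixed_layer(P[[sprintf("t%d_att_g0", t)]], de, dm, E) %*%
             P[[sprintf("t%d_V", t)]]),
      numeric(b$B))
    if (!is.matrix(sc)) sc <- matrix(sc, nrow = b$B)
    w <- softmax_rows(sc)
    xt <- matrix(0, b$B, de)
    for (i in seq_along(ex_t)) xt <- xt + w[, i] * ex_t[[i]]
    for (l in seq_len(config$tower_depth)) {
      in_dim <- if (l == 1L) de else dt
      xt <- fixed_layer(P[[sprintf("t%d_tw%d_g0", t, l)]], in_dim, dt, xt)
    }
    logits[[t]] <- sweep(xt %*% P[[sprintf("t%d_head_W", t)]], 2L,
                         P[[sprintf("t%d_head_b", t)]][1L, ], "+")
  }
  logits
}

#' Zero all meta-unit generator weights of a meta model
#'
#' In the resulting model every meta unit is scene-independent (the fixed
#' dense layer encoded by its `g0`), for any scene id.
#'
#' @param model a meta `tcm_model`.
#' @return the modified model.
#' @export
zero_scene_generators <- function(model) {
  stopifnot(model$kind == "meta")
  for (nm in grep("_(att_G|tw[0-9]+_G)$", names(model$params), value = TRUE))
    model$params[[nm]][] <- 0
  model
}
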