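# Minimal reverse-mode automatic differentiation over dense matrices.
#
# A tape records nodes in creation order; each node holds its value, its
# parent nodes and a backward closure that routes the node's accumulated
# gradient into its parents. backward() seeds the root with 1 and replays
# the tape in reverse. Values are plain base-R matrices (doubles).
#
# Only the operations the network module needs are provided; several fused
# ops (sequence attention, scene-conditioned dense layers, masked pooling)
# carry hand-written backward rules, which the finite-difference gradient
# tests exercise end-to-end.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp
}

node_new <- function(tape, value, backfn = NULL, needs_grad = TRUE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backfn <- backfn
  nd$needs_grad <- needs_grad
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

accum_grad <- function(nd, g) {
  if (!nd$needs_grad && is.null(nd$backfn)) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' @keywords internal
tp_param <- function(tape, value) node_new(tape, as_mat(value), needs_grad = TRUE)

#' @keywords internal
tp_const <- function(tape, value) node_new(tape, as_mat(value), needs_grad = FALSE)

#' Run backpropagation from a scalar root node
#' @keywords internal
tp_backward <- function(tape, root) {
  stopifnot(length(root$value) == 1L)
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  root$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

# ---- elementary ops ---------------------------------------------------------

tp_matmul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  node_new(tape, av %*% bv, backfn = function(g) {
    accum_grad(a, g %*% t(bv))
    accum_grad(b, t(av) %*% g)
  })
}

# a: B x n, b: 1 x n bias broadcast over rows (or identical shape)
tp_add <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  if (identical(dim(av), dim(bv))) {
    node_new(tape, av + bv, backfn = function(g) {
      accum_grad(a, g); accum_grad(b, g)
    })
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    node_new(tape, sweep(av, 2L, bv[1L, ], "+"), backfn = function(g) {
      accum_grad(a, g)
      accum_grad(b, matrix(colSums(g), 1L))
    })
  } else stop("tp_add: incompatible shapes ", paste(dim(av), collapse = "x"),
              " vs ", paste(dim(bv), collapse = "x"))
}

tp_mul <- function(tape, a, b) {   # elementwise, same shape
  av <- a$value; bv <- b$value
  stopifnot(identical(dim(av), dim(bv)))
  node_new(tape, av * bv, backfn = function(g) {
    accum_grad(a, g * bv)
    accum_grad(b, g * av)
  })
}

tp_scale <- function(tape, a, k) {  # constant scalar
  node_new(tape, a$value * k, backfn = function(g) accum_grad(a, g * k))
}

tp_relu <- function(tape, a) {
  av <- a$value
  node_new(tape, pmax(av, 0), backfn = function(g) accum_grad(a, g * (av > 0)))
}

tp_sigmoid <- function(tape, a) {
  sv <- 1 / (1 + exp(-a$value))
  node_new(tape, sv, backfn = function(g) accum_grad(a, g * sv * (1 - sv)))
}

tp_softmax_rows <- function(tape, a) {
  av <- a$value
  ex <- exp(av - apply(av, 1L, max))
  sv <- ex / rowSums(ex)
  node_new(tape, sv, backfn = function(g) {
    accum_grad(a, sv * (g - rowSums(g * sv)))
  })
}

tp_slice_cols <- function(tape, a, cols) {
  av <- a$value
  node_new(tape, av[, cols, drop = FALSE], backfn = function(g) {
    da <- matrix(0, nrow(av), ncol(av))
    da[, cols] <- g
    accum_grad(a, da)
  })
}

tp_concat_cols <- function(tape, nodes) {
  vals <- lapply(nodes, function(nd) nd$value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  node_new(tape, do.call(cbind, vals), backfn = function(g) {
    for (i in seq_along(nodes))
      accum_grad(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
  })
}

# mean over column groups: x (B x D) -> (B x G); groups = list of col indices
tp_group_means <- function(tape, x, groups) {
  xv <- x$value
  out <- vapply(groups, function(cols)
    rowMeans(xv[, cols, drop = FALSE]), numeric(nrow(xv)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(xv))
  node_new(tape, out, backfn = function(g) {
    dx <- matrix(0, nrow(xv), ncol(xv))
    for (j in seq_along(groups)) {
      cols <- groups[[j]]
      dx[, cols] <- dx[, cols] + g[, j] / length(cols)
    }
    accum_grad(x, dx)
  })
}

# Embedding row gather: table ((V+1) x d), ids in 0..V (0 = padding/unknown).
tp_embed <- function(tape, table, ids) {
  tv <- table$value
  ids <- as.integer(ids)
  node_new(tape, tv[ids + 1L, , drop = FALSE], backfn = function(g) {
    acc <- rowsum(g, group = ids, reorder = FALSE)
    rows <- as.integer(rownames(acc)) + 1L
    dT <- matrix(0, nrow(tv), ncol(tv))
    dT[rows, ] <- acc
    accum_grad(table, dT)
  })
}

# weighted sum of expert outputs: w (B x E), experts list of E nodes (B x d)
tp_weighted_sum <- function(tape, w, experts) {
  wv <- w$value
  ev <- lapply(experts, function(nd) nd$value)
  out <- matrix(0, nrow(wv), ncol(ev[[1L]]))
  for (i in seq_along(ev)) out <- out + wv[, i] * ev[[i]]
  node_new(tape, out, backfn = function(g) {
    dw <- matrix(0, nrow(wv), ncol(wv))
    for (i in seq_along(ev)) {
      accum_grad(experts[[i]], g * wv[, i])
      dw[, i] <- rowSums(g * ev[[i]])
    }
    accum_grad(w, dw)
  })
}

# ---- fused sequence ops -----------------------------------------------------
#
# Sequences are stored position-major: a batch of B cases padded to L
# positions is a (B*L) x d matrix whose rows (l-1)*B + (1:B) hold position l.

seq_rows <- function(l, B) (l - 1L) * B + seq_len(B)

# Masked scaled dot-product attention for one head.
# q, k, v: (B*L) x dh position-major; mask: B x L, 1 = real token, 0 = pad.
# Keys at padded positions receive -1e30 before the softmax (exactly zero
# weight after exp underflow); fully padded query rows fall back to uniform
# weights but are discarded by the downstream masked pooling.
tp_seq_attention <- function(tape, q, k, v, mask) {
  qv <- q$value; kv <- k$value; vv <- v$value
  B <- nrow(mask); L <- ncol(mask); dh <- ncol(qv)
  scale <- 1 / sqrt(dh)
  neg <- (1 - mask) * -1e30

  sc <- matrix(0, B * L, L)             # row (l1-1)*B+b, col l2
  for (l1 in seq_len(L)) {
    r1 <- seq_rows(l1, B)
    for (l2 in seq_len(L)) {
      sc[r1, l2] <- rowSums(qv[r1, , drop = FALSE] * kv[seq_rows(l2, B), , drop = FALSE]) *
        scale + neg[, l2]
    }
  }
  ex <- exp(sc - apply(sc, 1L, max))
  A <- ex / rowSums(ex)

  out <- matrix(0, B * L, dh)
  for (l1 in seq_len(L)) {
    r1 <- seq_rows(l1, B)
    for (l2 in seq_len(L)) {
      out[r1, ] <- out[r1, ] + A[r1, l2] * vv[seq_rows(l2, B), , drop = FALSE]
    }
  }

  node_new(tape, out, backfn = function(g) {
    dA <- matrix(0, B * L, L)
    dV <- matrix(0, B * L, dh)
    for (l1 in seq_len(L)) {
      r1 <- seq_rows(l1, B)
      g1 <- g[r1, , drop = FALSE]
      for (l2 in seq_len(L)) {
        r2 <- seq_rows(l2, B)
        dA[r1, l2] <- rowSums(g1 * vv[r2, , drop = FALSE])
        dV[r2, ] <- dV[r2, ] + A[r1, l2] * g1
      }
    }
    dS <- A * (dA - rowSums(dA * A))    # softmax backward per row
    dQ <- matrix(0, B * L, dh)
    dK <- matrix(0, B * L, dh)
    for (l1 in seq_len(L)) {
      r1 <- seq_rows(l1, B)
      for (l2 in seq_len(L)) {
        r2 <- seq_rows(l2, B)
        dQ[r1, ] <- dQ[r1, ] + dS[r1, l2] * kv[r2, , drop = FALSE] * scale
        dK[r2, ] <- dK[r2, ] + dS[r1, l2] * qv[r1, , drop = FALSE] * scale
      }
    }
    accum_grad(q, dQ); accum_grad(k, dK); accum_grad(v, dV)
  })
}

# Masked mean pooling over positions: x (B*L) x d position-major -> B x d.
tp_masked_mean <- function(tape, x, mask) {
  xv <- x$value
  B <- nrow(mask); L <- ncol(mask); d <- ncol(xv)
  cnt <- pmax(rowSums(mask), 1)
  out <- matrix(0, B, d)
  for (l in seq_len(L)) out <- out + mask[, l] * xv[seq_rows(l, B), , drop = FALSE]
  out <- out / cnt
  node_new(tape, out, backfn = function(g) {
    dx <- matrix(0, B * L, d)
    gm <- g / cnt
    for (l in seq_len(L)) dx[seq_rows(l, B), ] <- mask[, l] * gm
    accum_grad(x, dx)
  })
}

# ---- scene-conditioned (meta) dense layer -----------------------------------
#
# Weights and bias are generated from the scene embedding:
#   flat = G %*% e_scene + g0;  W = matrix(flat[1:(in*out)], out, in)  (column-
#   major reshape);  b = flat[in*out + (1:out)];  y = act(x %*% t(W) + b).
# Scene ids are categorical, so rows are processed grouped by unique scene;
# per-scene weight matrices are materialized once per batch.
#
# x: B x in; scene_table: ((Vs+1) x ds) embedding table node; scene_ids: B
# integers in 0..Vs; G: (in*out+out) x ds; g0: (in*out+out) x 1.
tp_meta_dense <- function(tape, x, scene_table, scene_ids, G, g0, out_dim,
                          activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  xv <- x$value
  in_dim <- ncol(xv)
  B <- nrow(xv)
  Gv <- G$value; g0v <- g0$value; Tv <- scene_table$value
  stopifnot(nrow(Gv) == in_dim * out_dim + out_dim, ncol(Gv) == ncol(Tv))

  uids <- sort(unique(scene_ids))
  out <- matrix(0, B, out_dim)
  ctx <- vector("list", length(uids))   # per-group forward context
  for (gi in seq_along(uids)) {
    sid <- uids[[gi]]
    I <- which(scene_ids == sid)
    e <- Tv[sid + 1L, ]
    flat <- drop(Gv %*% e) + g0v[, 1L]
    W <- matrix(flat[seq_len(in_dim * out_dim)], out_dim, in_dim)
    b <- flat[in_dim * out_dim + seq_len(out_dim)]
    pre <- sweep(xv[I, , drop = FALSE] %*% t(W), 2L, b, "+")
    y <- if (activation == "relu") pmax(pre, 0) else pre
    out[I, ] <- y
    ctx[[gi]] <- list(sid = sid, I = I, W = W, pre = pre)
  }

  node_new(tape, out, backfn = function(g) {
    dx <- matrix(0, B, in_dim)
    dG <- matrix(0, nrow(Gv), ncol(Gv))
    dg0 <- matrix(0, nrow(g0v), 1L)
    dT <- matrix(0, nrow(Tv), ncol(Tv))
    for (gi in seq_along(ctx)) {
      cx <- ctx[[gi]]
      I <- cx$I
      gI <- g[I, , drop = FALSE]
      dpre <- if (activation == "relu") gI * (cx$pre > 0) else gI
      dx[I, ] <- dpre %*% cx$W
      dW <- t(dpre) %*% xv[I, , drop = FALSE]     # out x in
      db <- colSums(dpre)
      dflat <- c(as.vector(dW), db)
      e <- Tv[cx$sid + 1L, ]
      dG <- dG + dflat %o% e
      dg0[, 1L] <- dg0[, 1L] + dflat
      dT[cx$sid + 1L, ] <- dT[cx$sid + 1L, ] + drop(crossprod(Gv, dflat))
    }
    accum_grad(x, dx)
    accum_grad(G, dG)
    accum_grad(g0, dg0)
    accum_grad(scene_table, dT)
  })
}

# ---- losses -----------------------------------------------------------------

# Numerically stable sigmoid cross-entropy with logits, mean over entries,
# returned as a 1x1 node. targets: 0/1 matrix of the same shape.
tp_bce_mean <- function(tape, logits, targets) {
  z <- logits$value
  n <- length(z)
  val <- sum(pmax(z, 0) - z * targets + log1p(exp(-abs(z)))) / n
  node_new(tape, matrix(val, 1L, 1L), backfn = function(g) {
    accum_grad(logits, g[1L, 1L] * (1 / (1 + exp(-z)) - targets) / n)
  })
}

# Softmax cross-entropy over rows with (possibly multi-hot, row-normalized)
# target distributions; mean over rows.
tp_softmax_xent_mean <- function(tape, logits, targets) {
  z <- logits$value
  rs <- rowSums(targets)
  tgt <- targets / ifelse(rs > 0, rs, 1)
  ex <- exp(z - apply(z, 1L, max))
  p <- ex / rowSums(ex)
  n <- nrow(z)
  val <- -sum(tgt * log(pmax(p, 1e-300))) / n
  node_new(tape, matrix(val, 1L, 1L), backfn = function(g) {
    accum_grad(logits, g[1L, 1L] * (p * rowSums(tgt) - tgt) / n)
  })
}
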