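#' Model configuration
#'
#' Architecture and optimisation settings for the localization network.
#' The default configuration is the full-size architecture: two stacked
#' bidirectional LSTM layers whose concatenated output dimension is 180
#' (90 per direction), a 41-head self-attention layer with inner dimension
#' 369, and a dense layer of `8 * n_org` units reshaped into the
#' suborganelle score matrix.  The flattened attention embedding passed to
#' the dense layer therefore has `2 * hidden * heads` elements (7380 by
#' default).
#'
#' @param n_org Number of organelles (columns of the score matrix); 10 for
#'   the bundled hierarchy.
#' @param hidden LSTM width per direction (default 90, so the bidirectional
#'   output dimension is 180).
#' @param attn_inner Inner dimension of the attention MLP (rows of `Ws1`),
#'   default 369.
#' @param heads Number of attention heads (rows of `Ws2`), default 41.
#' @param encode_len Input encoding length, default 1000.
#' @param attention_reg_weight Weight of the attention orthogonality
#'   penalty added to the loss, default `1e-3`.
#' @param dropout_lstm,dropout_dense Dropout rates on the LSTM outputs and
#'   on the flattened embedding, default 0.1 each.
#' @param lr,batch_size,beta1,beta2,adam_eps Adam optimiser settings.
#' @param grad_clip Global-norm gradient clip per minibatch (0 disables;
#'   default 5).
#' @param weight_decay Decoupled weight decay on weight matrices (0
#'   disables; biases are exempt).
#' @param empty_cells `"zero"` (default): empty hierarchy slots carry
#'   target 0 and participate in the cell-level loss; `"mask"`: they are
#'   excluded from the loss average.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return A `loc_config` list.
#' @export
loc_config <- function(n_org = 10, hidden = 90, attn_inner = 369, heads = 41,
                       encode_len = 1000, attention_reg_weight = 1e-3,
                       dropout_lstm = 0.1, dropout_dense = 0.1,
                       lr = 1e-3, batch_size = 32,
                       beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                       grad_clip = 5, weight_decay = 0,
                       empty_cells = c("zero", "mask"), seed = 1L) {
  empty_cells <- match.arg(empty_cells)
  stopifnot(n_org >= 1, n_org <= 10, hidden >= 1, heads >= 1, attn_inner >= 1,
            encode_len %% 2 == 0, attention_reg_weight >= 0,
            dropout_lstm >= 0, dropout_lstm < 1,
            dropout_dense >= 0, dropout_dense < 1)
  structure(list(n_org = as.integer(n_org), hidden = as.integer(hidden),
                 attn_inner = as.integer(attn_inner), heads = as.integer(heads),
                 encode_len = as.integer(encode_len), feat_dim = 25L,
                 dense_out = as.integer(8 * n_org),
                 flatten_len = as.integer(2 * hidden * heads),
                 attention_reg_weight = attention_reg_weight,
                 dropout_lstm = dropout_lstm, dropout_dense = dropout_dense,
                 lr = lr, batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 grad_clip = grad_clip, weight_decay = weight_decay,
                 empty_cells = empty_cells, seed = as.integer(seed)),
            class = "loc_config")
}

#' @export
print.loc_config <- function(x, ...) {
  cat(sprintf(paste0("<loc_config> 2x biLSTM(%d/dir -> %d), %d heads ",
                     "(inner %d), dense %d, flatten %d, L=%d\n"),
              x$hidden, 2 * x$hidden, x$heads, x$attn_inner,
              x$dense_out, x$flatten_len, x$encode_len))
  invisible(x)
}

# Glorot-uniform initial parameters; forget-gate biases start at 1.
init_params <- function(cfg) {
  set.seed(cfg$seed)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  lstm <- function(in_dim, u) {
    b <- matrix(0, 4 * u, 1)
    b[(u + 1):(2 * u), 1] <- 1
    list(W = glorot(4 * u, in_dim), U = glorot(4 * u, u), b = b)
  }
  u <- cfg$hidden
  p <- list()
  l1f <- lstm(cfg$feat_dim, u); l1b <- lstm(cfg$feat_dim, u)
  l2f <- lstm(2 * u, u); l2b <- lstm(2 * u, u)
  p[["l1f.W"]] <- l1f$W; p[["l1f.U"]] <- l1f$U; p[["l1f.b"]] <- l1f$b
  p[["l1b.W"]] <- l1b$W; p[["l1b.U"]] <- l1b$U; p[["l1b.b"]] <- l1b$b
  p[["l2f.W"]] <- l2f$W; p[["l2f.U"]] <- l2f$U; p[["l2f.b"]] <- l2f$b
  p[["l2b.W"]] <- l2b$W; p[["l2b.U"]] <- l2b$U; p[["l2b.b"]] <- l2b$b
  p[["Ws1"]] <- glorot(cfg$attn_inner, 2 * u)
  p[["Ws2"]] <- glorot(cfg$heads, cfg$attn_inner)
  p[["Wd"]] <- glorot(cfg$dense_out, cfg$flatten_len)
  p[["bd"]] <- matrix(0, cfg$dense_out, 1)
  p
}

zero_params <- function(params) lapply(params, function(m) m * 0)

# Valid-position input matrix (features x positions) for the C++ core.
enc_to_x <- function(enc) {
  n <- sum(enc$mask)
  if (n == 0) .stopf("all positions are masked: nothing to encode")
  t(enc$features[seq_len(n), , drop = FALSE])
}

#' Run the forward model on one encoded protein
#'
#' @param enc A `loc_encoded` input.
#' @param cfg A `loc_config`.
#' @param params Model parameters (from [init_params] via [train_submodel],
#'   or a trained model's `$params`).
#' @param hierarchy Optional `loc_hierarchy` used to name the score matrix.
#' @return A `loc_scores` object: `sub` (8 x n_org matrix of post-sigmoid
#'   probabilities), `org` (per-organelle score, the column maximum of
#'   `sub`), `A` (heads x encode_len attention matrix, zero at masked
#'   positions), `M` (embedding matrix), `n_valid`.
#' @export
forward <- function(enc, cfg, params, hierarchy = NULL) {
  X <- enc_to_x(enc)
  out <- cpp_forward(params, X, cfg$n_org)
  sub <- matrix(out$scores, nrow = 8, ncol = cfg$n_org)
  org <- as.numeric(out$org)
  if (!is.null(hierarchy)) {
    colnames(sub) <- hierarchy$organelles
    names(org) <- hierarchy$organelles
  }
  A <- matrix(0, nrow = cfg$heads, ncol = cfg$encode_len)
  A[, seq_len(ncol(out$A))] <- out$A
  structure(list(sub = sub, org = org, A = A, M = out$M,
                 n_valid = ncol(out$A), accession = enc$accession),
            class = "loc_scores")
}

#' @export
print.loc_scores <- function(x, ...) {
  cat(sprintf("<loc_scores> %s: top organelle %s (%.3f)\n",
              x$accession %||% "?",
              if (!is.null(names(x$org))) names(x$org)[which.max(x$org)]
              else which.max(x$org),
              max(x$org)))
  invisible(x)
}

#' Attention orthogonality penalty
#'
#' The squared Frobenius norm of `A A' - I`: zero when the attention rows
#' are orthonormal, and maximal when heads duplicate each other.  Added to
#' the training loss (scaled by `attention_reg_weight`) to push different
#' heads towards different sequence regions.
#'
#' @param A Attention matrix (heads x positions), rows summing to 1.
#' @return Non-negative scalar.
#' @export
attention_penalty <- function(A) {
  AAt <- A %*% t(A)
  sum((AAt - diag(nrow(A)))^2)
}

.bce <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

cell_mask_vec <- function(cfg, hierarchy = NULL) {
  if (cfg$empty_cells == "zero" || is.null(hierarchy))
    return(rep(1, cfg$dense_out))
  m <- rep(0, cfg$dense_out)
  m[(hierarchy$cells$col - 1L) * 8L + hierarchy$cells$row] <- 1
  m
}

#' Two-level training loss for a fully annotated sample
#'
#' Binary cross-entropy averaged over the 8 x n_org matrix cells (cell
#' term), plus binary cross-entropy averaged over the organelle scores
#' (organelle term), plus the weighted attention penalty.
#'
#' @param scores A `loc_scores` prediction.
#' @param target Target list from [labels_to_matrix()].
#' @param cfg A `loc_config`.
#' @param hierarchy Optional hierarchy, used when `cfg$empty_cells ==
#'   "mask"` to restrict the cell average to occupied cells.
#' @return Scalar loss.
#' @export
loss_lv2 <- function(scores, target, cfg, hierarchy = NULL) {
  cmask <- cell_mask_vec(cfg, hierarchy)
  p <- as.numeric(scores$sub)
  t2 <- as.numeric(target$matrix)
  cell_term <- sum(.bce(p, t2) * cmask) / sum(cmask)
  org_term <- mean(.bce(as.numeric(scores$org), as.numeric(target$org)))
  Avalid <- scores$A[, seq_len(scores$n_valid), drop = FALSE]
  cell_term + org_term + cfg$attention_reg_weight * attention_penalty(Avalid)
}

#' Organelle-only training loss for a level-1 annotated sample
#'
#' Used for samples that carry subcellular but no suborganellar labels:
#' only the organelle (post max-pooling) term and the attention penalty.
#'
#' @inheritParams loss_lv2
#' @return Scalar loss.
#' @export
loss_lv1 <- function(scores, target, cfg) {
  org_term <- mean(.bce(as.numeric(scores$org), as.numeric(target$org)))
  Avalid <- scores$A[, seq_len(scores$n_valid), drop = FALSE]
  org_term + cfg$attention_reg_weight * attention_penalty(Avalid)
}

#' Categorical cross-entropy for the single-label model variant
#'
#' The variant used when benchmarking against single-label predictors: a
#' softmax over organelle logits with one-hot targets.
#'
#' @param logits Numeric vector of per-class logits.
#' @param target One-hot numeric vector of the same length.
#' @return Scalar loss `-sum(t * log softmax(logits))`.
#' @export
loss_variant <- function(logits, target) {
  if (length(logits) != length(target) || !all(target %in% c(0, 1)) ||
      sum(target) != 1)
    .stopf("target must be a one-hot vector matching the logits")
  z <- logits - max(logits)
  -sum(target * (z - log(sum(exp(z)))))
}
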