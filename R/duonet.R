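# Dual-modality transformer aggregator.
#
# One parameter-shared transformer trunk (linear projection, learned class
# token, pre-norm multi-head self-attention blocks with GELU feed-forward)
# is applied to the H&E and the IHC tile-embedding bags; the two final
# class-token states are concatenated (H&E block first) and passed to an
# MLP head producing a single biomarker logit. A missing or dropped branch
# contributes a zero feature vector, which, combined with branch dropout
# during training, is what makes single-modality inference possible.
# Forward, backward and the AdamW optimizer are implemented directly with
# base-R matrix algebra; there are no positional encodings, so the model is
# permutation-invariant over tiles, as multiple-instance learning requires.

MODALITIES <- c("HE", "IHC")

#' Aggregator architecture configuration
#'
#' @param embed_dim_in input tile-embedding width (default 768).
#' @param model_dim transformer width (default 512); must be divisible by
#'   `n_heads`.
#' @param n_layers number of transformer blocks (default 2).
#' @param n_heads attention heads (default 8).
#' @param mlp_hidden hidden width of the classification head (default 512).
#' @param ffn_mult feed-forward expansion factor inside each block
#'   (default 2).
#' @param p_branch_dropout probability that one branch is omitted at a
#'   training step (default 0.3).
#' @return object of class `duonet_config`.
#' @export
duonet_config <- function(embed_dim_in = 768L, model_dim = 512L,
                          n_layers = 2L, n_heads = 8L, mlp_hidden = 512L,
                          ffn_mult = 2L, p_branch_dropout = 0.3) {
  if (model_dim %% n_heads != 0) stopf("model_dim must be divisible by n_heads")
  if (n_layers < 1) stopf("n_layers must be >= 1")
  if (!(p_branch_dropout >= 0 && p_branch_dropout < 1)) {
    stopf("p_branch_dropout must lie in [0, 1)")
  }
  structure(list(embed_dim_in = as.integer(embed_dim_in),
                 model_dim = as.integer(model_dim),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 mlp_hidden = as.integer(mlp_hidden),
                 ffn_mult = as.integer(ffn_mult),
                 p_branch_dropout = p_branch_dropout),
            class = "duonet_config")
}

rmat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Initialise an untrained aggregator
#'
#' @param config a [duonet_config()].
#' @param seed integer seed for the weight initialisation.
#' @return object of class `duonet` holding `config` and `params`.
#' @export
duonet_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "duonet_config"))
  d <- config$embed_dim_in; m <- config$model_dim
  ff <- m * config$ffn_mult; mh <- config$mlp_hidden
  with_seed(seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) {
      list(g1 = rep(1, m), b1 = rep(0, m),
           Wq = rmat(m, m), bq = rep(0, m),
           Wk = rmat(m, m), bk = rep(0, m),
           Wv = rmat(m, m), bv = rep(0, m),
           Wo = rmat(m, m), bo = rep(0, m),
           g2 = rep(1, m), b2 = rep(0, m),
           W1 = rmat(m, ff), b1f = rep(0, ff),
           W2 = rmat(ff, m), b2f = rep(0, m))
    })
    params <- list(
      trunk = list(Wp = rmat(d, m), bp = rep(0, m), cls = rmat(1, m),
                   layers = layers, gf = rep(1, m), bf = rep(0, m)),
      head = list(Wh1 = rmat(2 * m, mh), bh1 = rep(0, mh),
                  Wh2 = rmat(mh, 1), bh2 = 0)
    )
    structure(list(config = config, params = params), class = "duonet")
  })
}

# ---- numeric primitives ----------------------------------------------------

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  n <- nrow(X)
  Y <- xhat * rep(g, each = n) + rep(b, each = n)
  list(Y = Y, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, g) {
  dxhat <- dY * rep(g, each = nrow(dY))
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  dX <- cache$inv *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dX = dX, dg = dg, db = db)
}

softmax_rows <- function(S) {
  # global-max shift: cheaper than per-row and equally overflow-safe here
  E <- exp(S - max(S))
  E / rowSums(E)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

addb <- function(X, b) X + rep(b, each = nrow(X))

# ---- trunk -----------------------------------------------------------------

trunk_forward <- function(trunk, X, n_heads, cache = FALSE,
                          collect_attention = TRUE) {
  m <- ncol(trunk$Wp)
  dh <- m %/% n_heads
  H <- addb(X %*% trunk$Wp, trunk$bp)
  Tk <- rbind(trunk$cls, H)
  n <- nrow(Tk)
  attn <- vector("list", length(trunk$layers))
  caches <- if (cache) vector("list", length(trunk$layers)) else NULL
  for (l in seq_along(trunk$layers)) {
    ly <- trunk$layers[[l]]
    A <- layernorm_fwd(Tk, ly$g1, ly$b1)
    Q <- addb(A$Y %*% ly$Wq, ly$bq)
    K <- addb(A$Y %*% ly$Wk, ly$bk)
    V <- addb(A$Y %*% ly$Wv, ly$bv)
    O <- matrix(0, n, m)
    P_heads <- vector("list", n_heads)
    A_arr <- if (collect_attention) array(0, dim = c(n_heads, n, n))
    for (h in seq_len(n_heads)) {
      cols <- (h - 1) * dh + seq_len(dh)
      S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
      P <- softmax_rows(S)
      P_heads[[h]] <- P
      if (collect_attention) A_arr[h, , ] <- P
      O[, cols] <- P %*% V[, cols, drop = FALSE]
    }
    Aout <- addb(O %*% ly$Wo, ly$bo)
    T1 <- Tk + Aout
    B <- layernorm_fwd(T1, ly$g2, ly$b2)
    Z1 <- addb(B$Y %*% ly$W1, ly$b1f)
    G <- gelu(Z1)
    Z2 <- addb(G %*% ly$W2, ly$b2f)
    attn[[l]] <- A_arr
    if (cache) {
      caches[[l]] <- list(Tin = Tk, A = A, Q = Q, K = K, V = V,
                          P = P_heads, O = O, T1 = T1, B = B, Z1 = Z1, G = G)
    }
    Tk <- T1 + Z2
  }
  Fc <- layernorm_fwd(Tk, trunk$gf, trunk$bf)
  list(feat = Fc$Y[1, ], attention = attn,
       cache = if (cache) list(layers = caches, T_last = Tk, Fc = Fc, X = X))
}

trunk_backward <- function(trunk, cache, dfeat, n_heads) {
  m <- ncol(trunk$Wp)
  dh <- m %/% n_heads
  g <- list(Wp = NULL, bp = NULL, cls = NULL, layers = NULL, gf = NULL, bf = NULL)
  n <- nrow(cache$T_last)
  dTf <- matrix(0, n, m)
  dTf[1, ] <- dfeat
  lnf <- layernorm_bwd(dTf, cache$Fc, trunk$gf)
  g$gf <- lnf$dg; g$bf <- lnf$db
  dT <- lnf$dX
  g$layers <- vector("list", length(trunk$layers))
  for (l in rev(seq_along(trunk$layers))) {
    ly <- trunk$layers[[l]]
    cc <- cache$layers[[l]]
    # T_out = T1 + Z2, Z2 = gelu(LN2(T1) W1 + b1f) W2 + b2f
    dZ2 <- dT
    dG <- dZ2 %*% t(ly$W2)
    dW2 <- t(cc$G) %*% dZ2
    db2f <- colSums(dZ2)
    dZ1 <- dG * gelu_grad(cc$Z1)
    dBY <- dZ1 %*% t(ly$W1)
    dW1 <- t(cc$B$Y) %*% dZ1
    db1f <- colSums(dZ1)
    ln2 <- layernorm_bwd(dBY, cc$B, ly$g2)
    dT1 <- dT + ln2$dX
    # T1 = Tin + (O Wo + bo)
    dAout <- dT1
    dO <- dAout %*% t(ly$Wo)
    dWo <- t(cc$O) %*% dAout
    dbo <- colSums(dAout)
    dQ <- matrix(0, n, m); dK <- matrix(0, n, m); dV <- matrix(0, n, m)
    for (h in seq_len(n_heads)) {
      cols <- (h - 1) * dh + seq_len(dh)
      P <- cc$P[[h]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- cc$V[, cols, drop = FALSE]
      dP <- dOh %*% t(Vh)
      dV[, cols] <- t(P) %*% dOh
      dS <- P * (dP - rowSums(dP * P))
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- t(dS) %*% cc$Q[, cols, drop = FALSE] / sqrt(dh)
    }
    dAY <- dQ %*% t(ly$Wq) + dK %*% t(ly$Wk) + dV %*% t(ly$Wv)
    ln1 <- layernorm_bwd(dAY, cc$A, ly$g1)
    dT <- dT1 + ln1$dX
    g$layers[[l]] <- list(
      g1 = ln1$dg, b1 = ln1$db,
      Wq = t(cc$A$Y) %*% dQ, bq = colSums(dQ),
      Wk = t(cc$A$Y) %*% dK, bk = colSums(dK),
      Wv = t(cc$A$Y) %*% dV, bv = colSums(dV),
      Wo = dWo, bo = dbo,
      g2 = ln2$dg, b2 = ln2$db,
      W1 = dW1, b1f = db1f, W2 = dW2, b2f = db2f)
  }
  g$cls <- dT[1, , drop = FALSE]
  dH <- dT[-1, , drop = FALSE]
  g$Wp <- t(cache$X) %*% dH
  g$bp <- colSums(dH)
  list(grads = g, dX = dH %*% t(trunk$Wp))
}

# ---- branch dropout --------------------------------------------------------

#' Branch-dropout draw
#'
#' With both modalities available, one branch is dropped with probability
#' `p` (which branch is chosen uniformly); with a single modality available
#' that branch is always kept. The kept set is never empty. Interpreting
#' `p` as the per-step probability that some branch is omitted follows the
#' mechanism's description of omitting one of the branches during training.
#'
#' @param available character subset of `c("HE", "IHC")`.
#' @param p drop probability.
#' @return character vector of kept branches.
#' @export
branch_dropout_mask <- function(available, p = 0.3) {
  available <- intersect(MODALITIES, available)
  if (length(available) == 0) stopf("available branch set must be non-empty")
  if (length(available) == 1 || stats::runif(1) >= p) return(available)
  sample(available, 1)
}

# ---- full forward / backward ----------------------------------------------

as_bag_matrix <- function(bag, width) {
  if (is.null(bag)) return(NULL)
  X <- if (inherits(bag, "embedding_bag")) bag$embeddings else as.matrix(bag)
  if (ncol(X) != width) {
    stopf("bag width %d does not match model input width %d", ncol(X), width)
  }
  if (any(!is.finite(X))) stopf("NaN or Inf in embeddings")
  X
}

#' Forward pass of the dual-branch aggregator
#'
#' Runs each present (and kept) branch through the shared trunk, fills a
#' missing or dropped branch with the zero feature vector, concatenates the
#' branch features (H&E first) and applies the MLP head. Inference is
#' deterministic; attention tensors are recorded per layer and head for
#' explainability.
#'
#' @param model a `duonet`.
#' @param he,ihc [embedding_bag()]s or plain embedding matrices (may be
#'   `NULL` when the mode does not require them).
#' @param mode `"DUET"`, `"HE_ONLY"` or `"IHC_ONLY"`.
#' @param keep optional subset of branches to keep (from
#'   [branch_dropout_mask()] during training).
#' @param cache keep intermediate activations for [duonet_backward()].
#' @param collect_attention record per-layer, per-head attention tensors
#'   (disabled inside the training loop to save allocation).
#' @return a `forward_trace`: list with `probability`, `logit`,
#'   `branch_kept`, per-branch `attention` (per layer,
#'   `heads x tokens x tokens` arrays over class token + tiles), and
#'   activation caches when requested.
#' @export
duonet_forward <- function(model, he = NULL, ihc = NULL,
                           mode = c("DUET", "HE_ONLY", "IHC_ONLY"),
                           keep = NULL, cache = FALSE,
                           collect_attention = TRUE) {
  stopifnot(inherits(model, "duonet"))
  mode <- match.arg(mode)
  cfg <- model$config
  need <- switch(mode, DUET = MODALITIES, HE_ONLY = "HE", IHC_ONLY = "IHC")
  bags <- list(HE = if ("HE" %in% need) as_bag_matrix(he, cfg$embed_dim_in),
               IHC = if ("IHC" %in% need) as_bag_matrix(ihc, cfg$embed_dim_in))
  for (mdl in need) {
    if (is.null(bags[[mdl]])) stopf("mode %s requires an %s bag", mode, mdl)
  }
  kept <- if (is.null(keep)) need else intersect(need, keep)
  if (length(kept) == 0) stopf("kept branch set must be non-empty")

  m <- cfg$model_dim
  feats <- list(HE = rep(0, m), IHC = rep(0, m))
  attn <- list(HE = NULL, IHC = NULL)
  caches <- list(HE = NULL, IHC = NULL)
  for (mdl in kept) {
    br <- trunk_forward(model$params$trunk, bags[[mdl]], cfg$n_heads, cache,
                        collect_attention)
    feats[[mdl]] <- br$feat
    attn[[mdl]] <- br$attention
    caches[[mdl]] <- br$cache
  }
  z <- c(feats$HE, feats$IHC)
  hd <- model$params$head
  h1pre <- as.vector(z %*% hd$Wh1) + hd$bh1
  h1 <- gelu(h1pre)
  logit <- sum(h1 * hd$Wh2) + hd$bh2
  structure(list(probability = stats::plogis(logit), logit = logit,
                 branch_kept = kept, attention = attn,
                 mode = mode,
                 cache = if (cache) list(z = z, h1pre = h1pre, h1 = h1,
                                         trunks = caches)),
            class = "forward_trace")
}

#' @export
print.forward_trace <- function(x, ...) {
  cat(sprintf("forward trace: p = %.4f (logit %.4f), branches kept: %s\n",
              x$probability, x$logit, paste(x$branch_kept, collapse = "+")))
  invisible(x)
}

# Binary cross-entropy gradient through the whole model. Returns a gradient
# tree parallel to model$params plus the per-branch input gradients.
duonet_backward <- function(model, trace, y) {
  stopifnot(inherits(trace, "forward_trace"), !is.null(trace$cache))
  cfg <- model$config
  m <- cfg$model_dim
  hd <- model$params$head
  cc <- trace$cache
  dlogit <- trace$probability - y
  dh1 <- dlogit * as.vector(hd$Wh2)
  dh1pre <- dh1 * gelu_grad(cc$h1pre)
  gh <- list(Wh1 = outer(cc$z, dh1pre), bh1 = dh1pre,
             Wh2 = matrix(dlogit * cc$h1, ncol = 1), bh2 = dlogit)
  dz <- as.vector(hd$Wh1 %*% dh1pre)
  dfeat <- list(HE = dz[seq_len(m)], IHC = dz[m + seq_len(m)])
  gt <- NULL
  dX <- list(HE = NULL, IHC = NULL)
  for (mdl in trace$branch_kept) {
    bb <- trunk_backward(model$params$trunk, cc$trunks[[mdl]], dfeat[[mdl]],
                         cfg$n_heads)
    dX[[mdl]] <- bb$dX
    gt <- if (is.null(gt)) bb$grads else tree_map(`+`, gt, bb$grads)
  }
  if (is.null(gt)) gt <- tree_map(function(x) x * 0, model$params$trunk)
  list(grads = list(trunk = gt, head = gh), dX = dX, loss = bce_loss(trace$logit, y))
}

bce_loss <- function(logit, y) {
  # numerically stable binary cross-entropy on the logit
  max(logit, 0) - logit * y + log1p(exp(-abs(logit)))
}

# ---- parameter-tree helpers ------------------------------------------------

tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- vector("list", length(t1))
    names(out) <- names(t1)
    for (i in seq_along(t1)) {
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

tree_flatten <- function(tree, prefix = "") {
  if (is.list(tree)) {
    out <- list()
    nms <- if (is.null(names(tree))) seq_along(tree) else names(tree)
    for (i in seq_along(tree)) {
      out <- c(out, tree_flatten(tree[[i]], paste0(prefix, nms[i], ".")))
    }
    out
  } else {
    stats::setNames(list(tree), sub("\\.$", "", prefix))
  }
}

#' Parameter counts of the aggregator
#'
#' Reports the shared transformer trunk and the classification head
#' separately. Because the trunk is parameter-shared between the two
#' branches, a dual-input model carries exactly the trunk of a
#' single-branch model; only the head sees the doubled (concatenated)
#' feature width.
#'
#' @param model a `duonet`.
#' @return list with `trunk`, `head` and `total` counts.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "duonet"))
  n_of <- function(tree) sum(vapply(tree_flatten(tree), length, numeric(1)))
  trunk <- n_of(model$params$trunk)
  head <- n_of(model$params$head)
  list(trunk = trunk, head = head, total = trunk + head)
}

# ---- AdamW -----------------------------------------------------------------

adamw_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params), t = 0L)
}

# Decoupled weight decay, applied to weight matrices only (biases, layer
# norms and the class token are not decayed, following common practice).
# Single fused traversal keeps the per-step overhead low.
adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  rec <- function(p, g, mm, vv) {
    if (is.list(p)) {
      out_p <- p; out_m <- mm; out_v <- vv
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], mm[[i]], vv[[i]])
        out_p[[i]] <- r[[1]]; out_m[[i]] <- r[[2]]; out_v[[i]] <- r[[3]]
      }
      list(out_p, out_m, out_v)
    } else {
      mm <- beta1 * mm + (1 - beta1) * g
      vv <- beta2 * vv + (1 - beta2) * g^2
      upd <- (mm / c1) / (sqrt(vv / c2) + eps)
      wd <- if (is.matrix(p) && nrow(p) > 1) weight_decay else 0
      list(p - lr * upd - lr * wd * p, mm, vv)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  state$m <- r[[2]]; state$v <- r[[3]]
  list(params = r[[1]], state = state)
}
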