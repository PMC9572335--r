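## Causal GPT2-style transformer mapping observation frames x_{0:t} to the
## mean of the filtering posterior q(z_t | x_{0:t}). Small by design (two
## layers, one head), sized for on-device sensor streams.
## Forward and reverse passes are hand-derived; the test suite checks the
## full gradient against central differences.

#' Transformer configuration
#'
#' @param n_layers number of decoder blocks (default 2; 0 is a valid
#'   ablation in which each output depends on its own token only)
#' @param n_heads attention heads (default 1)
#' @param embed_dim embedding width; for a single head this is also the key
#'   dimension d_K (default 32)
#' @param max_len longest supported input sequence (default 128)
#' @param token_in_dim input channels per time step (default 4)
#' @param out_dim output width, the latent dimension (default 2)
#' @return a `transformer_config`
#' @export
transformer_config <- function(n_layers = 2L, n_heads = 1L, embed_dim = 32L,
                               max_len = 128L, token_in_dim = 4L,
                               out_dim = 2L) {
  assert_that(n_layers >= 0 && n_heads >= 1 && embed_dim >= 1 &&
                max_len >= 1 && token_in_dim >= 1 && out_dim >= 1,
              "invalid_argument", "all transformer dimensions must be positive")
  assert_that(embed_dim %% n_heads == 0, "invalid_argument",
              "embed_dim must be divisible by n_heads")
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 embed_dim = as.integer(embed_dim), max_len = as.integer(max_len),
                 token_in_dim = as.integer(token_in_dim),
                 out_dim = as.integer(out_dim)),
            class = "transformer_config")
}

#' Initialize a causal transformer
#'
#' Learned linear token embedding plus learned positional embeddings,
#' pre-norm blocks (layer norm -> causal self-attention -> residual;
#' layer norm -> 4x GELU feed-forward -> residual), final layer norm and a
#' linear output head.
#'
#' @param cfg a [transformer_config()]
#' @param seed integer seed for the weight draw
#' @return an object of class `transformer` with `cfg` and `params`
#' @export
transformer_init <- function(cfg = transformer_config(), seed = 0L) {
  assert_that(inherits(cfg, "transformer_config"), "invalid_argument",
              "cfg must be a transformer_config")
  E <- cfg$embed_dim
  rnd <- function(nr, nc, scale = 0.02) matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
  params <- with_seed(seed, {
    layers <- lapply(seq_len(cfg$n_layers), function(l) list(
      ln1_g = rep(1, E), ln1_b = numeric(E),
      Wq = rnd(E, E), bq = numeric(E),
      Wk = rnd(E, E), bk = numeric(E),
      Wv = rnd(E, E), bv = numeric(E),
      Wo = rnd(E, E), bo = numeric(E),
      ln2_g = rep(1, E), ln2_b = numeric(E),
      Wf1 = rnd(E, 4L * E), bf1 = numeric(4L * E),
      Wf2 = rnd(4L * E, E), bf2 = numeric(E)
    ))
    list(W_tok = rnd(cfg$token_in_dim, E, 0.1), b_tok = numeric(E),
         P = rnd(cfg$max_len, E), layers = layers,
         lnf_g = rep(1, E), lnf_b = numeric(E),
         W_out = rnd(E, cfg$out_dim, 0.1), b_out = numeric(cfg$out_dim))
  })
  structure(list(cfg = cfg, params = params), class = "transformer")
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  s <- sqrt(v + eps)
  Xh <- Xc / s
  list(out = sweep(Xh, 2L, g, "*") + rep(b, each = nrow(X)),
       Xh = Xh, s = s, g = g)
}

layernorm_bwd <- function(cache, dY) {
  g <- cache$g; Xh <- cache$Xh; s <- cache$s
  dXh <- sweep(dY, 2L, g, "*")
  dg <- colSums(dY * Xh)
  db <- colSums(dY)
  m1 <- rowMeans(dXh)
  m2 <- rowMeans(dXh * Xh)
  dX <- (dXh - m1 - Xh * m2) / s
  list(dX = dX, dg = dg, db = db)
}

row_softmax_masked <- function(S) {
  # -Inf entries (masked) become exactly 0 after exp
  mx <- apply(S, 1L, function(r) max(r[is.finite(r)]))
  E <- exp(S - mx)
  E[!is.finite(E)] <- 0
  E / rowSums(E)
}

#' Masked scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_K)) V` with an optional causal mask that sets the
#' logits of future positions to `-Inf` before the softmax, so position `i`
#' attends only to positions `j <= i`.
#'
#' @param Q,K,V n x d matrices; `Q` and `K` must share the key dimension
#' @param causal_mask apply the autoregressive mask (default TRUE)
#' @return list with `outputs` (n x ncol(V)) and `weights` (n x n, rows sum
#'   to 1; strictly upper-triangular entries are exactly 0 under the mask)
#' @export
#' @examples
#' scaled_dot_attention(matrix(0, 2, 1), matrix(0, 2, 1),
#'                      matrix(1:2, 2, 1))$weights
scaled_dot_attention <- function(Q, K, V, causal_mask = TRUE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  assert_that(ncol(Q) == ncol(K), "invalid_argument",
              "Q and K must share the key dimension")
  assert_that(nrow(K) == nrow(V), "invalid_argument",
              "K and V must have the same number of positions")
  S <- Q %*% t(K) / sqrt(ncol(K))
  if (causal_mask) {
    assert_that(nrow(Q) == nrow(K), "invalid_argument",
                "causal masking needs square attention")
    S[upper.tri(S)] <- -Inf
  }
  W <- row_softmax_masked(S)
  list(outputs = W %*% V, weights = W)
}

#' Forward pass of the causal transformer
#'
#' @param tf a [transformer_init()] model
#' @param X an n x token_in_dim matrix of frames (n <= max_len)
#' @param params optional parameter override
#' @return list with `out` (n x out_dim), `attn` (per-layer n x n attention
#'   weights) and `cache` for [transformer_backward()]
#' @export
transformer_forward <- function(tf, X, params = tf$params) {
  cfg <- tf$cfg
  X <- as.matrix(X)
  n <- nrow(X)
  assert_that(n >= 1 && n <= cfg$max_len, "invalid_argument",
              sprintf("sequence length %d exceeds max_len %d", n, cfg$max_len))
  assert_that(ncol(X) == cfg$token_in_dim, "invalid_argument",
              "frame width does not match token_in_dim")
  assert_that(all(is.finite(X)), "invalid_argument", "frames must be finite")
  E <- cfg$embed_dim
  H <- X %*% params$W_tok
  H <- sweep(H, 2L, params$b_tok, "+") + params$P[seq_len(n), , drop = FALSE]
  caches <- vector("list", cfg$n_layers)
  attn <- vector("list", cfg$n_layers)
  scale <- sqrt(E)
  for (l in seq_len(cfg$n_layers)) {
    p <- params$layers[[l]]
    ln1 <- layernorm_fwd(H, p$ln1_g, p$ln1_b)
    A <- ln1$out
    Q <- sweep(A %*% p$Wq, 2L, p$bq, "+")
    K <- sweep(A %*% p$Wk, 2L, p$bk, "+")
    V <- sweep(A %*% p$Wv, 2L, p$bv, "+")
    S <- Q %*% t(K) / scale
    S[upper.tri(S)] <- -Inf
    W <- row_softmax_masked(S)
    AV <- W %*% V
    O <- sweep(AV %*% p$Wo, 2L, p$bo, "+")
    H1 <- H + O
    ln2 <- layernorm_fwd(H1, p$ln2_g, p$ln2_b)
    F_in <- ln2$out
    Zf <- sweep(F_in %*% p$Wf1, 2L, p$bf1, "+")
    Af <- act_fun(Zf, "gelu")
    Ff <- sweep(Af %*% p$Wf2, 2L, p$bf2, "+")
    H2 <- H1 + Ff
    attn[[l]] <- W
    caches[[l]] <- list(ln1 = ln1, A = A, Q = Q, K = K, V = V, W = W, AV = AV,
                        ln2 = ln2, F_in = F_in, Zf = Zf, Af = Af)
    H <- H2
  }
  lnf <- layernorm_fwd(H, params$lnf_g, params$lnf_b)
  out <- sweep(lnf$out %*% params$W_out, 2L, params$b_out, "+")
  list(out = out, attn = attn,
       cache = list(X = X, n = n, layers = caches, lnf = lnf, params = params))
}

#' Backward pass of the causal transformer
#'
#' @param tf a [transformer_init()] model
#' @param cache cache from [transformer_forward()]
#' @param dY gradient w.r.t. the output (n x out_dim)
#' @return list of parameter gradients with the same shape as `tf$params`
#' @export
transformer_backward <- function(tf, cache, dY) {
  cfg <- tf$cfg
  params <- cache$params
  n <- cache$n
  E <- cfg$embed_dim
  scale <- sqrt(E)

  gW_out <- crossprod(cache$lnf$out, dY)
  gb_out <- colSums(dY)
  dLnf <- dY %*% t(params$W_out)
  bw <- layernorm_bwd(cache$lnf, dLnf)
  dH <- bw$dX
  g_lnf_g <- bw$dg; g_lnf_b <- bw$db

  g_layers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    p <- params$layers[[l]]
    cc <- cache$layers[[l]]
    # feed-forward branch: H2 = H1 + Ff
    dFf <- dH
    gWf2 <- crossprod(cc$Af, dFf)
    gbf2 <- colSums(dFf)
    dAf <- dFf %*% t(p$Wf2)
    dZf <- dAf * act_grad(cc$Zf, "gelu")
    gWf1 <- crossprod(cc$F_in, dZf)
    gbf1 <- colSums(dZf)
    dF_in <- dZf %*% t(p$Wf1)
    bw2 <- layernorm_bwd(cc$ln2, dF_in)
    dH1 <- dH + bw2$dX
    # attention branch: H1 = H + O
    dO <- dH1
    gWo <- crossprod(cc$AV, dO)
    gbo <- colSums(dO)
    dAV <- dO %*% t(p$Wo)
    dW <- dAV %*% t(cc$V)
    dV <- crossprod(cc$W, dAV)
    # softmax rows: dS = W * (dW - rowSums(dW * W))
    dS <- cc$W * (dW - rowSums(dW * cc$W))
    dQ <- dS %*% cc$K / scale
    dK <- crossprod(dS, cc$Q) / scale
    dA <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    gWq <- crossprod(cc$A, dQ); gbq <- colSums(dQ)
    gWk <- crossprod(cc$A, dK); gbk <- colSums(dK)
    gWv <- crossprod(cc$A, dV); gbv <- colSums(dV)
    bw1 <- layernorm_bwd(cc$ln1, dA)
    dH <- dH1 + bw1$dX
    g_layers[[l]] <- list(
      ln1_g = bw1$dg, ln1_b = bw1$db,
      Wq = gWq, bq = gbq, Wk = gWk, bk = gbk, Wv = gWv, bv = gbv,
      Wo = gWo, bo = gbo,
      ln2_g = bw2$dg, ln2_b = bw2$db,
      Wf1 = gWf1, bf1 = gbf1, Wf2 = gWf2, bf2 = gbf2)
  }
  gP <- matrix(0, cfg$max_len, E)
  gP[seq_len(n), ] <- dH
  list(W_tok = crossprod(cache$X, dH), b_tok = colSums(dH), P = gP,
       layers = g_layers, lnf_g = g_lnf_g, lnf_b = g_lnf_b,
       W_out = gW_out, b_out = gb_out)
}
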