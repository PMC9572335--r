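## Small feed-forward networks with hand-derived reverse-mode gradients.
## Parameters are plain lists of matrices/vectors so they can be flattened
## for the optimizer and hand-set in tests and toy constructions.

#' Initialize a feed-forward network
#'
#' Hidden layers use tanh (default) and the output layer is linear. Weights
#' are Xavier-uniform initialized; biases start at zero.
#'
#' @param sizes integer vector of layer widths, e.g. `c(2, 64, 64, 2)`
#' @param act hidden activation: "tanh" or "gelu"
#' @param seed integer seed for the weight draw
#' @param zero_init if TRUE all weights start at zero (testing aid)
#' @return an object of class `mlp` with a `params` list (`W`, `b`)
#' @export
mlp_init <- function(sizes, act = c("tanh", "gelu"), seed = 0L,
                     zero_init = FALSE) {
  act <- match.arg(act)
  assert_that(length(sizes) >= 2L && all(sizes >= 1), "invalid_argument",
              "sizes must list at least input and output widths")
  n_lay <- length(sizes) - 1L
  W <- vector("list", n_lay); b <- vector("list", n_lay)
  with_seed(seed, {
    for (l in seq_len(n_lay)) {
      r <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
      W[[l]] <- if (zero_init) matrix(0, sizes[l], sizes[l + 1L]) else
        matrix(stats::runif(sizes[l] * sizes[l + 1L], -r, r),
               sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
  })
  structure(list(sizes = as.integer(sizes), act = act,
                 params = list(W = W, b = b)), class = "mlp")
}

act_fun <- function(x, act) {
  switch(act, tanh = tanh(x), gelu = x * stats::pnorm(x))
}
act_grad <- function(x, act) {
  switch(act,
         tanh = 1 - tanh(x)^2,
         gelu = stats::pnorm(x) + x * stats::dnorm(x))
}

#' Forward pass of an [mlp_init()] network
#'
#' @param net an `mlp`
#' @param X an n x d_in matrix (rows = cases); a bare vector is treated as
#'   one row
#' @param params optional parameter list overriding `net$params` (used by
#'   the optimizer)
#' @return list with `out` (n x d_out) and `cache` for [mlp_backward()]
#' @export
mlp_forward <- function(net, X, params = net$params) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  assert_that(all(is.finite(X)), "invalid_argument",
              "network input must be finite")
  assert_that(ncol(X) == net$sizes[1L], "invalid_argument",
              "input width does not match the network")
  n_lay <- length(params$W)
  pre <- vector("list", n_lay); inp <- vector("list", n_lay)
  H <- X
  for (l in seq_len(n_lay)) {
    inp[[l]] <- H
    Z <- H %*% params$W[[l]]
    Z <- sweep(Z, 2L, params$b[[l]], "+")
    pre[[l]] <- Z
    H <- if (l < n_lay) act_fun(Z, net$act) else Z
  }
  list(out = H, cache = list(pre = pre, inp = inp, params = params))
}

#' Backward pass of an [mlp_init()] network
#'
#' @param net an `mlp`
#' @param cache cache from [mlp_forward()]
#' @param dY gradient of the loss w.r.t. the output (same shape as `out`)
#' @return list with `dX` (gradient w.r.t. the input) and `grads`
#'   (list `W`, `b` matching `net$params`)
#' @export
mlp_backward <- function(net, cache, dY) {
  params <- cache$params
  n_lay <- length(params$W)
  if (!is.matrix(dY)) dY <- matrix(dY, nrow = 1L)
  gW <- vector("list", n_lay); gb <- vector("list", n_lay)
  D <- dY
  for (l in rev(seq_len(n_lay))) {
    if (l < n_lay) D <- D * act_grad(cache$pre[[l]], net$act)
    gW[[l]] <- crossprod(cache$inp[[l]], D)
    gb[[l]] <- colSums(D)
    D <- D %*% t(params$W[[l]])
  }
  list(dX = D, grads = list(W = gW, b = gb))
}
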