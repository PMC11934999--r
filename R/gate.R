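#' @title Graph attention autoencoder (GATE)
#'
#' @description
#' The embedding engine: an L-layer encoder aggregates each node's neighbor
#' representations with learned softmax attention weights,
#' `h_i^(k) = sum_{j in A_i} alpha_ij^(k) sigma(W^(k) h_j^(k-1))`,
#' where the unnormalized attention is
#' `r_ij = sigmoid(v_s' sigma(W h_i) + v_t' sigma(W h_j))` and
#' `alpha_ij = softmax_j(r_ij)` over the neighborhood `A_i` (which always
#' includes `i` itself). The decoder mirrors the encoder with
#' transpose-tied weights and its own attention parameters, and the model
#' minimizes the squared reconstruction error of the normalized expression
#' profiles. Gradients are derived analytically and optimized with Adam.
#'
#' @name gate
NULL

act_funs <- function(name) {
  switch(name,
    elu = list(f = function(u) {
                 pos <- u > 0
                 r <- exp(pmin(u, 0)) - 1
                 r[pos] <- u[pos]
                 r
               },
               g = function(u) {
                 r <- exp(pmin(u, 0))
                 r[u > 0] <- 1
                 r
               }),
    identity = list(f = function(u) u,
                    g = function(u) array(1, dim(u))),
    stop("unknown activation: ", name, call. = FALSE))
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Initialize GATE parameters
#'
#' @param input_dim Number of input features (genes).
#' @param dims Widths of the encoder layers; the last entry is the embedding
#'   dimension. Default `c(512, 30)`.
#' @param activation `"elu"` (default) or `"identity"`.
#' @param seed Integer seed controlling the weight initialization.
#' @return An object of class `gate_params`: per layer, the shared weight
#'   matrix `W` (decoder uses its transpose), encoder attention vectors
#'   `v_s`, `v_t`, and decoder attention vectors `dec_v_s`, `dec_v_t`.
#' @export
init_gate_params <- function(input_dim, dims = c(512, 30),
                             activation = "elu", seed = 1) {
  set.seed(as.integer(seed))
  all_dims <- c(input_dim, dims)
  L <- length(dims)
  layers <- lapply(seq_len(L), function(k) {
    d_in <- all_dims[k]; d_out <- all_dims[k + 1]
    list(W = glorot(d_out, d_in),
         v_s = as.numeric(glorot(d_out, 1)),
         v_t = as.numeric(glorot(d_out, 1)),
         dec_v_s = as.numeric(glorot(d_in, 1)),
         dec_v_t = as.numeric(glorot(d_in, 1)))
  })
  structure(list(layers = layers, dims = all_dims, activation = activation),
            class = "gate_params")
}

# Edge-wise softmax attention over a graph. S holds sigma(W h) for all nodes;
# returns per-edge alpha plus the intermediates needed for backprop.
edge_attention <- function(S, edges, v_s, v_t) {
  a <- as.numeric(S %*% v_s)
  b <- as.numeric(S %*% v_t)
  r <- 1 / (1 + exp(-(a[edges$i] + b[edges$j])))
  er <- exp(r)                       # r in (0,1): no overflow risk
  denom <- as.numeric(rowsum(er, edges$i))  # groups 1..n (self-loops guarantee)
  alpha <- er / denom[edges$i]
  list(alpha = alpha, r = r, a = a, b = b)
}

#' Attention coefficients of one GATE layer
#'
#' Computes the softmax-normalized edge weights `alpha_ij` for every edge of
#' the graph, given the previous-layer node representations. For each node
#' the weights over its neighborhood (self included) sum to one.
#'
#' @param h_prev Numeric matrix of node representations (nodes x features).
#' @param graph An [adj_graph()].
#' @param W Layer weight matrix (out x in).
#' @param v_s,v_t Attention vectors (length = layer output width).
#' @param activation `"elu"` or `"identity"`.
#' @return A list with `i`, `j` (edge endpoints; the softmax runs over all
#'   edges sharing `i`) and `alpha`.
#' @export
attention_coefficients <- function(h_prev, graph, W, v_s, v_t,
                                   activation = "elu") {
  act <- act_funs(activation)
  edges <- graph_edges(graph)
  S <- act$f(h_prev %*% t(W))
  att <- edge_attention(S, edges, v_s, v_t)
  list(i = edges$i, j = edges$j, alpha = att$alpha)
}

# One attention layer forward: H_out[i,] = sum_j alpha_ij S[j,].
# `V` is the weight in the orientation U = H_prev %*% t(V).
attention_layer_forward <- function(H_prev, edges, V, v_s, v_t, act, n) {
  U <- H_prev %*% t(V)
  S <- act$f(U)
  att <- edge_attention(S, edges, v_s, v_t)
  A <- Matrix::sparseMatrix(i = edges$i, j = edges$j, x = att$alpha,
                            dims = c(n, n))
  H <- as.matrix(A %*% S)
  list(H = H, cache = list(H_prev = H_prev, U = U, S = S, A = A, att = att))
}

# Backward pass through one attention layer. G = dLoss/dH_out.
# Returns gradients for V (same orientation as forward), v_s, v_t, H_prev.
attention_layer_backward <- function(G, cache, edges, V, v_s, v_t, act) {
  S <- cache$S; att <- cache$att; n <- nrow(S)
  ei <- edges$i; ej <- edges$j
  dS <- as.matrix(Matrix::crossprod(cache$A, G))          # aggregation path
  dAlpha <- rowSums(G[ei, , drop = FALSE] * S[ej, , drop = FALSE])
  sdot <- as.numeric(rowsum(att$alpha * dAlpha, ei))
  dr <- att$alpha * (dAlpha - sdot[ei])                    # softmax backward
  ge <- dr * att$r * (1 - att$r)                           # sigmoid backward
  da <- as.numeric(rowsum(ge, ei))
  db0 <- rowsum(ge, ej)                                    # every node self-loops
  db <- as.numeric(db0)
  dv_s <- as.numeric(crossprod(S, da))
  dv_t <- as.numeric(crossprod(S, db))
  dS <- dS + outer(da, v_s) + outer(db, v_t)
  dU <- dS * act$g(cache$U)
  list(dV = crossprod(dU, cache$H_prev),                   # t(dU) %*% H_prev
       dv_s = dv_s, dv_t = dv_t,
       dH_prev = dU %*% V)
}

#' GATE forward pass
#'
#' `direction = "encode"` consumes normalized expression profiles as the
#' initial node representations and returns the last-layer embedding Z;
#' `direction = "decode"` consumes Z and returns the reconstructed profiles.
#'
#' @param X Numeric matrix: expression (encode) or embedding (decode), nodes
#'   in rows.
#' @param graph An [adj_graph()] over the same nodes.
#' @param params A [init_gate_params()] object.
#' @param direction `"encode"` or `"decode"`.
#' @return A numeric matrix (embedding or reconstruction). The full cache
#'   used for backpropagation is attached as attribute `"cache"`.
#' @export
gate_forward <- function(X, graph, params, direction = c("encode", "decode")) {
  direction <- match.arg(direction)
  act <- act_funs(params$activation)
  edges <- graph_edges(graph)
  n <- graph$n_nodes
  if (nrow(X) != n) stop("node count mismatch between X and graph", call. = FALSE)
  L <- length(params$layers)
  caches <- vector("list", L)
  H <- X
  if (direction == "encode") {
    if (ncol(X) != params$dims[1]) stop("input width mismatch", call. = FALSE)
    for (k in seq_len(L)) {
      p <- params$layers[[k]]
      out <- attention_layer_forward(H, edges, p$W, p$v_s, p$v_t, act, n)
      H <- out$H; caches[[k]] <- out$cache
    }
  } else {
    if (ncol(X) != params$dims[L + 1]) stop("embedding width mismatch", call. = FALSE)
    for (k in rev(seq_len(L))) {
      p <- params$layers[[k]]
      # decoder weight is t(W): U = H %*% t(t(W)) = H %*% W
      out <- attention_layer_forward(H, edges, t(p$W), p$dec_v_s, p$dec_v_t, act, n)
      H <- out$H; caches[[k]] <- out$cache
    }
  }
  attr(H, "cache") <- caches
  H
}

# Full forward + analytic backward of the reconstruction loss sum||x - xhat||^2.
# Returns loss, Z, xhat and the gradient list (same shape as params$layers).
gate_loss_and_grad <- function(X, graph, params, want_grad = TRUE) {
  act <- act_funs(params$activation)
  edges <- graph_edges(graph)
  n <- graph$n_nodes
  L <- length(params$layers)
  enc_cache <- vector("list", L)
  H <- X
  for (k in seq_len(L)) {
    p <- params$layers[[k]]
    out <- attention_layer_forward(H, edges, p$W, p$v_s, p$v_t, act, n)
    H <- out$H; enc_cache[[k]] <- out$cache
  }
  Z <- H
  dec_cache <- vector("list", L)
  for (k in rev(seq_len(L))) {
    p <- params$layers[[k]]
    out <- attention_layer_forward(H, edges, t(p$W), p$dec_v_s, p$dec_v_t, act, n)
    H <- out$H; dec_cache[[k]] <- out$cache
  }
  xhat <- H
  loss <- sum((X - xhat)^2)
  if (!is.finite(loss)) stop("non-finite reconstruction loss", call. = FALSE)
  if (!want_grad) return(list(loss = loss, Z = Z, xhat = xhat))
  grads <- lapply(params$layers, function(p)
    list(W = array(0, dim(p$W)), v_s = numeric(length(p$v_s)),
         v_t = numeric(length(p$v_t)), dec_v_s = numeric(length(p$dec_v_s)),
         dec_v_t = numeric(length(p$dec_v_t))))
  G <- 2 * (xhat - X)
  # decoder ran k = L..1; backprop in reverse order k = 1..L
  for (k in seq_len(L)) {
    p <- params$layers[[k]]
    bk <- attention_layer_backward(G, dec_cache[[k]], edges,
                                   t(p$W), p$dec_v_s, p$dec_v_t, act)
    grads[[k]]$W <- grads[[k]]$W + t(bk$dV)   # tied: dec V = t(W)
    grads[[k]]$dec_v_s <- bk$dv_s
    grads[[k]]$dec_v_t <- bk$dv_t
    G <- bk$dH_prev
  }
  for (k in rev(seq_len(L))) {
    p <- params$layers[[k]]
    bk <- attention_layer_backward(G, enc_cache[[k]], edges,
                                   p$W, p$v_s, p$v_t, act)
    grads[[k]]$W <- grads[[k]]$W + bk$dV
    grads[[k]]$v_s <- bk$dv_s
    grads[[k]]$v_t <- bk$dv_t
    G <- bk$dH_prev
  }
  list(loss = loss, Z = Z, xhat = xhat, grads = grads)
}

adam_state <- function(template) {
  list(m = rapply(template, function(x) x * 0, how = "replace"),
       v = rapply(template, function(x) x * 0, how = "replace"),
       t = 0L)
}

adam_update <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  flat_par <- unlist(par, use.names = FALSE)
  flat_g <- unlist(grad, use.names = FALSE)
  flat_m <- unlist(state$m, use.names = FALSE)
  flat_v <- unlist(state$v, use.names = FALSE)
  flat_m <- beta1 * flat_m + (1 - beta1) * flat_g
  flat_v <- beta2 * flat_v + (1 - beta2) * flat_g^2
  mhat <- flat_m / (1 - beta1^state$t)
  vhat <- flat_v / (1 - beta2^state$t)
  flat_par <- flat_par - lr * mhat / (sqrt(vhat) + eps)
  list(par = utils::relist(flat_par, par),
       state = list(m = utils::relist(flat_m, state$m),
                    v = utils::relist(flat_v, state$v), t = state$t))
}

#' Train the graph attention autoencoder
#'
#' Minimizes the reconstruction loss of the normalized expression profiles
#' with full-batch Adam; with a fixed seed the run is bit-reproducible.
#'
#' @param E [expression_matrix()] with layer `"cpm_log2"` (or a plain numeric
#'   matrix of node features).
#' @param graph [adj_graph()] with one node per row of `E`.
#' @param dims Encoder layer widths (default `c(512, 30)`; the last entry is
#'   the embedding dimension).
#' @param epochs Number of Adam steps (default 500). `epochs = 0` returns the
#'   untrained forward pass.
#' @param lr Adam learning rate (default 1e-4).
#' @param activation `"elu"` (default) or `"identity"`.
#' @param seed Integer seed for the weight initialization.
#' @param verbose Print the loss every 50 epochs.
#' @return A list of class `gate_fit`: `params` (trained [gate_params]),
#'   `embedding` (nodes x `dims[length(dims)]` matrix, row names preserved),
#'   `losses` (reconstruction loss per epoch, position 1 = initial).
#' @export
train_gate <- function(E, graph, dims = c(512, 30), epochs = 500, lr = 1e-4,
                       activation = "elu", seed = 1, verbose = FALSE) {
  X <- if (inherits(E, "expr_matrix")) {
    if (E$layer != "cpm_log2")
      stop("train_gate expects cpm_log2 normalized expression", call. = FALSE)
    E$values
  } else as.matrix(E)
  if (nrow(X) != graph$n_nodes)
    stop("graph node count does not match the expression rows", call. = FALSE)
  params <- init_gate_params(ncol(X), dims = dims, activation = activation,
                             seed = seed)
  losses <- numeric(epochs + 1)
  fw <- gate_loss_and_grad(X, graph, params, want_grad = epochs > 0)
  losses[1] <- fw$loss
  if (epochs > 0) {
    state <- adam_state(params$layers)
    for (ep in seq_len(epochs)) {
      upd <- adam_update(params$layers, fw$grads, state, lr)
      params$layers <- upd$par
      state <- upd$state
      fw <- gate_loss_and_grad(X, graph, params, want_grad = ep < epochs)
      if (!is.finite(fw$loss))
        stop("non-finite reconstruction loss at epoch ", ep, call. = FALSE)
      losses[ep + 1] <- fw$loss
      if (verbose && ep %% 50 == 0)
        message(sprintf("epoch %d: loss %.4f", ep, fw$loss))
    }
  }
  Z <- fw$Z
  rownames(Z) <- rownames(X)
  structure(list(params = params, embedding = Z, losses = losses),
            class = "gate_fit")
}

#' @export
print.gate_fit <- function(x, ...) {
  cat(sprintf("<gate_fit> dims %s, %d epochs, loss %.4g -> %.4g\n",
              paste(x$params$dims, collapse = "-"), length(x$losses) - 1,
              x$losses[1], x$losses[length(x$losses)]))
  invisible(x)
}
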