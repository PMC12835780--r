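# Feed-forward log-hazard network: SELU multilayer perceptron with
# manual reverse-mode gradients and SGD-with-momentum updates. All in
# plain matrix algebra; layer l stores weights W (fan_in x fan_out) and
# bias b.

.selu_lambda <- 1.0507009873554805
.selu_alpha <- 1.6732632423543772

selu <- function(x) {
  .selu_lambda * ifelse(x > 0, x, .selu_alpha * (exp(pmin(x, 0)) - 1))
}

selu_grad <- function(x) {
  .selu_lambda * ifelse(x > 0, 1, .selu_alpha * exp(pmin(x, 0)))
}

#' Architecture of the log-hazard network
#'
#' An input linear layer mapping p features to `hidden_width` units,
#' `hidden_layers` further dense layers of the same width, SELU
#' activations throughout (self-normalising; no batch normalisation or
#' dropout), and a final linear projection to a single log-hazard score.
#' `hidden_layers = 0` with `activation = "linear"` collapses the network
#' to a plain linear Cox predictor, which is useful for recovery checks
#' against a known linear generative model.
#'
#' @param input_dim Number of covariates p (filled in at fit time when
#'   `NULL`).
#' @param hidden_width Width of each hidden layer (default 32).
#' @param hidden_layers Number of hidden layers after the input layer
#'   (default 4).
#' @param activation `"selu"` (default) or `"linear"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(input_dim = NULL, hidden_width = 32L,
                       hidden_layers = 4L,
                       activation = c("selu", "linear")) {
  activation <- match.arg(activation)
  stopifnot(hidden_width >= 1L, hidden_layers >= 0L)
  structure(list(input_dim = input_dim,
                 hidden_width = as.integer(hidden_width),
                 hidden_layers = as.integer(hidden_layers),
                 activation = activation),
            class = "model_spec")
}

# Uniform(-1/sqrt(fan_in), 1/sqrt(fan_in)) init for every linear layer,
# the convention of mainstream deep-learning libraries. `linear_only`
# (hidden_layers = 0, activation "linear") yields a single p -> 1 layer.
mlp_init <- function(spec) {
  p <- spec$input_dim
  stopifnot(!is.null(p), p >= 1L)
  if (spec$hidden_layers == 0L && spec$activation == "linear") {
    dims <- c(p, 1L)
  } else {
    dims <- c(p, rep(spec$hidden_width, spec$hidden_layers + 1L), 1L)
  }
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    k <- 1 / sqrt(fan_in)
    layers[[l]] <- list(
      W = matrix(stats::runif(fan_in * dims[l + 1L], -k, k),
                 fan_in, dims[l + 1L]),
      b = stats::runif(dims[l + 1L], -k, k))
  }
  structure(list(layers = layers, spec = spec), class = "fairsurv_mlp")
}

# Forward pass. Returns scores and, when cache = TRUE, the pre- and
# post-activation values needed for the backward pass.
mlp_forward <- function(net, X, cache = FALSE) {
  L <- length(net$layers)
  act <- net$spec$activation
  A <- X
  pre <- if (cache) vector("list", L) else NULL
  post <- if (cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    Z <- A %*% net$layers[[l]]$W
    Z <- sweep(Z, 2, net$layers[[l]]$b, "+")
    if (l < L && act == "selu") Anew <- selu(Z) else Anew <- Z
    if (cache) { pre[[l]] <- Z; post[[l]] <- Anew }
    A <- Anew
  }
  scores <- as.numeric(A)
  if (cache) list(scores = scores, pre = pre, post = post, X = X)
  else scores
}

# Backward pass from d(loss)/d(score). Returns per-layer gradients.
mlp_backward <- function(net, fw, dscore) {
  L <- length(net$layers)
  act <- net$spec$activation
  grads <- vector("list", L)
  delta <- matrix(dscore, ncol = 1)
  for (l in rev(seq_len(L))) {
    A_in <- if (l == 1L) fw$X else fw$post[[l - 1L]]
    grads[[l]] <- list(W = crossprod(A_in, delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- delta %*% t(net$layers[[l]]$W)
      if (act == "selu") delta <- delta * selu_grad(fw$pre[[l - 1L]])
    }
  }
  grads
}

# SGD with momentum and L2 weight decay (decay added to the gradient,
# then folded into the momentum buffer, as in mainstream SGD).
sgd_state <- function(net) {
  lapply(net$layers, function(l)
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b))))
}

sgd_step <- function(net, grads, state, lr, momentum, weight_decay) {
  for (l in seq_along(net$layers)) {
    gW <- grads[[l]]$W + weight_decay * net$layers[[l]]$W
    gb <- grads[[l]]$b
    state[[l]]$W <- momentum * state[[l]]$W + gW
    state[[l]]$b <- momentum * state[[l]]$b + gb
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * state[[l]]$W
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * state[[l]]$b
  }
  list(net = net, state = state)
}
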