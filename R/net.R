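# ---- hierarchical network ----------------------------------------------------

# SELU constants (Klambauer et al. self-normalizing networks)
.selu_lambda <- 1.0507009873554804934193349852946
.selu_alpha  <- 1.6732632423543772848170429916717

#' Scaled exponential linear unit
#' @param x numeric vector/matrix.
#' @return SELU(x) elementwise.
#' @export
selu <- function(x)
  ifelse(x > 0, .selu_lambda * x, .selu_lambda * .selu_alpha * (exp(x) - 1))

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Construct a hierarchical network object
#'
#' Holds the weights of one 25-16-8-2 network: SELU on the two hidden
#' layers, an independent sigmoid on each of the two output neurons.
#'
#' @param W1,b1,W2,b2,W3,b3 weight matrices (d x 16, 16 x 8, 8 x 2) and bias
#'   vectors (16, 8, 2).
#' @param dropout_rate training-mode probability of disabling a hidden
#'   neuron (default 0.25).
#' @param meta optional list of training metadata.
#' @return object of class `drabc_net`.
#' @export
hier_net <- function(W1, b1, W2, b2, W3, b3, dropout_rate = 0.25,
                     meta = list()) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2); W3 <- as.matrix(W3)
  stopifnot(ncol(W1) == 16L, identical(dim(W2), c(16L, 8L)),
            identical(dim(W3), c(8L, 2L)),
            length(b1) == 16L, length(b2) == 8L, length(b3) == 2L,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(W1 = W1, b1 = as.numeric(b1), W2 = W2, b2 = as.numeric(b2),
                 W3 = W3, b3 = as.numeric(b3), dropout_rate = dropout_rate,
                 meta = meta),
            class = "drabc_net")
}

#' Forward pass
#'
#' In `infer` mode the pass is deterministic (dropout disabled, the standard
#' inference convention). In `train` mode inverted-dropout masks are drawn
#' from `seed`: each hidden neuron is disabled with probability
#' `dropout_rate` and survivors are scaled by `1/(1 - dropout_rate)`.
#'
#' @param net a `drabc_net`.
#' @param x numeric input: a length-d vector or an n x d matrix.
#' @param mode `"infer"` (default) or `"train"`.
#' @param seed integer, required in train mode.
#' @return n x 2 matrix of probabilities, columns `P1` (any-carrier head)
#'   and `P2` (BRCA1/2-given-carrier head), each strictly inside (0, 1).
#' @export
net_forward <- function(net, x, mode = c("infer", "train"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "drabc_net"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!all(is.finite(x))) stop("non-finite network input")
  if (ncol(x) != nrow(net$W1))
    stop("input has ", ncol(x), " features; network expects ", nrow(net$W1))
  mask <- function(n_units) {
    if (mode == "infer" || net$dropout_rate == 0)
      return(matrix(1, nrow(x), n_units))
    keep <- 1 - net$dropout_rate
    matrix(rbinom(nrow(x) * n_units, 1L, keep) / keep, nrow(x), n_units)
  }
  if (mode == "train") {
    if (is.null(seed)) stop("train-mode forward requires a seed")
    set.seed(as.integer(seed))
  }
  A1 <- selu(sweep(x %*% net$W1, 2, net$b1, "+")) * mask(16L)
  A2 <- selu(sweep(A1 %*% net$W2, 2, net$b2, "+")) * mask(8L)
  P <- sigmoid(sweep(A2 %*% net$W3, 2, net$b3, "+"))
  colnames(P) <- c("P1", "P2")
  P
}

#' Chain-rule decomposition of the two network outputs
#'
#' Given the any-carrier probability `P1` and the conditional BRCA1/2
#' probability `P2`, returns the three reported risks:
#' `p_any = P1`, `p_brca = P1 * P2`, `p_other = P1 * (1 - P2)`, so that
#' `p_brca + p_other = p_any` holds identically.
#'
#' @param P1,P2 probabilities in \[0, 1\] (vectors of equal length).
#' @return data.frame with columns `p_any`, `p_brca`, `p_other`.
#' @export
derive_probabilities <- function(P1, P2) {
  stopifnot(length(P1) == length(P2))
  if (any(!is.finite(P1) | !is.finite(P2) | P1 < 0 | P1 > 1 | P2 < 0 | P2 > 1))
    stop("P1 and P2 must lie in [0, 1]")
  data.frame(p_any = P1, p_brca = P1 * P2, p_other = P1 * (1 - P2))
}

#' Hierarchical cross-entropy loss
#'
#' `L = BCE(P1, y_any) + y_any * BCE(P2, y_brca)`: binary cross-entropy on
#' the any-carrier head plus, for carriers only, binary cross-entropy on the
#' conditional BRCA1/2 head. For non-carriers `y_brca` is undefined (`NA`)
#' and its term contributes nothing.
#'
#' @param P1,P2 predicted probabilities.
#' @param y_any 0/1 any-carrier labels.
#' @param y_brca 0/1 BRCA1/2 labels, `NA` for non-carriers.
#' @return mean loss over the records (non-negative).
#' @export
hierarchical_loss <- function(P1, P2, y_any, y_brca) {
  stopifnot(length(P1) == length(y_any), length(P2) == length(P1),
            all(y_any %in% c(0L, 1L)),
            all(is.na(y_brca) | y_brca %in% c(0L, 1L)),
            all(!(y_any == 0L) | is.na(y_brca)))
  P1 <- pmin(pmax(P1, 1e-12), 1 - 1e-12)
  P2 <- pmin(pmax(P2, 1e-12), 1 - 1e-12)
  l1 <- -(y_any * log(P1) + (1 - y_any) * log(1 - P1))
  yb <- ifelse(is.na(y_brca), 0, y_brca)
  l2 <- -y_any * (yb * log(P2) + (1 - yb) * log(1 - P2))
  mean(l1 + l2)
}

#' Train a single hierarchical network
#'
#' Minibatch gradient descent (Adam) on the hierarchical cross-entropy,
#' with SELU hidden layers, inverted dropout and LeCun-normal
#' initialization. Training is bit-deterministic given `(data, seed,
#' hyperparameters)`; it uses its own Mersenne-Twister stream and leaves R's
#' RNG untouched. Stops early when the epoch training loss has not improved
#' by more than `tol` for `patience` consecutive epochs.
#'
#' @param cohort labeled `drabc_cohort` (complete records), or an encoded
#'   matrix via `x`/`y_any`/`y_brca` (see [encode_cohort()]).
#' @param spec encoding spec used when `cohort` is given.
#' @param epochs,learning_rate,batch_size,dropout,tol,patience optimizer
#'   hyperparameters.
#' @param seed integer seed.
#' @param x,y_any,y_brca low-level interface bypassing the encoder.
#' @return a `drabc_net` with `meta$loss` (per-epoch trajectory) and
#'   `meta$epochs_run`.
#' @export
train_net <- function(cohort = NULL, spec = encoding_spec(), epochs = 200L,
                      learning_rate = 1e-3, batch_size = 64L, dropout = 0.25,
                      seed = 1L, tol = 1e-6, patience = 10L,
                      x = NULL, y_any = NULL, y_brca = NULL) {
  if (is.null(x)) {
    stopifnot(has_labels(cohort))
    x <- encode_cohort(cohort, spec)
    tg <- carrier_targets(cohort$group)
    y_any <- tg$y_any
    y_brca <- tg$y_brca
  }
  if (length(unique(y_any)) < 2L)
    stop("training labels contain a single y_any class")
  yb <- as.numeric(y_brca)
  yb[is.na(yb)] <- NaN
  fit <- cpp_train_net(x, as.numeric(y_any), yb,
                       epochs = as.integer(epochs), lr = learning_rate,
                       batch_size = as.integer(batch_size), dropout = dropout,
                       seed = as.integer(seed), tol = tol,
                       patience = as.integer(patience))
  hier_net(fit$W1, fit$b1, fit$W2, fit$b2, fit$W3, fit$b3,
           dropout_rate = dropout,
           meta = list(loss = fit$loss, epochs_run = fit$epochs_run,
                       seed = as.integer(seed),
                       hyper = list(epochs = epochs,
                                    learning_rate = learning_rate,
                                    batch_size = batch_size)))
}
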