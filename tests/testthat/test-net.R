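zero_net <- function(d = 25) {
  hier_net(matrix(0, d, 16), rep(0, 16), matrix(0, 16, 8), rep(0, 8),
           matrix(0, 8, 2), rep(0, 2))
}

random_net <- function(d = 25, seed = 1) {
  set.seed(seed)
  hier_net(matrix(rnorm(d * 16, sd = 0.4), d, 16), rnorm(16, sd = 0.1),
           matrix(rnorm(16 * 8, sd = 0.4), 16, 8), rnorm(8, sd = 0.1),
           matrix(rnorm(16, sd = 0.4), 8, 2), rnorm(2, sd = 0.1))
}

test_that("SELU matches its closed form", {
  expect_equal(selu(0), 0)
  lambda <- 1.0507009873554805; alpha <- 1.6732632423543772
  expect_equal(selu(-10), lambda * alpha * (exp(-10) - 1))
  expect_equal(round(selu(-10), 4), -1.758)
  expect_equal(selu(2), lambda * 2)
})

test_that("forward pass fixes: zero weights, zero input, dropout modes", {
  # sigmoid(0) = 0.5 everywhere with zero weights and biases
  P <- net_forward(zero_net(), rep(0, 25))
  expect_equal(unname(P[1, ]), c(0.5, 0.5))
  # SELU(0) = 0 propagates a zero input through zero biases untouched,
  # so any weights still give (0.5, 0.5) as long as biases are zero
  nb <- random_net()
  nb$b1[] <- 0; nb$b2[] <- 0; nb$b3[] <- 0
  P <- net_forward(nb, rep(0, 25))
  expect_equal(unname(P[1, ]), c(0.5, 0.5))

  net <- random_net()
  x <- matrix(rnorm(4 * 25), 4)
  expect_identical(net_forward(net, x), net_forward(net, x))  # infer: no RNG
  # train mode needs a seed, is reproducible under it, and differs from infer
  expect_error(net_forward(net, x, mode = "train"), "seed")
  a <- net_forward(net, x, mode = "train", seed = 5)
  b <- net_forward(net, x, mode = "train", seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, net_forward(net, x)))
  expect_true(all(a > 0 & a < 1))

  expect_error(net_forward(net, c(rep(0, 24), NA)), "finite")
})

test_that("forward pass agrees with a loop-written oracle", {
  # independent re-implementation: per-record loops, no matrix algebra
  oracle <- function(net, x) {
    h1 <- vapply(seq_len(16), function(j)
      selu(sum(x * net$W1[, j]) + net$b1[j]), numeric(1))
    h2 <- vapply(seq_len(8), function(j)
      selu(sum(h1 * net$W2[, j]) + net$b2[j]), numeric(1))
    z <- vapply(1:2, function(j)
      sum(h2 * net$W3[, j]) + net$b3[j], numeric(1))
    1 / (1 + exp(-z))
  }
  net <- random_net(seed = 9)
  for (i in 1:5) {
    x <- rnorm(25)
    expect_equal(unname(net_forward(net, x)[1, ]), oracle(net, x),
                 tolerance = 1e-12)
  }
})

test_that("derive_probabilities satisfies the chain-rule identity", {
  expect_equal(unlist(derive_probabilities(0.5, 0.5)),
               c(p_any = 0.5, p_brca = 0.25, p_other = 0.25))
  expect_equal(unlist(derive_probabilities(1, 1)),
               c(p_any = 1, p_brca = 1, p_other = 0))
  set.seed(1)
  p <- derive_probabilities(runif(1000), runif(1000))
  expect_lt(max(abs(p$p_brca + p$p_other - p$p_any)), 1e-12)
  expect_true(all(p$p_brca <= p$p_any & p$p_other <= p$p_any))
  expect_error(derive_probabilities(1.2, 0.5), "\\[0, 1\\]")
})

test_that("hierarchical loss masks the conditional head for non-carriers", {
  # perfect confident predictions drive the loss to ~0
  expect_lt(hierarchical_loss(c(1 - 1e-9, 1e-9), c(1 - 1e-9, 0.5),
                              y_any = c(1L, 0L), y_brca = c(1L, NA)), 1e-6)
  # non-carrier at P1 = 0.5: exactly ln 2 regardless of P2
  expect_equal(hierarchical_loss(0.5, 0.123, 0L, NA), log(2))
  expect_equal(hierarchical_loss(0.5, 0.987, 0L, NA), log(2))
  # d/dP2 = 0 for a non-carrier (central finite differences)
  h <- 1e-5
  g <- (hierarchical_loss(0.4, 0.3 + h, 0L, NA) -
          hierarchical_loss(0.4, 0.3 - h, 0L, NA)) / (2 * h)
  expect_equal(g, 0)
  # ...and nonzero for a BRCA carrier
  g1 <- (hierarchical_loss(0.9, 0.3 + h, 1L, 1L) -
           hierarchical_loss(0.9, 0.3 - h, 1L, 1L)) / (2 * h)
  expect_lt(g1, 0)
})

test_that("trainer and R forward agree (lr = 0 returns the initial net)", {
  co <- generate_cohort(120, seed = 21)
  X <- encode_cohort(co)
  tg <- carrier_targets(co$group)
  net <- train_net(x = X, y_any = tg$y_any, y_brca = tg$y_brca,
                   epochs = 1, learning_rate = 0, dropout = 0,
                   batch_size = nrow(X), seed = 4)
  P <- net_forward(net, X)
  expect_equal(net$meta$loss[1],
               hierarchical_loss(P[, 1], P[, 2], tg$y_any, tg$y_brca),
               tolerance = 1e-10)
})

test_that("training descends, separates separable data, is deterministic", {
  co <- generate_cohort(200, seed = 31)
  # full-batch, no dropout, small lr: loss non-increasing within tolerance
  net <- train_net(co, epochs = 60, learning_rate = 2e-4, dropout = 0,
                   batch_size = 200, seed = 8)
  expect_true(all(diff(net$meta$loss) <= 1e-6))

  # linearly separable toy data
  n <- 60
  X <- rbind(matrix(1, n / 2, 25), matrix(0, n / 2, 25))
  y <- rep(c(1L, 0L), each = n / 2)
  yb <- ifelse(y == 1L, 1L, NA_integer_)
  net <- train_net(x = X, y_any = y, y_brca = yb, seed = 2, epochs = 200)
  auc <- roc_auc(net_forward(net, X)[, 1], y)$auc
  expect_gt(auc, 0.99)

  # bit-identical weights under an identical seed; different otherwise
  a <- train_net(co, seed = 5, epochs = 20)
  b <- train_net(co, seed = 5, epochs = 20)
  expect_identical(a$W1, b$W1)
  expect_identical(a$b3, b$b3)
  expect_false(identical(a$W1, train_net(co, seed = 6, epochs = 20)$W1))

  # degenerate labels are refused
  one_class <- drabc:::subset_cohort(co, co$group == "non_carrier")
  expect_error(train_net(one_class, epochs = 5), "single")
})

test_that("select_cutoff meets the target or maximizes sensitivity", {
  # perfectly separated
  tau <- select_cutoff(c(rep(0.9, 5), rep(0.1, 5)), c(rep(1, 5), rep(0, 5)))
  expect_equal(as.numeric(tau), 0.9)
  expect_equal(attr(tau, "sensitivity"), 1)

  # 10 positives scored 0.1..1.0, target 0.90 -> tau = 0.2 (9/10 called)
  tau <- select_cutoff(seq(0.1, 1, by = 0.1), rep(1, 10),
                       target_sensitivity = 0.90)
  expect_equal(as.numeric(tau), 0.2)
  expect_equal(attr(tau, "sensitivity"), 0.9)

  # all scores identical
  tau <- select_cutoff(rep(0.42, 6), c(1, 1, 0, 0, 0, 0))
  expect_equal(as.numeric(tau), 0.42)
  expect_equal(attr(tau, "sensitivity"), 1)

  expect_error(select_cutoff(runif(5), rep(0, 5)), "positive")
})

test_that("select_cutoff matches exhaustive search (brute-force oracle)", {
  brute <- function(scores, labels, target) {
    cand <- sort(unique(scores))
    sens <- vapply(cand, function(t) mean(scores[labels == 1] >= t),
                   numeric(1))
    hit <- cand[sens >= target]
    if (length(hit)) max(hit) else cand[which.max(sens)]
  }
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0) labels[sample(n, 1)] <- 1L
    target <- sample(c(0.5, 0.8, 0.9, 1), 1)
    expect_equal(as.numeric(select_cutoff(scores, labels, target)),
                 brute(scores, labels, target))
  }
})

test_that("sensitivity is non-increasing in the threshold (property)", {
  set.seed(5)
  for (rep in 1:20) {
    scores <- runif(30)
    labels <- rbinom(30, 1, 0.4)
    if (!sum(labels)) labels[1] <- 1L
    taus <- sort(unique(scores))
    sens <- vapply(taus, function(t) mean(scores[labels == 1] >= t),
                   numeric(1))
    expect_true(all(diff(sens) <= 0))
  }
})
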