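# ---- cutoff selection --------------------------------------------------------

#' Sensitivity-targeted decision threshold
#'
#' Candidate thresholds are the distinct observed scores; a record is called
#' positive when `score >= tau`. Returns the *largest* candidate achieving
#' sensitivity at or above `target_sensitivity`; when no candidate reaches
#' the target, returns the smallest candidate (the maximum-sensitivity
#' choice).
#'
#' @param scores numeric scores.
#' @param labels 0/1 outcome labels (at least one positive).
#' @param target_sensitivity default 0.90.
#' @return threshold, with attributes `sensitivity` and `attained`
#'   (TRUE when the target was reachable).
#' @export
select_cutoff <- function(scores, labels, target_sensitivity = 0.90) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  npos <- sum(labels == 1L)
  if (npos == 0L) stop("select_cutoff requires at least one positive label")
  cand <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(cand, function(tau) sum(scores >= tau & labels == 1L) / npos,
                 numeric(1))
  ok <- sens >= target_sensitivity
  i <- if (any(ok)) which(ok)[1L] else length(cand)
  structure(cand[i], sensitivity = sens[i], attained = any(ok))
}

# ---- ensemble training -------------------------------------------------------

#' Train the ensemble model
#'
#' Trains `n_members` networks (default 101) with member seeds
#' `seed, seed + 1, ..., seed + n_members - 1`, each on a bootstrap resample
#' of the training records (bagging; switchable off). The ensemble score of
#' a record is the arithmetic mean of the member `(P1, P2)` outputs, pushed
#' through the chain rule; decision thresholds for the three scenarios are
#' selected on the training cohort's ensemble scores at the target
#' sensitivity. `age_center`/`age_scale` of the encoding are refit from the
#' training ages and serialized with the model.
#'
#' @param cohort labeled, complete `drabc_cohort` (run [apply_exclusions()]
#'   first on raw data).
#' @param n_members ensemble size (default 101).
#' @param seed base integer seed.
#' @param bootstrap bagging on/off.
#' @param aggregate `"mean"` (average member probabilities, default) or
#'   `"vote"` (majority over member-level calls is emulated by the median).
#' @param target_sensitivity cutoff-selection target (default 0.90).
#' @param zero_features encoded feature names forced to zero at training and
#'   prediction time (feature-ablation support).
#' @param epochs,learning_rate,batch_size,dropout per-member optimizer
#'   settings (see [train_net()]).
#' @return object of class `drabc_ensemble`.
#' @export
train_ensemble <- function(cohort, n_members = 101L, seed = 1L,
                           bootstrap = TRUE,
                           aggregate = c("mean", "vote"),
                           target_sensitivity = 0.90,
                           zero_features = character(0),
                           epochs = 200L, learning_rate = 1e-3,
                           batch_size = 64L, dropout = 0.25) {
  aggregate <- match.arg(aggregate)
  stopifnot(has_labels(cohort), n_members >= 1L)
  spec <- encoding_spec(
    age_center = mean(cohort$age_at_diagnosis),
    age_scale = max(sd(cohort$age_at_diagnosis), 1e-6))
  X <- encode_cohort(cohort, spec)
  X <- zero_feature_block(X, zero_features, spec)
  tg <- carrier_targets(cohort$group)
  n <- nrow(X)

  members <- vector("list", n_members)
  for (k in seq_len(n_members)) {
    member_seed <- as.integer(seed) + k - 1L
    idx <- if (bootstrap) {
      set.seed(member_seed)
      sample.int(n, n, replace = TRUE)
    } else seq_len(n)
    members[[k]] <- train_net(x = X[idx, , drop = FALSE],
                              y_any = tg$y_any[idx], y_brca = tg$y_brca[idx],
                              epochs = epochs, learning_rate = learning_rate,
                              batch_size = batch_size, dropout = dropout,
                              seed = member_seed)
  }

  model <- structure(list(members = members, encoding = spec,
                          aggregate = aggregate,
                          zero_features = zero_features,
                          thresholds = NULL,
                          training_meta = list(
                            n_members = n_members, seed = as.integer(seed),
                            bootstrap = bootstrap, n_train = n,
                            target_sensitivity = target_sensitivity,
                            hyper = list(epochs = epochs,
                                         learning_rate = learning_rate,
                                         batch_size = batch_size,
                                         dropout = dropout))),
                     class = "drabc_ensemble")

  tr <- ensemble_scores(model, X)
  model$thresholds <- list(
    tau_any = select_cutoff(tr$p_any, tg$y_any, target_sensitivity),
    tau_brca = select_cutoff(tr$p_brca,
                             as.integer(!is.na(tg$y_brca) & tg$y_brca == 1L),
                             target_sensitivity),
    tau_other = select_cutoff(tr$p_other,
                              as.integer(!is.na(tg$y_brca) & tg$y_brca == 0L),
                              target_sensitivity))
  model$training_meta$training_sensitivity <- vapply(
    model$thresholds, function(t) attr(t, "sensitivity"), numeric(1))
  model
}

zero_feature_block <- function(X, zero_features, spec) {
  if (!length(zero_features)) return(X)
  unknown <- setdiff(zero_features, spec$feature_order)
  if (length(unknown))
    stop("unknown encoded feature(s): ", paste(unknown, collapse = ", "))
  X[, zero_features] <- 0
  X
}

# mean member (P1, P2) -> chain rule; "vote" uses the member median instead
ensemble_scores <- function(model, X) {
  acc1 <- matrix(NA_real_, nrow(X), length(model$members))
  acc2 <- acc1
  for (k in seq_along(model$members)) {
    P <- net_forward(model$members[[k]], X, mode = "infer")
    acc1[, k] <- P[, 1L]
    acc2[, k] <- P[, 2L]
  }
  agg <- if (model$aggregate == "mean") rowMeans else
    function(m) apply(m, 1L, stats::median)
  derive_probabilities(agg(acc1), agg(acc2))
}

#' @export
print.drabc_ensemble <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf(
    "<drabc_ensemble> %d members; thresholds any=%.4f brca=%.4f other=%.4f\n",
    length(x$members), th$tau_any, th$tau_brca, th$tau_other))
  invisible(x)
}

#' Predict carrier risks for a cohort
#'
#' Per record: ensemble `(P1, P2)` in inference mode (no dropout), the
#' chain-rule probabilities, and the three scenario calls at the model's
#' thresholds (`score >= tau`).
#'
#' @param object a `drabc_ensemble`.
#' @param cohort a `drabc_cohort`, complete w.r.t. the model encoding.
#' @param ... unused.
#' @return data.frame: `patient_id`, `p_any`, `p_brca`, `p_other`,
#'   `call_any`, `call_brca`, `call_other`.
#' @export
predict.drabc_ensemble <- function(object, cohort, ...) {
  X <- encode_cohort(cohort, object$encoding)
  X <- zero_feature_block(X, object$zero_features, object$encoding)
  sc <- ensemble_scores(object, X)
  th <- object$thresholds
  data.frame(patient_id = cohort$patient_id, sc,
             call_any = sc$p_any >= as.numeric(th$tau_any),
             call_brca = sc$p_brca >= as.numeric(th$tau_brca),
             call_other = sc$p_other >= as.numeric(th$tau_other))
}

# ---- model serialization (JSON container) -----------------------------------

#' Write / read an ensemble model (JSON)
#'
#' The container stores member weights as nested arrays together with the
#' encoding spec, thresholds and training metadata; it is portable and
#' diff-able.
#'
#' @param model a `drabc_ensemble`.
#' @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "drabc_ensemble"))
  payload <- list(
    format = "drabc_ensemble/1",
    encoding = encoding_to_list(model$encoding),
    aggregate = model$aggregate,
    zero_features = as.list(model$zero_features),
    thresholds = lapply(model$thresholds, function(t)
      list(value = as.numeric(t), sensitivity = attr(t, "sensitivity"),
           attained = attr(t, "attained"))),
    training_meta = model$training_meta,
    members = lapply(model$members, function(m)
      list(W1 = m$W1, b1 = m$b1, W2 = m$W2, b2 = m$b2, W3 = m$W3, b3 = m$b3,
           dropout_rate = m$dropout_rate)))
  # digits = I(17): significant-digit formatting that round-trips doubles
  # exactly, so a reloaded model reproduces calls at threshold boundaries
  atomic_write(path, function(tmp)
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = I(17)))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (!identical(x$format, "drabc_ensemble/1"))
    stop("not a drabc ensemble container: ", path)
  members <- lapply(seq_len(nrow_of(x$members)), function(k) {
    m <- member_slice(x$members, k)
    hier_net(m$W1, m$b1, m$W2, m$b2, m$W3, m$b3,
             dropout_rate = m$dropout_rate)
  })
  thresholds <- lapply(x$thresholds, function(t)
    structure(t$value, sensitivity = t$sensitivity, attained = t$attained))
  structure(list(members = members,
                 encoding = encoding_from_list(x$encoding),
                 aggregate = x$aggregate,
                 zero_features = unlist(x$zero_features) %||% character(0),
                 thresholds = thresholds,
                 training_meta = x$training_meta),
            class = "drabc_ensemble")
}

# jsonlite may simplify the member list into a data.frame-like structure;
# normalize both layouts
nrow_of <- function(members)
  if (is.data.frame(members)) nrow(members) else length(members)

member_slice <- function(members, k) {
  if (is.data.frame(members))
    lapply(members, function(col) if (is.list(col)) col[[k]] else col[k])
  else members[[k]]
}
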