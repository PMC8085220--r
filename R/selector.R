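# Event selection: a small fully connected network (2 -> 80 -> 40 -> 1,
# ReLU / ReLU / sigmoid, dropout 0.25 after the first hidden layer during
# training) that classifies coincidence events as signal or background
# from the two measured plane energies alone, trained by minimizing
# binary cross-entropy. Implemented directly with matrix operations; the
# architecture is small enough that no deep-learning framework is
# needed, and inference stays a pure function of (E1, E2).

.relu <- function(x) pmax(x, 0)
.sigmoid <- function(x) 1 / (1 + exp(-x))

.bce <- function(p, y, w = NULL) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- y * log(p) + (1 - y) * log(1 - p)
  if (is.null(w)) -mean(ll) else -sum(w * ll) / sum(w)
}

.selector_forward <- function(model, X) {
  if (isTRUE(model$standardize)) {
    X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  }
  H1 <- .relu(sweep(X %*% model$W1, 2, model$b1, "+"))
  H2 <- .relu(sweep(H1 %*% model$W2, 2, model$b2, "+"))
  as.numeric(.sigmoid(H2 %*% model$W3 + model$b3))
}

.event_features <- function(events) {
  as.matrix(events[, c("E1", "E2"), drop = FALSE])
}

.he_init <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

#' Build a selector model from explicit weights
#'
#' Mostly for testing and for loading saved models; [train_selector()] is
#' the normal constructor.
#'
#' @param W1,b1,W2,b2,W3,b3 layer weights/biases (2x80, 80, 80x40, 40,
#'   40x1, 1 for the default architecture; any compatible sizes work).
#' @param threshold decision threshold on the sigmoid output.
#' @param standardize whether inputs are standardized with `center`/`scale`.
#' @param center,scale feature standardization parameters.
#' @return object of class `pg_selector`.
#' @export
selector_model <- function(W1, b1, W2, b2, W3, b3, threshold = 0.5,
                           standardize = FALSE, center = c(0, 0),
                           scale = c(1, 1)) {
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 W3 = as.matrix(W3), b3 = b3,
                 threshold = threshold, standardize = standardize,
                 center = center, scale = scale,
                 history = NULL),
            class = "pg_selector")
}

#' Train the signal/background event selector
#'
#' Splits the labeled events into equally sized training and validation
#' halves (default `val_fraction = 0.5`), then minimizes binary
#' cross-entropy with Adam and inverted dropout after the first hidden
#' layer. Training stops after `epochs` epochs or when the validation
#' loss has not improved for `patience` epochs, whichever comes first;
#' the weights with the best validation loss are kept. Deterministic
#' given `seed`.
#'
#' @param events labeled event data.frame (columns `E1`, `E2`, `label`).
#' @param hidden hidden-layer sizes.
#' @param dropout dropout rate after the first hidden layer (training
#'   only; inference is deterministic).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum number of epochs.
#' @param patience early-stopping patience on validation loss.
#' @param val_fraction fraction of events held out for validation.
#' @param standardize standardize the two energy features (recorded in
#'   the model; default FALSE, energies are used in MeV as measured).
#' @param balance_classes weight the two classes inversely to their
#'   frequencies in the binary cross-entropy (default TRUE). At the low
#'   signal prevalence of coincidence data an unweighted classifier
#'   collapses to rejecting everything; balanced weights make the 0.5
#'   cut a likelihood-ratio test, which accepts a sizeable fraction of
#'   events while enriching the signal.
#' @param seed training seed.
#' @return a `pg_selector` with a `history` data.frame (per-epoch
#'   training and validation BCE).
#' @export
train_selector <- function(events, hidden = c(80, 40), dropout = 0.25,
                           lr = 1e-3, batch_size = 256, epochs = 100,
                           patience = 10, val_fraction = 0.5,
                           standardize = FALSE, balance_classes = TRUE,
                           seed = 1) {
  if (is.null(events$label) || anyNA(events$label))
    stop("training requires truth labels for every event")
  y_all <- as.numeric(events$label == "signal")
  if (length(unique(y_all)) < 2)
    pg_degenerate_training("training set contains a single class")
  set.seed(seed)

  X_all <- .event_features(events)
  n <- nrow(X_all)
  perm <- sample.int(n)
  n_val <- floor(n * val_fraction)
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  Xt <- X_all[tr_idx, , drop = FALSE]; yt <- y_all[tr_idx]
  Xv <- X_all[val_idx, , drop = FALSE]; yv <- y_all[val_idx]

  # per-class BCE weights (mean weight 1)
  if (balance_classes) {
    w_pos <- 0.5 / max(mean(yt), 1e-12)
    w_neg <- 0.5 / max(1 - mean(yt), 1e-12)
  } else {
    w_pos <- w_neg <- 1
  }
  wt <- ifelse(yt == 1, w_pos, w_neg)
  wv <- ifelse(yv == 1, w_pos, w_neg)

  center <- c(0, 0); scl <- c(1, 1)
  if (standardize) {
    center <- colMeans(Xt)
    scl <- apply(Xt, 2, sd)
    scl[scl == 0] <- 1
    Xt <- sweep(sweep(Xt, 2, center), 2, scl, "/")
    Xv <- sweep(sweep(Xv, 2, center), 2, scl, "/")
  }

  W1 <- .he_init(2, hidden[1]); b1 <- numeric(hidden[1])
  W2 <- .he_init(hidden[1], hidden[2]); b2 <- numeric(hidden[2])
  W3 <- .he_init(hidden[2], 1); b3 <- 0

  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3)
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0

  fwd_val <- function() {
    H1 <- .relu(sweep(Xv %*% params$W1, 2, params$b1, "+"))
    H2 <- .relu(sweep(H1 %*% params$W2, 2, params$b2, "+"))
    as.numeric(.sigmoid(H2 %*% params$W3 + params$b3))
  }

  nt <- nrow(Xt)
  history <- data.frame(epoch = integer(0), train_bce = numeric(0),
                        val_bce = numeric(0))
  best_val <- Inf; best <- params; stale <- 0

  for (ep in seq_len(epochs)) {
    ord <- sample.int(nt)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, nt, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, nt)]
      X <- Xt[idx, , drop = FALSE]; y <- yt[idx]
      w <- wt[idx]

      Z1 <- sweep(X %*% params$W1, 2, params$b1, "+")
      H1 <- .relu(Z1)
      if (dropout > 0) {
        mask <- matrix(runif(length(H1)) >= dropout, nrow(H1), ncol(H1)) /
          (1 - dropout)
        H1d <- H1 * mask
      } else {
        H1d <- H1
      }
      Z2 <- sweep(H1d %*% params$W2, 2, params$b2, "+")
      H2 <- .relu(Z2)
      p <- as.numeric(.sigmoid(H2 %*% params$W3 + params$b3))

      ep_loss <- ep_loss + .bce(p, y, w); nb <- nb + 1

      d3 <- matrix(w * (p - y) / sum(w), ncol = 1)
      gW3 <- crossprod(H2, d3); gb3 <- sum(d3)
      d2 <- (d3 %*% t(params$W3)) * (Z2 > 0)
      gW2 <- crossprod(H1d, d2); gb2 <- colSums(d2)
      d1 <- (d2 %*% t(params$W2))
      if (dropout > 0) d1 <- d1 * mask
      d1 <- d1 * (Z1 > 0)
      gW1 <- crossprod(X, d1); gb1 <- colSums(d1)

      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3)
      step <- step + 1
      for (pn in names(params)) {
        mom[[pn]] <- beta1 * mom[[pn]] + (1 - beta1) * grads[[pn]]
        vel[[pn]] <- beta2 * vel[[pn]] + (1 - beta2) * grads[[pn]]^2
        mhat <- mom[[pn]] / (1 - beta1^step)
        vhat <- vel[[pn]] / (1 - beta2^step)
        params[[pn]] <- params[[pn]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val_bce <- .bce(fwd_val(), yv, wv)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_bce = ep_loss / nb,
                                         val_bce = val_bce))
    if (val_bce < best_val - 1e-6) {
      best_val <- val_bce; best <- params; stale <- 0
    } else {
      stale <- stale + 1
      if (stale >= patience) break
    }
  }

  model <- selector_model(best$W1, best$b1, best$W2, best$b2, best$W3,
                          best$b3, threshold = 0.5,
                          standardize = standardize,
                          center = center, scale = scl)
  model$history <- history
  model$seed <- seed
  model
}

#' Selector scores for events
#'
#' Sigmoid outputs in (0, 1); inference is deterministic (dropout
#' disabled) and depends only on `(E1, E2)`.
#'
#' @param object a `pg_selector`.
#' @param newdata event data.frame or 2-column matrix.
#' @param ... unused.
#' @return numeric scores.
#' @export
predict.pg_selector <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else .event_features(newdata)
  .selector_forward(object, X)
}

#' Select events accepted by the trained network
#'
#' Keeps the events whose score is strictly greater than the model's
#' decision threshold (0.5), preserving order. Idempotent.
#'
#' @param model a `pg_selector`.
#' @param events event data.frame.
#' @return the accepted subset.
#' @export
select_events <- function(model, events) {
  scores <- predict(model, events)
  out <- events[scores > model$threshold, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("config", "seed")) attr(out, a) <- attr(events, a)
  out
}

#' Selection quality metrics
#'
#' Recall (percentage of the total true signal accepted), precision
#' (percentage of true signal among accepted events, which equals the
#' post-selection signal fraction), signal fractions before and after
#' selection, and the relative increase of the signal fraction. All as
#' percentages in full precision; the print method shows one decimal.
#'
#' @param events the full labeled event set before selection.
#' @param accepted the accepted subset (labels required).
#' @return object of class `pg_selection_metrics`.
#' @export
selection_metrics <- function(events, accepted) {
  if (is.null(events$label) || anyNA(events$label) ||
      is.null(accepted$label) || anyNA(accepted$label))
    pg_schema_error("selection metrics require truth labels on all events")
  selection_metrics_counts(
    n_total = nrow(events),
    n_signal = sum(events$label == "signal"),
    n_accepted = nrow(accepted),
    n_accepted_signal = sum(accepted$label == "signal")
  )
}

#' @rdname selection_metrics
#' @param n_total,n_signal,n_accepted,n_accepted_signal confusion counts;
#'   useful to evaluate the metrics on published tables.
#' @export
selection_metrics_counts <- function(n_total, n_signal, n_accepted,
                                     n_accepted_signal) {
  stopifnot(n_total >= n_signal, n_signal >= n_accepted_signal,
            n_accepted >= n_accepted_signal)
  if (n_accepted == 0)
    pg_undefined("no accepted events: precision undefined")
  if (n_signal == 0)
    pg_undefined("no signal events: recall undefined")
  before <- 100 * n_signal / n_total
  after <- 100 * n_accepted_signal / n_accepted
  structure(list(
    recall = 100 * n_accepted_signal / n_signal,
    precision = after,
    signal_fraction_before = before,
    signal_fraction_after = after,
    relative_increase = 100 * (after - before) / before
  ), class = "pg_selection_metrics")
}

#' @export
print.pg_selection_metrics <- function(x, ...) {
  cat(sprintf("recall %.1f%% | precision %.1f%% | signal %% %.1f -> %.1f (relative increase %.1f%%)\n",
              x$recall, x$precision, x$signal_fraction_before,
              x$signal_fraction_after, x$relative_increase))
  invisible(x)
}

#' Save / load a selector model
#'
#' Self-describing JSON container with the architecture, weights and
#' preprocessing flags; loading reproduces scores bit-for-bit on the
#' same platform.
#'
#' @param model a `pg_selector`.
#' @param path file path.
#' @return `load_selector` returns the model; `save_selector` the path,
#'   invisibly.
#' @export
save_selector <- function(model, path) {
  num <- function(x) sprintf("%.17g", as.numeric(x))  # exact round trip
  payload <- list(
    format = "pgcc-selector-v1",
    layers = list(ncol(model$W1), ncol(model$W2), 1),
    threshold = model$threshold,
    standardize = model$standardize,
    center = num(model$center), scale = num(model$scale),
    # weights flattened column-major with explicit dims
    dim_W1 = dim(model$W1), W1 = num(model$W1), b1 = num(model$b1),
    dim_W2 = dim(model$W2), W2 = num(model$W2), b2 = num(model$b2),
    W3 = num(model$W3), b3 = num(model$b3)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_selector
#' @export
load_selector <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "pgcc-selector-v1"))
    pg_integrity_error("not a pgcc selector file")
  selector_model(matrix(as.numeric(p$W1), p$dim_W1[1], p$dim_W1[2]),
                 as.numeric(p$b1),
                 matrix(as.numeric(p$W2), p$dim_W2[1], p$dim_W2[2]),
                 as.numeric(p$b2), matrix(as.numeric(p$W3), ncol = 1),
                 as.numeric(p$b3), threshold = p$threshold,
                 standardize = isTRUE(p$standardize),
                 center = as.numeric(p$center), scale = as.numeric(p$scale))
}
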