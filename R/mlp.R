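# The identification network: a shallow multilayer perceptron mapping a
# flattened step cycle to a participant. One hidden layer of twice the
# input width with hyperbolic-tangent activation, softmax cross-entropy
# readout, plain mini-batch gradient descent (batches of 25, at most 1000
# epochs). The network is bias-free by default so that the epsilon-rule
# relevance decomposition is conserved exactly layer to layer, and
# centers every input variable on its training-set mean so that both
# learning and the relevance decomposition operate on deviations from
# the cohort's average movement pattern.

#' Fit the step-cycle identification network
#'
#' @param x numeric matrix of scaled step cycles (rows) x variables.
#' @param labels participant label per row (coerced to factor).
#' @param hidden hidden-layer width; defaults to twice the input width.
#' @param batch_size mini-batch size.
#' @param epochs epoch limit.
#' @param lr learning rate of plain gradient descent.
#' @param seed integer seed for weight initialization and batch order.
#' @param use_bias add bias terms to both layers (off by default; see
#'   Details).
#' @param center subtract each variable's training-set mean before the
#'   network (default TRUE; see Details). The stored means are re-applied
#'   automatically by [predict.gait_mlp()] and [relevance()].
#' @param patience training stops early once training accuracy has been
#'   100% for this many consecutive epochs (the epoch limit is always
#'   honoured). The default of 150 keeps training running well past the
#'   point where training accuracy saturates, so that the softmax
#'   decision margins mature; held-out accuracy and relevance rankings
#'   are insensitive to the exact value over a wide range.
#' @details Weights are initialized uniformly in
#'   \eqn{\pm\sqrt{6/(fan_{in}+fan_{out})}}. Without bias terms the total
#'   input relevance of the epsilon-rule decomposition equals the
#'   explained output score up to the stabilizer, which keeps relevance
#'   conservation checkable; biases can be enabled for sensitivity work.
#'
#'   Centering removes the cohort-average waveform that all participants
#'   share. Without it, variables with a large common amplitude receive
#'   systematic weight updates (the gradient on an input's weights is
#'   proportional to its activation, whether or not it discriminates
#'   between participants) and consequently attract relevance mass that
#'   reflects amplitude rather than identity. On centered inputs the
#'   network and its relevance decomposition respond only to deviations
#'   from the average movement pattern, i.e. to what is individual.
#' @return Object of class `gait_mlp`: weight matrices `W1`, `W2`
#'   (optional `b1`, `b2`), the training-mean vector `center` (NULL when
#'   centering is disabled), the label `levels`, the fitting `config` and
#'   a per-epoch training `log` (epoch, loss, accuracy).
#' @export
gait_mlp <- function(x, labels, hidden = 2L * ncol(x), batch_size = 25L,
                     epochs = 1000L, lr = 0.01, seed = 1L,
                     use_bias = FALSE, center = TRUE, patience = 150L) {
  x <- as.matrix(x)
  ctr <- if (center) colMeans(x) else NULL
  if (center) x <- sweep(x, 2L, ctr)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 participants", call. = FALSE)
  if (any(table(labels) < 1)) stop("every participant needs >= 1 cycle",
                                   call. = FALSE)
  n <- nrow(x); p <- ncol(x); k <- nlevels(labels)
  batch_size <- min(batch_size, n)
  y <- diag(k)[as.integer(labels), , drop = FALSE]

  init <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  set.seed(as.integer(seed))
  W1 <- init(p, hidden); W2 <- init(hidden, k)
  b1 <- numeric(hidden); b2 <- numeric(k)

  log_epoch <- integer(0); log_loss <- numeric(0); log_acc <- numeric(0)
  perfect <- 0L
  epochs <- as.integer(epochs)
  if (epochs > 0) {
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]; yb <- y[idx, , drop = FALSE]
        h <- tanh(sweep_bias(xb %*% W1, b1, use_bias))
        s <- sweep_bias(h %*% W2, b2, use_bias)
        pr <- softmax(s)
        ds <- (pr - yb) / nrow(xb)
        gW2 <- crossprod(h, ds)
        dh <- (ds %*% t(W2)) * (1 - h^2)
        gW1 <- crossprod(xb, dh)
        W2 <- W2 - lr * gW2
        W1 <- W1 - lr * gW1
        if (use_bias) {
          b2 <- b2 - lr * colSums(ds)
          b1 <- b1 - lr * colSums(dh)
        }
      }
      h <- tanh(sweep_bias(x %*% W1, b1, use_bias))
      s <- sweep_bias(h %*% W2, b2, use_bias)
      pr <- softmax(s)
      loss <- -mean(log(pmax(pr[cbind(seq_len(n), as.integer(labels))], 1e-300)))
      if (!is.finite(loss)) {
        stop("training diverged: non-finite loss at epoch ", e, call. = FALSE)
      }
      acc <- mean(max.col(s, ties.method = "first") == as.integer(labels))
      log_epoch <- c(log_epoch, e); log_loss <- c(log_loss, loss)
      log_acc <- c(log_acc, acc)
      perfect <- if (acc == 1) perfect + 1L else 0L
      if (perfect >= patience) break
    }
  }

  structure(list(
    W1 = W1, W2 = W2,
    b1 = if (use_bias) b1 else NULL, b2 = if (use_bias) b2 else NULL,
    center = ctr,
    levels = levels(labels),
    config = list(input_nodes = p, hidden_nodes = hidden, output_nodes = k,
                  batch_size = batch_size, epoch_limit = epochs, lr = lr,
                  seed = seed, use_bias = use_bias, center = center,
                  patience = patience,
                  loss = "softmax cross-entropy"),
    log = data.frame(epoch = log_epoch, loss = log_loss, accuracy = log_acc)
  ), class = "gait_mlp")
}

sweep_bias <- function(z, b, use_bias) {
  if (use_bias) sweep(z, 2L, b, "+") else z
}

softmax <- function(s) {
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

forward_mlp <- function(object, x) {
  use_bias <- isTRUE(object$config$use_bias)
  x <- as.matrix(x)
  if (!is.null(object$center)) x <- sweep(x, 2L, object$center)
  a1 <- x %*% object$W1
  if (use_bias) a1 <- sweep(a1, 2L, object$b1, "+")
  h <- tanh(a1)
  s <- h %*% object$W2
  if (use_bias) s <- sweep(s, 2L, object$b2, "+")
  list(hidden = h, scores = s)
}

#' Predict participants for step cycles
#'
#' @param object a fitted [gait_mlp()].
#' @param newdata matrix of cycles x variables (same layout as training).
#' @param type "class" for predicted participant labels, "score" for the
#'   pre-softmax output scores, "prob" for softmax probabilities.
#' @param ... unused.
#' @return Factor of predictions, or a numeric matrix for
#'   `type = "score"`/`"prob"`. Ties in the output scores are broken in
#'   favour of the lowest class index.
#' @export
predict.gait_mlp <- function(object, newdata,
                             type = c("class", "score", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$config$input_nodes) {
    stop("newdata has ", ncol(newdata), " variables; the network expects ",
         object$config$input_nodes, call. = FALSE)
  }
  s <- forward_mlp(object, newdata)$scores
  colnames(s) <- object$levels
  switch(type,
         class = factor(object$levels[max.col(s, ties.method = "first")],
                        levels = object$levels),
         score = s,
         prob = softmax(s))
}

#' @export
print.gait_mlp <- function(x, ...) {
  cfg <- x$config
  cat("Step-cycle identification network (tanh MLP)\n")
  cat(sprintf("  layers: %d -> %d -> %d%s%s\n", cfg$input_nodes,
              cfg$hidden_nodes, cfg$output_nodes,
              if (cfg$use_bias) " (with biases)" else "",
              if (isTRUE(cfg$center)) ", mean-centered inputs" else ""))
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  trained %d epochs (limit %d); final training accuracy %.1f%%\n",
                last$epoch, cfg$epoch_limit, 100 * last$accuracy))
  } else {
    cat("  untrained (epoch limit 0): initialized weights only\n")
  }
  invisible(x)
}

#' @export
summary.gait_mlp <- function(object, ...) {
  out <- list(config = object$config, log = object$log,
              n_weights = length(object$W1) + length(object$W2))
  class(out) <- "summary.gait_mlp"
  out
}

#' @export
print.summary.gait_mlp <- function(x, ...) {
  cat(sprintf("tanh MLP %d -> %d -> %d, %d weights, %s loss\n",
              x$config$input_nodes, x$config$hidden_nodes,
              x$config$output_nodes, x$n_weights, x$config$loss))
  if (nrow(x$log)) {
    cat("training log (last 5 epochs):\n")
    print(utils::tail(x$log, 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.gait_mlp <- function(object, ...) {
  out <- list(W1 = object$W1, W2 = object$W2)
  if (isTRUE(object$config$use_bias)) {
    out$b1 <- object$b1; out$b2 <- object$b2
  }
  out
}

#' Participant-wise identification accuracy
#'
#' Accuracy(p) = n_p / N_p * 100, the percentage of a participant's
#' cycles assigned to them; the overall accuracy pools all cycles.
#' Participants absent from `truth` are reported as NA rather than 0.
#'
#' @param predictions predicted labels.
#' @param truth true labels (defines the participant set).
#' @return List with `per_participant` (data.frame participant,
#'   n_correct, n_total, accuracy) and `overall` (percent).
#' @export
accuracy_by_participant <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth))
  if (!is.factor(truth)) truth <- factor(truth)
  predictions <- as.character(predictions)
  unseen <- setdiff(unique(predictions), levels(truth))
  if (length(unseen)) {
    warning("predictions contain labels absent from truth; counted incorrect")
  }
  per <- data.frame(participant = levels(truth), n_correct = NA_integer_,
                    n_total = NA_integer_, accuracy = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(per))) {
    rows <- truth == per$participant[i]
    per$n_total[i] <- sum(rows)
    if (per$n_total[i] == 0) next
    per$n_correct[i] <- sum(predictions[rows] == per$participant[i])
    per$accuracy[i] <- per$n_correct[i] / per$n_total[i] * 100
  }
  overall <- sum(per$n_correct, na.rm = TRUE) /
    sum(per$n_total[per$n_total > 0]) * 100
  list(per_participant = per, overall = overall)
}

#' Draw a seeded training subset of cycles per participant
#'
#' @param info row metadata of the cycle matrix (column `participant`).
#' @param n_per_participant training cycles per participant.
#' @param seed integer seed.
#' @param trials restrict sampling to these trial labels (e.g. the
#'   pooled CR/WR training runs).
#' @return Integer row indices into the matrix.
#' @export
sample_training_cycles <- function(info, n_per_participant, seed = 1L,
                                   trials = NULL) {
  pool <- seq_len(nrow(info))
  if (!is.null(trials)) pool <- pool[info$trial[pool] %in% trials]
  with_seed(seed, {
    unlist(lapply(split(pool, info$participant[pool]), function(rows) {
      if (length(rows) < n_per_participant) {
        stop("not enough cycles to sample ", n_per_participant,
             " per participant", call. = FALSE)
      }
      sample(rows, n_per_participant)
    }), use.names = FALSE)
  })
}
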