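#' Train a small back-propagation network
#'
#' Single-hidden-layer feed-forward network (default 14-6-2 for two-channel,
#' seven-scale feature vectors): sigmoid hidden units, identity outputs,
#' one-hot targets and mean-squared-error loss, trained by full-batch
#' gradient descent with a loss-plateau early stop. Features are
#' standardised internally using training-set statistics. Deterministic
#' given `seed`.
#'
#' @param x Numeric matrix or data frame of features (rows = trials).
#' @param y Class labels (factor or coercible; exactly two classes).
#' @param hidden Number of hidden units.
#' @param learning_rate Gradient-descent step size.
#' @param max_epochs Maximum training epochs.
#' @param tol,patience Early stop when the loss improves by less than `tol`
#'   over `patience` epochs.
#' @param seed Seed for the uniform small-range weight initialisation.
#' @param standardize Standardise columns with training mean/SD.
#' @return An object of class `"bp_net"`.
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' fit <- bp_train(x, rep(c("a", "b"), each = 20), seed = 1)
#' mean(predict(fit, x) == rep(c("a", "b"), each = 20))
#' @export
bp_train <- function(x, y, hidden = 6, learning_rate = 0.05,
                     max_epochs = 2000, tol = 1e-6, patience = 50,
                     seed = 1, standardize = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x) || !all(is.finite(x))) {
    abort("x must be a finite numeric matrix")
  }
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L) {
    abort("y must contain exactly two classes")
  }
  y <- droplevels(y)
  if (nrow(x) != length(y)) abort("x and y sizes differ")
  hidden <- check_count(hidden, "hidden")
  max_epochs <- check_count(max_epochs, "max_epochs")

  ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  }
  X <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  Tg <- cbind(as.numeric(y == levels(y)[1]), as.numeric(y == levels(y)[2]))
  n_obs <- nrow(X); p <- ncol(X)

  withr::with_seed(as.integer(seed), {
    W1 <- matrix(runif(p * hidden, -0.5, 0.5), p, hidden)
    b1 <- runif(hidden, -0.5, 0.5)
    W2 <- matrix(runif(hidden * 2L, -0.5, 0.5), hidden, 2L)
    b2 <- runif(2L, -0.5, 0.5)
  })

  loss <- numeric(max_epochs)
  epoch <- 0L
  for (e in seq_len(max_epochs)) {
    H <- 1 / (1 + exp(-(X %*% W1 + rep(b1, each = n_obs))))
    O <- H %*% W2 + rep(b2, each = n_obs)
    E <- O - Tg
    loss[e] <- mean(rowSums(E^2))  # per-sample squared error
    epoch <- e
    if (e > patience && loss[e - patience] - loss[e] < tol) break
    dO <- 2 * E / n_obs
    dW2 <- crossprod(H, dO)
    db2 <- colSums(dO)
    dH <- (dO %*% t(W2)) * H * (1 - H)
    dW1 <- crossprod(X, dH)
    db1 <- colSums(dH)
    W2 <- W2 - learning_rate * dW2
    b2 <- b2 - learning_rate * db2
    W1 <- W1 - learning_rate * dW1
    b1 <- b1 - learning_rate * db1
  }

  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 levels = levels(y), center = ctr, scale = scl,
                 loss = loss[seq_len(epoch)], epochs = epoch,
                 converged = epoch < max_epochs,
                 learning_rate = learning_rate, hidden = hidden,
                 seed = seed),
            class = "bp_net")
}

#' Predict classes or network outputs from a fitted bp_net
#'
#' Class predictions take the argmax of the two linear outputs; an exact
#' tie resolves deterministically to the first class level.
#'
#' @param object A `"bp_net"` fit.
#' @param newdata Feature matrix or data frame with the training dimension.
#' @param type `"class"` (default) or `"response"` (raw output matrix).
#' @param ... Unused.
#' @return A factor of predicted labels, or the n x 2 output matrix.
#' @export
predict.bp_net <- function(object, newdata, type = c("class", "response"),
                           ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$center)) {
    abort(sprintf("newdata has %d features; the model expects %d",
                  ncol(X), length(object$center)))
  }
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  H <- 1 / (1 + exp(-(X %*% object$W1 + rep(object$b1, each = nrow(X)))))
  O <- H %*% object$W2 + rep(object$b2, each = nrow(X))
  if (type == "response") return(O)
  factor(object$levels[max.col(O, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.bp_net <- function(x, ...) {
  cat(sprintf("<bp_net> %d-%d-2, %d epochs (final loss %.4g)%s\n",
              length(x$center), x$hidden, x$epochs,
              x$loss[length(x$loss)],
              if (x$converged) ", plateau stop" else ""))
  invisible(x)
}

#' @method glance bp_net
#' @export
glance.bp_net <- function(x, ...) {
  tibble::tibble(epochs = x$epochs, final_loss = x$loss[length(x$loss)],
                 converged = x$converged, hidden = x$hidden,
                 n_features = length(x$center))
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs `repeats` independent rounds of stratified `k`-fold
#' cross-validation of the back-propagation classifier on a feature table,
#' training a fresh network on each training split and scoring the held-out
#' fold. Yields `k * repeats` accuracies in percent (100 values for the
#' standard 10 x 10 protocol), the unit of the downstream statistical
#' comparison. Fold assignment for repeat `r` and every model seed are
#' derived from `seed`, so the whole procedure is reproducible.
#'
#' @param data Data frame holding one row per trial: a label column, an
#'   optional `trial` id column (ignored), and numeric feature columns
#'   (e.g. the output of [extract_features()]).
#' @param label Name of the label column (default `"label"`).
#' @param k Number of folds.
#' @param repeats Number of repetitions.
#' @param seed Master seed.
#' @inheritParams bp_train
#' @return An object of class `"wcmfe_cv"`: a list with `accuracies` (a
#'   tibble with `rep`, `fold`, `accuracy` in %), `folds` (a tibble with
#'   the held-out row index per rep/fold, for auditing), and the settings.
#'   Use [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' df <- tibble::tibble(label = rep(c("a", "b"), each = 15),
#'                      f1 = c(rnorm(15), rnorm(15, 4)),
#'                      f2 = rnorm(30))
#' glance(repeated_cv(df, k = 3, repeats = 2, seed = 1))
#' @export
repeated_cv <- function(data, label = "label", k = 10, repeats = 10,
                        seed = 1, hidden = 6, learning_rate = 0.05,
                        max_epochs = 2000, tol = 1e-6, patience = 50) {
  if (!is.data.frame(data)) abort("data must be a data frame")
  if (!label %in% names(data)) {
    abort(sprintf("label column '%s' not found", label))
  }
  k <- check_count(k, "k")
  repeats <- check_count(repeats, "repeats")
  y <- droplevels(as.factor(data[[label]]))
  if (nlevels(y) != 2L) abort("exactly two classes are required")
  feat_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                       c(label, "trial"))
  if (length(feat_cols) == 0) abort("no numeric feature columns found")
  X <- as.matrix(data[feat_cols])
  n_obs <- nrow(X)
  if (k > n_obs) abort(sprintf("k = %d exceeds n = %d", k, n_obs))

  acc <- vector("list", repeats)
  fold_log <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- withr::with_seed(as.integer(seed) + r, {
      f <- integer(n_obs)
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        f[idx] <- rep_len(seq_len(k), length(idx))
      }
      f
    })
    a <- numeric(k)
    for (fd in seq_len(k)) {
      test <- which(folds == fd)
      train <- which(folds != fd)
      if (nlevels(droplevels(y[train])) != 2L) {
        abort("a training fold lost a class; reduce k")
      }
      fit <- bp_train(X[train, , drop = FALSE], y[train], hidden = hidden,
                      learning_rate = learning_rate,
                      max_epochs = max_epochs, tol = tol,
                      patience = patience,
                      seed = as.integer(seed) + 1000L * r + fd)
      pred <- predict(fit, X[test, , drop = FALSE])
      a[fd] <- 100 * mean(pred == y[test])
    }
    acc[[r]] <- tibble::tibble(rep = r, fold = seq_len(k), accuracy = a)
    fold_log[[r]] <- tibble::tibble(rep = r, fold = folds,
                                    index = seq_len(n_obs))
  }

  structure(list(accuracies = dplyr::bind_rows(acc),
                 folds = dplyr::bind_rows(fold_log),
                 k = k, repeats = repeats, seed = seed, n = n_obs,
                 features = feat_cols),
            class = "wcmfe_cv")
}

#' @export
print.wcmfe_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<wcmfe_cv> %d x %d-fold CV on %d trials: mean %.2f%%, sd %.2f\n",
              x$repeats, x$k, x$n, g$mean, g$sd))
  invisible(x)
}

#' Per-fold accuracies of a cross-validation run
#' @param x A `"wcmfe_cv"` object.
#' @param ... Unused.
#' @return A tibble with columns `rep`, `fold`, `accuracy` (%).
#' @method tidy wcmfe_cv
#' @export
tidy.wcmfe_cv <- function(x, ...) x$accuracies

#' One-row summary of a cross-validation run
#' @param x A `"wcmfe_cv"` object.
#' @param ... Unused.
#' @return A tibble with `mean`, `sd`, `min`, `max` of the fold accuracies
#'   (%), and `n_folds`.
#' @method glance wcmfe_cv
#' @export
glance.wcmfe_cv <- function(x, ...) {
  a <- x$accuracies$accuracy
  tibble::tibble(mean = mean(a), sd = sd(a), min = min(a), max = max(a),
                 n_folds = length(a))
}
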