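# Minimal dense multilayer perceptron: glorot-uniform init, tanh hidden
# layers, softmax output, minibatch SGD on categorical cross-entropy.
# Written in plain matrix algebra; sizes here (a few thousand cells, a few
# thousand genes, 16-unit layers) need nothing heavier.

.glorot_uniform <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.mlp_forward <- function(weights, biases, X) {
  L <- length(weights)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% weights[[l]]
    z <- sweep(z, 2, biases[[l]], `+`)
    acts[[l + 1]] <- if (l < L) tanh(z) else .softmax(z)
  }
  acts
}

.xent <- function(p, y_onehot) {
  -mean(rowSums(y_onehot * log(pmax(p, 1e-12))))
}

#' Train the dosage-group multilayer perceptron
#'
#' Architecture: an initial 16-unit layer, three 16-unit hidden layers and a
#' 3-unit output layer; glorot-uniform initialization, hyperbolic-tangent
#' activations, softmax output. Optimized by minibatch stochastic gradient
#' descent on categorical cross-entropy for `epochs` passes over a seeded,
#' class-stratified 65/35 train/validation split. Targets are one-hot encoded
#' in fixed label order (low, intermediate, high). By default each feature is
#' z-scored on the training split first (the scaling step single-cell
#' toolkits apply before such models; with thousands of unstandardized
#' log-normalized inputs the first tanh layer saturates and training stalls
#' at the class prior); `standardize = FALSE` feeds the values as given.
#'
#' @param X normalized genes x cells matrix (or SingleCellExperiment with
#'   `logcounts`), restricted to the features the model should see.
#' @param labels per-cell class labels (>= 3 classes for the default output
#'   width; the output layer adapts to the number of classes).
#' @param epochs training epochs (the "200 iterations" of the protocol, read
#'   as epochs of the optimizer).
#' @param train_fraction fraction of cells in the training split.
#' @param learning_rate,batch_size SGD hyperparameters (framework defaults).
#' @param hidden_units width of the four tanh layers.
#' @param standardize z-score each feature on the training split first.
#' @param seed integer seed controlling init, split and shuffling.
#' @return a `kdn_mlp` object: weights/biases, config, feature and class
#'   names, train/validation indices, initial/final training loss, and
#'   validation accuracy.
#' @export
train_mlp <- function(X, labels, epochs = 200, train_fraction = 0.65,
                      learning_rate = 0.01, batch_size = 32,
                      hidden_units = 16, standardize = TRUE, seed = 1L) {
  m <- .get_logcounts(X)
  .stopifnot_named(m, "X")
  xs <- t(as.matrix(m))            # cells x genes
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(xs))
  classes <- if (all(unique(labels) %in% .DOSAGE_LEVELS))
    .DOSAGE_LEVELS[.DOSAGE_LEVELS %in% labels] else sort(unique(labels))
  y <- match(labels, classes)
  if (anyNA(y)) stop("labels outside the class set")
  n_class <- length(classes)

  set.seed(as.integer(seed))
  train_idx <- unlist(lapply(seq_len(n_class), function(k) {
    ids <- which(y == k)
    sample(ids, round(train_fraction * length(ids)))
  }), use.names = FALSE)
  val_idx <- setdiff(seq_len(nrow(xs)), train_idx)
  if (length(unique(y[train_idx])) < n_class)
    stop("a class is absent from the training split")

  ctr <- NULL; sc <- NULL
  if (standardize) {
    ctr <- colMeans(xs[train_idx, , drop = FALSE])
    sc <- apply(xs[train_idx, , drop = FALSE], 2, sd)
    sc[sc == 0] <- 1
    xs <- sweep(sweep(xs, 2, ctr), 2, sc, `/`)
  }

  d <- ncol(xs)
  sizes <- c(d, rep(hidden_units, 4), n_class)
  weights <- biases <- vector("list", 5)
  for (l in 1:5) {
    weights[[l]] <- .glorot_uniform(sizes[l], sizes[l + 1])
    biases[[l]] <- numeric(sizes[l + 1])
  }
  w1_init <- weights[[1]]

  Xtr <- xs[train_idx, , drop = FALSE]
  Ytr <- diag(n_class)[y[train_idx], , drop = FALSE]
  n_tr <- nrow(Xtr)
  initial_loss <- .xent(.mlp_forward(weights, biases, Xtr)[[6]], Ytr)

  for (ep in seq_len(epochs)) {
    ord <- sample(n_tr)
    for (start in seq(1, n_tr, by = batch_size)) {
      b <- ord[start:min(start + batch_size - 1, n_tr)]
      acts <- .mlp_forward(weights, biases, Xtr[b, , drop = FALSE])
      delta <- (acts[[6]] - Ytr[b, , drop = FALSE]) / length(b)
      for (l in 5:1) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1)
          delta <- (delta %*% t(weights[[l]])) * (1 - acts[[l]]^2)
        weights[[l]] <- weights[[l]] - learning_rate * gW
        biases[[l]] <- biases[[l]] - learning_rate * gb
      }
    }
  }
  final_loss <- .xent(.mlp_forward(weights, biases, Xtr)[[6]], Ytr)

  model <- structure(list(
    weights = weights, biases = biases, w1_init = w1_init,
    classes = classes, features = colnames(xs),
    center = ctr, scale = sc,
    config = list(epochs = epochs, train_fraction = train_fraction,
                  learning_rate = learning_rate, batch_size = batch_size,
                  hidden_units = hidden_units, standardize = standardize,
                  seed = as.integer(seed)),
    train_idx = sort(train_idx), val_idx = val_idx,
    initial_loss = initial_loss, final_loss = final_loss),
    class = "kdn_mlp")

  val <- predict(model, m[, val_idx, drop = FALSE], truth = labels[val_idx])
  model$validation_accuracy <- val$accuracy
  model$validation_confusion <- val$confusion
  model
}

#' Predict dosage groups with a trained MLP
#'
#' Forward pass through the trained network; class = argmax of the softmax
#' output. When `truth` is supplied, the confusion matrix (truth x predicted)
#' and overall accuracy are returned as well.
#'
#' @param object a `kdn_mlp` model.
#' @param newdata normalized genes x cells matrix (or SCE with `logcounts`)
#'   containing at least the training features, in any row order.
#' @param truth optional per-cell true labels.
#' @param ... unused.
#' @return list(class, prob, confusion, accuracy); `prob` rows sum to 1.
#' @export
predict.kdn_mlp <- function(object, newdata, truth = NULL, ...) {
  m <- .get_logcounts(newdata)
  .stopifnot_named(m, "newdata")
  missing <- setdiff(object$features, rownames(m))
  if (length(missing))
    stop("newdata lacks ", length(missing), " training feature(s): ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "")
  xs <- t(as.matrix(m[object$features, , drop = FALSE]))
  if (!is.null(object$center))
    xs <- sweep(sweep(xs, 2, object$center), 2, object$scale, `/`)
  prob <- .mlp_forward(object$weights, object$biases, xs)[[6]]
  colnames(prob) <- object$classes
  rownames(prob) <- colnames(m)
  cls <- factor(object$classes[max.col(prob, ties.method = "first")],
                levels = object$classes)
  names(cls) <- colnames(m)
  out <- list(class = cls, prob = prob, confusion = NULL, accuracy = NULL)
  if (!is.null(truth)) {
    truth <- factor(as.character(truth), levels = object$classes)
    out$confusion <- table(truth = truth, predicted = cls)
    out$accuracy <- mean(as.character(truth) == as.character(cls))
  }
  out
}

#' @export
print.kdn_mlp <- function(x, ...) {
  cat("kdn MLP:", length(x$features), "features ->",
      paste(rep(x$config$hidden_units, 4), collapse = "-"), "->",
      length(x$classes), "classes\n")
  cat(sprintf("training loss %.4f -> %.4f over %d epochs\n",
              x$initial_loss, x$final_loss, x$config$epochs))
  if (!is.null(x$validation_accuracy))
    cat(sprintf("validation accuracy %.3f (n = %d held-out cells)\n",
                x$validation_accuracy, length(x$val_idx)))
  invisible(x)
}
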