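# hexagonal grid geometry: offset rows with unit spacing, row-major neuron
# order; grid distance = Euclidean distance between hex centres
hex_coords <- function(rows, cols) {
  row <- rep(seq_len(rows) - 1L, each = cols)
  col <- rep(seq_len(cols) - 1L, times = rows)
  data.frame(col = col, row = row,
             x = col + 0.5 * (row %% 2), y = row * sqrt(3) / 2)
}

# squared hex-centre distance matrix between all neuron pairs
hex_dist2 <- function(coords) {
  dx <- outer(coords$x, coords$x, "-")
  dy <- outer(coords$y, coords$y, "-")
  dx^2 + dy^2
}

# cosine-similarity BMU over spectral weights only; ties -> lowest index
bmu_index <- function(W, wnorm, x) {
  xn <- sqrt(sum(x^2))
  if (!is.finite(xn) || xn == 0)
    stop("zero-norm or non-finite input vector", call. = FALSE)
  sims <- drop(W %*% x) / (wnorm * xn)
  sims[wnorm == 0] <- -Inf
  which.max(sims)
}

#' Fit a SKiNET supervised self-organizing map
#'
#' Trains a Kohonen self-organizing map on a hexagonal neuron grid with
#' cosine similarity as the matching metric. Class labels ride along as
#' one-hot class weight vectors updated by the same neighbourhood rule but
#' excluded from best-matching-unit (BMU) selection, so supervision never
#' influences the topology learned from the spectra. Defaults follow the
#' published configuration: 10 x 10 grid, nine epochs, initial learning
#' rate 0.3, initial neighbourhood radius two-thirds of the grid edge
#' length.
#'
#' @param x Training spectra: numeric matrix (one row per spectrum) or a
#'   `"spectral_map"` (columns become rows).
#' @param labels Class label per spectrum (factor or character).
#' @param rows,cols Grid dimensions (>= 2 each). Defaults 10 x 10.
#' @param epochs Passes over the training data. Default 9.
#' @param steps Optional total-update override; when larger than
#'   `epochs * n` samples are drawn with replacement, otherwise the shuffled
#'   epoch order is truncated. Default `epochs * n`.
#' @param alpha0 Initial learning rate in (0, 1]. Default 0.3.
#' @param radius0 Initial neighbourhood radius (grid units). Default
#'   `(2/3) * max(rows, cols)`.
#' @param seed RNG seed (weight init and sample order); NULL consumes the
#'   session RNG.
#' @return An object of class `"skinet"`: spectral `weights` (neurons x
#'   channels), nonnegative `class_weights` (neurons x classes), hexagonal
#'   `grid` coordinates, per-neuron per-class `activation_counts` from a
#'   final pass, `class_names`, `channel_axis`, and the training
#'   configuration.
#' @seealso [predict.skinet()], [somdi()], [kfold_cv()],
#'   [evaluate_repeated()]
#' @export
skinet <- function(x, labels, rows = 10, cols = 10, epochs = 9,
                   steps = NULL, alpha0 = 0.3, radius0 = NULL,
                   seed = NULL) {
  if (inherits(x, "spectral_map")) {
    axis <- x$wavenumber
    x <- t(x$intensities)
  } else {
    x <- as.matrix(x)
    axis <- as.numeric(colnames(x) %||% seq_len(ncol(x)))
  }
  labels <- as.character(labels)
  if (nrow(x) != length(labels))
    stop("one label per spectrum required", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite training data", call. = FALSE)
  if (rows < 2 || cols < 2) stop("grid must be at least 2 x 2", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (alpha0 <= 0 || alpha0 > 1) stop("alpha0 must be in (0, 1]",
                                      call. = FALSE)
  if (is.null(radius0)) radius0 <- (2 / 3) * max(rows, cols)
  if (radius0 <= 0) stop("radius0 must be > 0", call. = FALSE)
  class_names <- sort(unique(labels))
  K <- length(class_names)
  onehot <- diag(K)[match(labels, class_names), , drop = FALSE]
  n <- nrow(x); p <- ncol(x); nn <- rows * cols
  total_steps <- if (is.null(steps)) as.integer(epochs * n) else
    as.integer(steps)
  if (total_steps < 1) stop("steps must be >= 1", call. = FALSE)

  coords <- hex_coords(rows, cols)
  d2 <- hex_dist2(coords)

  with_seed(seed, {
    lo <- apply(x, 2, min); hi <- apply(x, 2, max)
    W <- matrix(runif(nn * p), nn, p)
    W <- sweep(sweep(W, 2, hi - lo, "*"), 2, lo, "+")
    C <- matrix(1 / K, nn, K)
    order_idx <- if (total_steps > epochs * n) {
      sample.int(n, total_steps, replace = TRUE)
    } else {
      unlist(lapply(seq_len(epochs), function(e) sample.int(n)))[
        seq_len(total_steps)]
    }
    denom <- max(total_steps - 1L, 1L)
    for (t in seq_len(total_steps)) {
      frac <- (t - 1) / denom
      alpha <- alpha0 * (1 - 0.99 * frac)         # linear to 0.01 * alpha0
      sigma <- radius0 + frac * (1 - radius0)      # linear to 1
      i <- order_idx[t]
      xi <- x[i, ]
      wnorm <- sqrt(rowSums(W * W))
      b <- bmu_index(W, wnorm, xi)
      ah <- alpha * exp(-d2[, b] / (2 * sigma^2))
      W <- W * (1 - ah) + tcrossprod(ah, xi)
      C <- C * (1 - ah) + tcrossprod(ah, onehot[i, ])
      if (t %% 1000L == 0L && any(!is.finite(W)))
        stop("non-finite weights at training step ", t, call. = FALSE)
    }
    if (any(!is.finite(W)))
      stop("non-finite weights after training", call. = FALSE)
    # final pass: tally which class activates each neuron
    wnorm <- sqrt(rowSums(W * W))
    xnorm <- sqrt(rowSums(x * x))
    if (any(xnorm == 0)) stop("zero-norm training spectrum", call. = FALSE)
    S <- tcrossprod(x / xnorm, W / pmax(wnorm, .Machine$double.xmin))
    bmus <- max.col(S, ties.method = "first")
    act <- matrix(0L, nn, K, dimnames = list(NULL, class_names))
    for (i in seq_len(n)) act[bmus[i], onehot[i, ] == 1] <-
        act[bmus[i], onehot[i, ] == 1] + 1L
    structure(list(weights = W, class_weights = C, grid = coords,
                   rows = rows, cols = cols, class_names = class_names,
                   activation_counts = act, channel_axis = axis,
                   dist2 = d2,
                   config = list(rows = rows, cols = cols, epochs = epochs,
                                 steps = total_steps, alpha0 = alpha0,
                                 radius0 = radius0, metric = "cosine",
                                 seed = seed),
                   train_bmus = bmus, n_train = n),
              class = "skinet")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total training steps for a SKiNET configuration
#'
#' `epochs * n` unless an explicit step override is given — e.g. nine epochs
#' over 6,400 training spectra gives 57,600 steps.
#'
#' @param epochs Training epochs.
#' @param n Number of training spectra.
#' @param steps Optional override.
#' @return Integer step count.
#' @export
som_total_steps <- function(epochs, n, steps = NULL) {
  if (is.null(steps)) as.integer(epochs * n) else as.integer(steps)
}

#' Best matching unit of a spectrum
#'
#' Argmax of cosine similarity between the input and each neuron's spectral
#' weight vector; class weights are excluded from matching and ties break to
#' the lowest neuron index. Cosine similarity makes the match invariant to
#' global intensity scaling.
#'
#' @param model A fitted `"skinet"`.
#' @param x Numeric spectrum vector (same channel count as training data).
#' @return Neuron index (row-major over the grid).
#' @export
find_bmu <- function(model, x) {
  stopifnot(inherits(model, "skinet"))
  x <- as.numeric(x)
  if (length(x) != ncol(model$weights))
    stop("input has ", length(x), " channels; model expects ",
         ncol(model$weights), call. = FALSE)
  bmu_index(model$weights, sqrt(rowSums(model$weights^2)), x)
}

#' Classify spectra with a fitted SKiNET model
#'
#' Each spectrum is assigned the class with the largest class weight at its
#' BMU (ties break to the first class in sorted order). A BMU that no
#' training spectrum ever activated carries no class evidence; such inputs
#' fall back to the nearest activated neuron by grid distance — the model's
#' analogue of the blank (white) neurons on the map display.
#'
#' @param object A fitted `"skinet"`.
#' @param newdata Matrix (one row per spectrum), `"spectral_map"`, or a
#'   single numeric vector.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.skinet <- function(object, newdata, ...) {
  if (inherits(newdata, "spectral_map")) newdata <- t(newdata$intensities)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  activated <- which(rowSums(object$activation_counts) > 0)
  if (!length(activated))
    stop("model has no activated neurons", call. = FALSE)
  wnorm <- sqrt(rowSums(object$weights^2))
  out <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    b <- bmu_index(object$weights, wnorm, newdata[i, ])
    if (sum(object$activation_counts[b, ]) == 0)
      b <- activated[which.min(object$dist2[b, activated])]
    out[i] <- object$class_names[which.max(object$class_weights[b, ])]
  }
  out
}

#' SOMDI discriminant feature extraction
#'
#' The self-optimizing-map discriminant index summarizes which wavenumbers
#' drive the clustering: for each class, the neurons whose class weight
#' argmax is that class (and that were activated in training) contribute
#' their class-weight-scaled spectral weight vectors; the mean of those,
#' minus the mean spectral weight over all activated neurons (a contrast
#' term making "prominent" operational), is the class's SOMDI profile.
#' Higher SOMDI intensity marks a wavenumber as more important to the class.
#'
#' @param model A fitted `"skinet"`.
#' @param contrast Subtract the activated-neuron mean weight (default TRUE).
#' @return A `"somdi_result"`: `wavenumber`, `profiles` (channels x
#'   classes), and per-class `peaks` (local maxima ranked by intensity).
#' @export
somdi <- function(model, contrast = TRUE) {
  stopifnot(inherits(model, "skinet"))
  act <- rowSums(model$activation_counts) > 0
  if (!any(act)) stop("model has no activated neurons", call. = FALSE)
  grand <- colMeans(model$weights[act, , drop = FALSE])
  K <- length(model$class_names)
  modal <- apply(model$class_weights, 1, which.max)
  profiles <- matrix(0, ncol(model$weights), K,
                     dimnames = list(NULL, model$class_names))
  for (k in seq_len(K)) {
    nk <- which(act & modal == k)
    if (!length(nk)) {
      warning("no activated neurons for class ", model$class_names[k],
              "; returning zero profile", call. = FALSE)
      next
    }
    contrib <- model$class_weights[nk, k] * model$weights[nk, , drop = FALSE]
    profiles[, k] <- colMeans(contrib) - if (contrast) grand else 0
  }
  peaks <- lapply(seq_len(K), function(k) {
    y <- profiles[, k]
    n <- length(y)
    is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                         y[2:(n - 1)] >= y[3:n], FALSE)
    idx <- which(is_max)
    idx <- idx[order(y[idx], decreasing = TRUE)]
    data.frame(wavenumber = model$channel_axis[idx], intensity = y[idx])
  })
  names(peaks) <- model$class_names
  structure(list(wavenumber = model$channel_axis, profiles = profiles,
                 peaks = peaks), class = "somdi_result")
}

#' Stratified train/test split
#'
#' Per class, `round(test_fraction * n)` items are drawn uniformly at random
#' into the test partition; train and test are disjoint and cover the data.
#'
#' @param labels Class label per item.
#' @param test_fraction Fraction reserved for testing, in (0, 1).
#'   Default 0.2.
#' @param seed RNG seed; NULL consumes the session RNG.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = NULL) {
  labels <- as.character(labels)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2))
    stop("every class needs >= 2 items to split", call. = FALSE)
  with_seed(seed, {
    test <- integer(0)
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      n_test <- round(test_fraction * length(idx))
      test <- c(test, sample(idx, n_test))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

#' Stratified k-fold cross-validation of SKiNET
#'
#' @param x Spectra matrix (rows) or `"spectral_map"`.
#' @param labels Class labels.
#' @param k Number of folds. Default 10. Every class must have >= k items.
#' @param seed RNG seed for fold assignment and per-fold training.
#' @param ... Passed to [skinet()] (grid size, epochs, ...).
#' @return A `"skinet_cv"` list: per-fold accuracies, their `mean` and `sd`.
#' @export
kfold_cv <- function(x, labels, k = 10, seed = NULL, ...) {
  if (inherits(x, "spectral_map")) x <- t(x$intensities)
  x <- as.matrix(x)
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("every class needs >= k items for ", k, "-fold CV", call. = FALSE)
  folds <- with_seed(seed, {
    f <- integer(length(labels))
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  acc <- numeric(k)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    fit <- skinet(x[tr, , drop = FALSE], labels[tr],
                  seed = if (is.null(seed)) NULL else
                    stage_seed(seed, paste0("fold", fold)), ...)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    acc[fold] <- mean(pred == labels[!tr])
  }
  structure(list(fold_accuracy = acc, mean = mean(acc), sd = sd(acc),
                 k = k), class = "skinet_cv")
}

#' Build a confusion matrix
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels.
#' @param classes Optional fixed class order (default: sorted union).
#' @return A square counts matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, classes), factor(predicted, classes))
  m <- matrix(as.numeric(cm), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Repeated-initialization test-set evaluation
#'
#' Trains `n_repeats` SKiNET models from distinct random initializations,
#' classifies the held-out test set with each, and averages the resulting
#' confusion matrices elementwise — the repeat verifies the stability of
#' the model rather than a single lucky initialization.
#'
#' @param x_train,labels_train Training spectra and labels.
#' @param x_test,labels_test Held-out test spectra and labels.
#' @param n_repeats Number of independent initializations. Default 10.
#' @param seed Base seed; per-repeat seeds are derived from it.
#' @param ... Passed to [skinet()].
#' @return A `"skinet_eval"` list: `mean_confusion` (elementwise mean),
#'   `confusions` per repeat, and per-repeat `accuracy`.
#' @export
evaluate_repeated <- function(x_train, labels_train, x_test, labels_test,
                              n_repeats = 10, seed = NULL, ...) {
  if (inherits(x_train, "spectral_map")) x_train <- t(x_train$intensities)
  if (inherits(x_test, "spectral_map")) x_test <- t(x_test$intensities)
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  if (nrow(x_test) == 0) stop("empty test set", call. = FALSE)
  classes <- sort(unique(c(as.character(labels_train),
                           as.character(labels_test))))
  cms <- vector("list", n_repeats)
  acc <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    fit <- skinet(x_train, labels_train,
                  seed = if (is.null(seed)) NULL else
                    stage_seed(seed, paste0("repeat", r)), ...)
    pred <- predict(fit, x_test)
    cms[[r]] <- confusion_matrix(labels_test, pred, classes)
    acc[r] <- mean(pred == as.character(labels_test))
  }
  structure(list(mean_confusion = Reduce(`+`, cms) / n_repeats,
                 confusions = cms, accuracy = acc,
                 n_repeats = n_repeats), class = "skinet_eval")
}

#' @export
print.skinet <- function(x, ...) {
  cat("SKiNET supervised SOM\n")
  cat("  grid: ", x$rows, " x ", x$cols, " hexagonal neurons\n", sep = "")
  cat("  channels: ", ncol(x$weights), "; classes: ",
      paste(x$class_names, collapse = ", "), "\n", sep = "")
  cat("  training: ", x$config$steps, " steps (", x$config$epochs,
      " epochs over ", x$n_train, " spectra), alpha0 = ",
      x$config$alpha0, ", radius0 = ", format(x$config$radius0, digits = 4),
      ", cosine metric\n", sep = "")
  invisible(x)
}

#' @export
summary.skinet <- function(object, ...) {
  act <- rowSums(object$activation_counts)
  modal <- apply(object$class_weights, 1, which.max)
  modal_tab <- table(factor(object$class_names[modal[act > 0]],
                            object$class_names))
  purity <- vapply(which(act > 0), function(n)
    max(object$activation_counts[n, ]) / act[n], numeric(1))
  out <- list(n_neurons = nrow(object$weights),
              n_activated = sum(act > 0),
              modal_class_counts = modal_tab,
              mean_neuron_purity = mean(purity),
              config = object$config)
  class(out) <- "summary.skinet"
  out
}

#' @export
print.summary.skinet <- function(x, ...) {
  cat("SKiNET model summary\n")
  cat("  activated neurons: ", x$n_activated, " / ", x$n_neurons, "\n",
      sep = "")
  cat("  modal class counts:\n")
  print(x$modal_class_counts)
  cat("  mean neuron purity: ", format(x$mean_neuron_purity, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Plot the neuron grid colored by modal class
#'
#' Hexagons are colored by the modal class of the spectra that activate
#' each neuron; neurons activating no data are white.
#'
#' @param x A fitted `"skinet"`.
#' @param palette Colors, one per class.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.skinet <- function(x, palette = NULL, ...) {
  if (is.null(palette))
    palette <- grDevices::hcl.colors(length(x$class_names), "Dark 3")
  act <- rowSums(x$activation_counts)
  modal <- apply(x$activation_counts, 1, which.max)
  fill <- ifelse(act > 0, palette[modal], "white")
  r <- 0.5
  graphics::plot(NA, xlim = range(x$grid$x) + c(-1, 1),
                 ylim = range(x$grid$y) + c(-1, 1), asp = 1,
                 xlab = "", ylab = "", axes = FALSE, ...)
  ang <- seq(pi / 6, 2 * pi, by = pi / 3)
  for (i in seq_len(nrow(x$grid)))
    graphics::polygon(x$grid$x[i] + r * cos(ang) / cos(pi / 6),
                      x$grid$y[i] + r * sin(ang) / cos(pi / 6),
                      col = fill[i], border = "grey40")
  graphics::legend("topright", legend = x$class_names, fill = palette,
                   bty = "n")
  invisible(x)
}

#' @export
print.somdi_result <- function(x, ...) {
  cat("SOMDI profiles for ", ncol(x$profiles), " classes over ",
      length(x$wavenumber), " channels\n", sep = "")
  for (cl in colnames(x$profiles)) {
    pk <- x$peaks[[cl]]
    if (nrow(pk))
      cat("  ", cl, ": top peaks at ",
          paste(format(utils::head(pk$wavenumber, 3)), collapse = ", "),
          " cm^-1\n", sep = "")
  }
  invisible(x)
}

#' @export
print.skinet_cv <- function(x, ...) {
  cat(x$k, "-fold CV accuracy: ", format(x$mean, digits = 4), " +/- ",
      format(x$sd, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
print.skinet_eval <- function(x, ...) {
  cat("Averaged confusion matrix over ", x$n_repeats,
      " initializations (mean accuracy ",
      format(mean(x$accuracy), digits = 4), "):\n", sep = "")
  print(x$mean_confusion)
  invisible(x)
}
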