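test_that("BMU search matches a brute-force oracle and is scale-invariant", {
  set.seed(12)
  for (trial in 1:100) {
    W <- matrix(rnorm(25 * 8), 25, 8)
    model <- fake_skinet(W)
    x <- rnorm(8)
    b <- find_bmu(model, x)
    expect_identical(b, brute_force_bmu(W, x))
    expect_identical(find_bmu(model, 10 * x), b)
  }
  model <- fake_skinet(matrix(rnorm(16), 4, 4))
  expect_error(find_bmu(model, rep(0, 4)), "zero-norm")
  expect_error(find_bmu(model, rep(1, 7)), "channels")
})

test_that("an exactly matching weight vector wins the BMU search", {
  W <- diag(5)  # orthogonal neurons
  model <- fake_skinet(W)
  for (i in 1:5) expect_identical(find_bmu(model, W[i, ]), i)
})

test_that("class weights never influence BMU selection", {
  cl <- separable_clusters(n_per_class = 20, p = 10)
  model <- skinet(cl$x, cl$labels, rows = 4, cols = 4, seed = 5)
  perturbed <- model
  set.seed(1)
  perturbed$class_weights <- matrix(runif(length(model$class_weights)),
                                    nrow(model$class_weights))
  for (i in seq_len(nrow(cl$x)))
    expect_identical(find_bmu(model, cl$x[i, ]),
                     find_bmu(perturbed, cl$x[i, ]))
})

test_that("training is deterministic, supervised correctly, and separable", {
  cl <- separable_clusters(n_per_class = 100, p = 20)
  m1 <- skinet(cl$x, cl$labels, rows = 5, cols = 5, seed = 42)
  m2 <- skinet(cl$x, cl$labels, rows = 5, cols = 5, seed = 42)
  expect_identical(m1, m2)
  expect_true(all(m1$class_weights >= 0))
  expect_equal(dim(m1$weights), c(25, 20))
  expect_true(all(is.finite(m1$weights)))
  # >= 95% of activated neurons carry a single modal class
  act <- rowSums(m1$activation_counts)
  purity <- apply(m1$activation_counts[act > 0, ], 1, max) / act[act > 0]
  expect_gte(mean(purity == 1), 0.95)
  expect_gte(mean(predict(m1, cl$x) == cl$labels), 0.95)
})

test_that("step budget follows epochs x n with an explicit override", {
  expect_identical(som_total_steps(9, 6400), 57600L)
  cl <- separable_clusters(n_per_class = 10, p = 5)
  m <- skinet(cl$x, cl$labels, rows = 3, cols = 3, epochs = 9, seed = 1)
  expect_identical(m$config$steps, 9L * 20L)
  m2 <- skinet(cl$x, cl$labels, rows = 3, cols = 3, epochs = 2,
               steps = 100, seed = 1)
  expect_identical(m2$config$steps, 100L)
})

test_that("default neighbourhood radius is two-thirds the grid edge", {
  cl <- separable_clusters(n_per_class = 10, p = 5)
  m <- skinet(cl$x, cl$labels, rows = 4, cols = 6, epochs = 1, seed = 1)
  expect_equal(m$config$radius0, (2 / 3) * 6)
})

test_that("trained maps are topographically ordered", {
  cl <- separable_clusters(n_per_class = 60, p = 15)
  m <- skinet(cl$x, cl$labels, rows = 5, cols = 5, seed = 8)
  W <- m$weights
  wn <- sqrt(rowSums(W^2))
  cosd <- 1 - tcrossprod(W / wn)
  adjacent <- m$dist2 > 0 & m$dist2 <= 1.01
  nonadj <- m$dist2 > 1.01
  expect_lt(mean(cosd[adjacent]), mean(cosd[nonadj]))
})

test_that("SOMDI recovers the discriminating band and handles edge cases", {
  # two classes differing only in the 2930-band amplitude
  axis <- seq(2800, 3200, by = 2)
  set.seed(21)
  base <- eval_bands(axis, list(band_spec(2850, 45, 1),
                                band_spec(2880, 45, 0.4)))
  hi <- eval_bands(axis, list(band_spec(2930, 45, 1.5)))
  n <- 60
  X <- rbind(
    t(replicate(n, base + hi * runif(1, 0.8, 1.2) + rnorm(length(axis),
                                                          0, 0.02))),
    t(replicate(n, base + hi * 0.1 * runif(1, 0.8, 1.2) +
                  rnorm(length(axis), 0, 0.02))))
  colnames(X) <- axis
  labels <- rep(c("TBI", "control"), each = n)
  m <- skinet(X, labels, rows = 5, cols = 5, seed = 3)
  s <- somdi(m)
  expect_equal(colnames(s$profiles), c("TBI", "control"))
  expect_true(all(is.finite(s$profiles)))
  expect_equal(nrow(s$profiles), length(axis))
  top_tbi <- s$peaks[["TBI"]]$wavenumber[1]
  expect_lt(abs(top_tbi - 2930), 45 / 2)
  # single-class training: no contrast -> near-zero profile
  m1 <- skinet(X[1:n, ], labels[1:n], rows = 4, cols = 4, seed = 3)
  s1 <- somdi(m1)
  expect_lt(max(abs(s1$profiles)), 0.05 * max(abs(X)))
})

test_that("prediction falls back to the nearest activated neuron", {
  cl <- separable_clusters(n_per_class = 15, p = 8)
  m <- skinet(cl$x, cl$labels, rows = 4, cols = 4, seed = 13)
  # force a neuron to be unactivated but perfectly matching a probe
  probe <- rnorm(8)
  m$weights[7, ] <- probe * 5
  m$activation_counts[7, ] <- 0L
  m$class_weights[7, ] <- c(0.5, 0.5)
  expect_identical(find_bmu(m, probe), 7L)
  expect_true(predict(m, probe) %in% m$class_names)
})

test_that("stratified split reserves the configured fraction per class", {
  labels <- rep(c("TBI", "control"), c(100, 60))
  sp <- stratified_split(labels, 0.2, seed = 9)
  expect_equal(length(sp$test), 0.2 * 100 + 0.2 * 60)
  expect_equal(sum(labels[sp$test] == "TBI"), 20)
  expect_equal(sum(labels[sp$test] == "control"), 12)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, stratified_split(labels, 0.2, seed = 9))
  expect_error(stratified_split(labels, 0), "test_fraction")
  expect_error(stratified_split(labels, 1), "test_fraction")
  expect_error(stratified_split(c("a", "b", "b"), 0.5), ">= 2")
})

test_that("k-fold CV is perfect on separable data and rejects small classes", {
  cl <- separable_clusters(n_per_class = 30, p = 10)
  cv <- kfold_cv(cl$x, cl$labels, k = 5, seed = 2, rows = 4, cols = 4,
                 epochs = 5)
  expect_equal(cv$mean, 1.0)
  expect_length(cv$fold_accuracy, 5)
  expect_error(kfold_cv(cl$x, cl$labels, k = 31), ">= k")
})

test_that("label-permuted CV accuracy is at chance", {
  set.seed(77)
  x <- matrix(rnorm(120 * 10), 120, 10) + 5
  labels <- sample(rep(c("A", "B"), each = 60))
  cv <- kfold_cv(x, labels, k = 10, seed = 4, rows = 4, cols = 4,
                 epochs = 5)
  se <- sqrt(0.25 / 120)
  expect_lt(abs(cv$mean - 0.5), 3 * 3 * se)  # generous null band
})

test_that("repeated evaluation averages confusion matrices conservatively", {
  cl <- separable_clusters(n_per_class = 40, p = 10)
  sp <- stratified_split(cl$labels, 0.2, seed = 1)
  ev <- evaluate_repeated(cl$x[sp$train, ], cl$labels[sp$train],
                         cl$x[sp$test, ], cl$labels[sp$test],
                         n_repeats = 3, seed = 6, rows = 4, cols = 4,
                         epochs = 5)
  cm <- ev$mean_confusion
  # row sums equal test-set class counts
  expect_equal(unname(rowSums(cm)),
               unname(as.numeric(table(cl$labels[sp$test]))))
  # separable: off-diagonal means <= 5% of row totals
  off <- cm; diag(off) <- 0
  expect_true(all(rowSums(off) <= 0.05 * rowSums(cm)))
  ev1 <- evaluate_repeated(cl$x[sp$train, ], cl$labels[sp$train],
                          cl$x[sp$test, ], cl$labels[sp$test],
                          n_repeats = 1, seed = 6, rows = 4, cols = 4,
                          epochs = 5)
  expect_identical(ev1$mean_confusion, ev1$confusions[[1]])
  expect_error(evaluate_repeated(cl$x, cl$labels,
                                 cl$x[0, , drop = FALSE], character(0)),
               "empty test set")
})
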