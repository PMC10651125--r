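# shared fixtures: all synthetic, generated at test time

# reduced cohort configuration used where full study scale is unnecessary
tiny_cohort_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_tbi_samples = 3, n_control_samples = 3, spectra_per_sample = 8,
         axis_step = 4, seed = seed),
    list(...))
  do.call(cohort_config, args)
}

# two well-separated spherical clusters, angularly separated (centres on
# orthogonal axes, ~10 noise-sd from the origin) so the cosine metric
# separates them cleanly
separable_clusters <- function(n_per_class = 50, p = 20, sep = 10,
                               seed = 99) {
  set.seed(seed)
  half <- p %/% 2
  mu_a <- c(rep(sep, half), rep(0, p - half))
  mu_b <- c(rep(0, half), rep(sep, p - half))
  x <- rbind(
    matrix(rnorm(n_per_class * p), n_per_class, p) +
      matrix(mu_a, n_per_class, p, byrow = TRUE),
    matrix(rnorm(n_per_class * p), n_per_class, p) +
      matrix(mu_b, n_per_class, p, byrow = TRUE))
  list(x = x, labels = rep(c("A", "B"), each = n_per_class))
}

# minimal model container for BMU oracle checks on hand-set weights
fake_skinet <- function(W) {
  structure(list(weights = W,
                 class_weights = matrix(0.5, nrow(W), 2),
                 activation_counts = matrix(1L, nrow(W), 2),
                 dist2 = matrix(0, nrow(W), nrow(W)),
                 class_names = c("A", "B"),
                 channel_axis = seq_len(ncol(W))),
            class = "skinet")
}

# brute-force cosine BMU: independent of the package's vectorized search
brute_force_bmu <- function(W, x) {
  best <- -Inf; best_i <- NA_integer_
  for (i in seq_len(nrow(W))) {
    s <- sum(W[i, ] * x) / (sqrt(sum(W[i, ]^2)) * sqrt(sum(x^2)))
    if (s > best) { best <- s; best_i <- i }
  }
  best_i
}

# brute-force AUC by exhaustive pair counting with the 1/2 tie rule
brute_force_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}
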