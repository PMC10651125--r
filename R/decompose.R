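#' Average spectrum of a sample map
#'
#' Channel-wise arithmetic mean over all spectra of a map, yielding the one
#' spectrum per sample that the decomposition stage fits.
#'
#' @param map A `"spectral_map"`.
#' @return A `"raman_spectrum"`.
#' @export
average_spectrum <- function(map) {
  stopifnot(inherits(map, "spectral_map"))
  if (n_spectra(map) < 1) stop("empty map", call. = FALSE)
  meta <- list()
  if ("sample_id" %in% names(map$meta))
    meta$sample_id <- map$meta$sample_id[1]
  if ("class" %in% names(map$meta)) meta$class <- map$meta$class[1]
  raman_spectrum(map$wavenumber, rowMeans(map$intensities), meta)
}

#' Non-negative least-squares fit of a component library
#'
#' Finds nonnegative coefficients minimizing
#' `|| y - sum_i c_i * component_i ||_2` over the fitting window (default
#' 1200-3000 cm^-1), using the Lawson-Hanson active-set solver. The spectrum
#' is aligned to the library grid by unit-grid resampling when the grids
#' differ. Karush-Kuhn-Tucker optimality is verified on every returned fit:
#' the gradient of the residual is ~0 on positive coefficients and >= 0 on
#' zero ones.
#'
#' @param y A `"raman_spectrum"` (typically a per-sample average).
#' @param lib A `"component_library"`.
#' @param range_lo,range_hi Fitting window (cm^-1). Defaults 1200 and 3000.
#' @param normalize Normalize `y` and each component to unit area over the
#'   window before fitting, making coefficients comparable across samples.
#'   Default FALSE (raw fit, exact-recovery semantics).
#' @return An `"nnls_fit"`: named `coefficients` (>= 0), `residual_norm`
#'   (2-norm of the misfit), `fitted` reconstruction, the window `grid`,
#'   and `kkt` diagnostics.
#' @export
nnls_fit <- function(y, lib, range_lo = 1200, range_hi = 3000,
                     normalize = FALSE) {
  stopifnot(inherits(y, "raman_spectrum"), inherits(lib, "component_library"))
  keep <- lib$grid >= range_lo & lib$grid <= range_hi
  if (sum(keep) < ncol(lib$matrix))
    stop("fitting window leaves fewer points than components", call. = FALSE)
  grid <- lib$grid[keep]
  A <- lib$matrix[keep, , drop = FALSE]
  if (!isTRUE(all.equal(y$wavenumber, lib$grid)) &&
      !all(grid %in% y$wavenumber)) {
    y <- resample_unit_grid(y)
  }
  idx <- match(grid, y$wavenumber)
  if (any(is.na(idx)))
    stop("spectrum does not cover the library grid in [", range_lo, ", ",
         range_hi, "] after alignment", call. = FALSE)
  b <- y$intensity[idx]
  if (normalize) {
    b <- b / trapz_integral(grid, b)
    A <- apply(A, 2, function(col) col / trapz_integral(grid, col))
  }
  if (qr(A)$rank < ncol(A))
    warning("rank-deficient component library; NNLS solution returned",
            call. = FALSE)
  sol <- pracma::lsqnonneg(A, b)
  coef <- sol$x
  names(coef) <- lib$names
  fitted <- drop(A %*% coef)
  resid <- b - fitted
  grad <- drop(crossprod(A, -resid))  # gradient of 0.5*||Ax - b||^2
  scale <- max(abs(grad), sqrt(sum(b^2)), 1)
  tol <- 1e-8 * scale
  kkt <- list(grad = grad,
              stationarity = all(abs(grad[coef > 0]) <= tol),
              dual_feasibility = all(grad[coef == 0] >= -tol))
  if (!kkt$stationarity || !kkt$dual_feasibility)
    warning("NNLS fit violates KKT optimality at tolerance 1e-8",
            call. = FALSE)
  structure(list(coefficients = coef,
                 residual_norm = sqrt(sum(resid^2)),
                 fitted = fitted, grid = grid, observed = b, kkt = kkt),
            class = "nnls_fit")
}

#' @export
print.nnls_fit <- function(x, ...) {
  cat("NNLS fit over ", length(x$grid), " channels (",
      format(min(x$grid)), "-", format(max(x$grid)), " cm^-1)\n", sep = "")
  print(round(x$coefficients, 6))
  cat("residual 2-norm: ", format(x$residual_norm, digits = 6), "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.nnls_fit <- function(object, ...) object$coefficients

#' Group-wise comparison of NNLS coefficients
#'
#' Per component: group means, a two-sided t statistic, a normal-based 95%
#' confidence interval of the mean difference, the p-value, and a
#' significance flag at alpha = 0.05.
#'
#' @param coefs Numeric matrix of fitted coefficients, one row per sample,
#'   one column per component (e.g. rbind of `coef(nnls_fit(...))`).
#' @param labels Group label per sample (exactly two groups, >= 2 samples
#'   each).
#' @param conf_level Confidence level. Default 0.95.
#' @return Data frame: component, means, difference, CI bounds, t, p,
#'   significant.
#' @export
compare_groups <- function(coefs, labels, conf_level = 0.95) {
  coefs <- as.matrix(coefs)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2)
    stop("exactly two groups required", call. = FALSE)
  if (any(table(labels) < 2))
    stop("each group needs >= 2 samples", call. = FALSE)
  g1 <- labels == groups[1]
  z <- qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(seq_len(ncol(coefs)), function(j) {
    a <- coefs[g1, j]; b <- coefs[!g1, j]
    tt <- t.test(a, b)
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    diff <- mean(a) - mean(b)
    data.frame(component = colnames(coefs)[j] %||% paste0("component_", j),
               mean_1 = mean(a), mean_2 = mean(b), difference = diff,
               ci_lo = diff - z * se, ci_hi = diff + z * se,
               t = unname(tt$statistic), p = tt$p.value,
               significant = tt$p.value < 1 - conf_level)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("mean_", groups)
  out
}
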