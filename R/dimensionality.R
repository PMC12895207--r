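#' Plots x metrics matrix for one land-use category
#'
#' Extracts the three diversity metrics (D, raoD, raoQ), in that fixed
#' column order, for the plots of one category.
#'
#' @param profile data frame from \code{\link{diversity_profile}} (needs
#'   columns plot, category, D, raoD, raoQ).
#' @param category land-use category to extract.
#' @param metrics metric columns to use.
#' @return numeric matrix, plots in rows.
#' @export
metric_matrix <- function(profile, category, metrics = c("D", "raoD", "raoQ")) {
  rows <- profile$category == category
  if (!any(rows)) stop("no plots in category: ", category)
  M <- as.matrix(profile[rows, metrics, drop = FALSE])
  rownames(M) <- profile$plot[rows]
  if (nrow(M) < 4) stop("need at least 4 plots per category, got ", nrow(M))
  v <- apply(M, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance metric(s): ", paste(metrics[v == 0], collapse = ", "))
  M
}

#' PCA on the correlation matrix of diversity metrics
#'
#' Eigendecomposition of the Pearson correlation matrix of the metric
#' columns. Loadings are scaled to metric-component correlations
#' r_mk = e_mk * sqrt(lambda_k), so that sum_m r_mk^2 = lambda_k and
#' sum_k r_mk^2 = 1 for every metric. Eigenvector signs are fixed by
#' making each component's largest-magnitude loading positive.
#'
#' @param M plots x metrics matrix.
#' @return list: \code{eigenvalues} (descending, summing to the number of
#'   metrics), \code{proportions}, \code{correlations} (metrics x
#'   components matrix r_mk).
#' @export
pca_correlation <- function(M) {
  if (any(!is.finite(M))) stop("non-finite entries in metric matrix")
  R <- stats::cor(M)
  eig <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  V <- eig$vectors
  for (k in seq_len(ncol(V))) {
    imax <- which.max(abs(V[, k]))
    if (V[imax, k] < 0) V[, k] <- -V[, k]
  }
  r <- V %*% diag(sqrt(lambda), nrow = length(lambda))
  dimnames(r) <- list(colnames(M), paste0("PC", seq_along(lambda)))
  list(eigenvalues = lambda, proportions = lambda / sum(lambda),
       correlations = r)
}

#' Camargo evenness
#'
#' For proportions q_i = v_i / sum(v):
#' E = 1 - sum_{i<j} |q_i - q_j| / S, with S the number of values.
#' E = 1 for perfectly even values and 1/S when a single value carries
#' everything.
#'
#' @param values non-negative values with positive sum.
#' @return evenness in (0, 1].
#' @export
camargo_evenness <- function(values) {
  if (any(values < 0)) stop("negative values")
  s <- sum(values)
  if (s <= 0) stop("values sum to zero")
  q <- values / s
  S <- length(q)
  pairs <- utils::combn(S, 2)
  1 - sum(abs(q[pairs[1, ]] - q[pairs[2, ]])) / S
}

#' Evenness of eigenvalues (EE)
#'
#' Camargo evenness of the correlation-PCA eigenvalues. EE near 1 means
#' the diversity metrics are complementary (several independent dimensions
#' are needed to describe community variation); EE near 1/S means they are
#' redundant (one dimension suffices).
#'
#' @param eigenvalues from \code{\link{pca_correlation}}.
#' @return EE in [1/S, 1].
#' @export
evenness_of_eigenvalues <- function(eigenvalues) {
  camargo_evenness(eigenvalues)
}

#' Importance value (IV) of each diversity metric
#'
#' Share of total biodiversity-space variation attributable to each metric:
#' raw_m = sum_k p_k r_mk^2 with p_k the eigenvalue proportions, normalized
#' so the IVs sum to 1. With squared correlations raw_m is the metric's
#' communality weighted by component variance. \code{variant = "abs_r"}
#' uses |r_mk| instead of r_mk^2.
#'
#' @param eigenvalues,correlations from \code{\link{pca_correlation}}.
#' @param variant \code{"r2"} (default) or \code{"abs_r"}.
#' @return named IV vector summing to 1.
#' @export
importance_values <- function(eigenvalues, correlations,
                              variant = c("r2", "abs_r")) {
  variant <- match.arg(variant)
  p <- eigenvalues / sum(eigenvalues)
  w <- if (variant == "r2") correlations^2 else abs(correlations)
  raw <- drop(w %*% p)
  if (sum(raw) <= 0) stop("degenerate loadings; importance values undefined")
  raw / sum(raw)
}

#' Evenness of importance values
#'
#' Camargo evenness of the IVs. High values mean several metrics
#' contribute comparably to the biodiversity space (redundancy of
#' metrics); low values mean one metric dominates.
#'
#' @param iv importance values (summing to 1).
#' @return evenness in [1/S, 1].
#' @export
iv_evenness <- function(iv) {
  camargo_evenness(iv)
}

# full chain for one plots x metrics matrix
dimensionality_chain <- function(M, iv_variant = "r2") {
  pca <- pca_correlation(M)
  iv <- importance_values(pca$eigenvalues, pca$correlations, iv_variant)
  list(pca = pca,
       EE = evenness_of_eigenvalues(pca$eigenvalues),
       IV = iv,
       iv_evenness = iv_evenness(iv))
}

#' Bootstrap confidence interval for IV evenness
#'
#' Resamples plots with replacement within the category, recomputes the
#' full chain (correlation PCA, IVs, Camargo evenness of IVs) per
#' resample, and returns the percentile 95% interval. Degenerate
#' resamples (a zero-variance metric column) are redrawn and counted.
#'
#' @param M plots x metrics matrix (one category).
#' @param n_boot number of bootstrap resamples; 0 returns the point
#'   estimate only.
#' @param seed integer seed.
#' @param iv_variant see \code{\link{importance_values}}.
#' @param level confidence level.
#' @return list: \code{point}, \code{ci_low}, \code{ci_high},
#'   \code{n_boot}, \code{n_redrawn}.
#' @export
bootstrap_iv_evenness <- function(M, n_boot = 999, seed = 1,
                                  iv_variant = "r2", level = 0.95) {
  point <- dimensionality_chain(M, iv_variant)$iv_evenness
  if (n_boot == 0)
    return(list(point = point, ci_low = NA_real_, ci_high = NA_real_,
                n_boot = 0L, n_redrawn = 0L))
  set.seed(seed)
  vals <- numeric(n_boot)
  n <- nrow(M)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      Mb <- M[sample.int(n, n, replace = TRUE), , drop = FALSE]
      if (all(apply(Mb, 2, stats::var) > 0)) break
      redrawn <- redrawn + 1L
      if (redrawn > 100 * n_boot) stop("too many degenerate bootstrap resamples")
    }
    vals[b] <- dimensionality_chain(Mb, iv_variant)$iv_evenness
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(point = point, ci_low = ci[1], ci_high = ci[2],
       n_boot = as.integer(n_boot), n_redrawn = redrawn)
}

#' Biodiversity dimensionality per land-use category
#'
#' For each category: correlation PCA of (D, raoD, raoQ), evenness of
#' eigenvalues (EE), importance value per metric, IV evenness and its
#' bootstrap CI.
#'
#' @param profile data frame from \code{\link{diversity_profile}}.
#' @param n_boot bootstrap resamples for the IV-evenness CI.
#' @param seed global seed (per-category seeds derived).
#' @param iv_variant see \code{\link{importance_values}}.
#' @param metrics metric columns.
#' @return data frame: category, EE, IV_<metric>..., iv_evenness, ci_low,
#'   ci_high, n_plots.
#' @export
dimensionality_by_category <- function(profile, n_boot = 999, seed = 1,
                                       iv_variant = "r2",
                                       metrics = c("D", "raoD", "raoQ")) {
  cats <- unique(profile$category)
  seeds <- derive_seed(seed, paste0("boot_", cats))
  rows <- lapply(seq_along(cats), function(i) {
    M <- metric_matrix(profile, cats[i], metrics)
    ch <- dimensionality_chain(M, iv_variant)
    bt <- bootstrap_iv_evenness(M, n_boot, seeds[i], iv_variant)
    ivs <- as.data.frame(as.list(ch$IV))
    names(ivs) <- paste0("IV_", metrics)
    cbind(data.frame(category = cats[i], EE = ch$EE), ivs,
          data.frame(iv_evenness = ch$iv_evenness,
                     ci_low = bt$ci_low, ci_high = bt$ci_high,
                     n_plots = nrow(M)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
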