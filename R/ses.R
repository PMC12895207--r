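# Null-model machinery. A tip shuffle (or a joint permutation of trait
# rows) acts on the precomputed distance matrix as a simultaneous row and
# column permutation, so nulls are generated by relabeling the matrix
# rather than recomputing distances; the two routes are identical and the
# equivalence is asserted in the test suite.

# plots x pool matrix of relative abundances, pool = species with positive
# total abundance
pool_weights <- function(comm) {
  pool <- colnames(comm)[colSums(comm) > 0]
  P <- unclass(comm)[, pool, drop = FALSE]
  sweep(P, 1, rowSums(P), "/")
}

# Rao Q of every plot given weights P (plots x pool) and distances d (pool x pool)
rao_all_plots <- function(P, d) {
  rowSums((P %*% d) * P)
}

# core SES loop for a distance-based metric under pool-label permutation
ses_from_distance <- function(P, d, n_rand, seed) {
  obs <- rao_all_plots(P, d)
  npool <- ncol(P)
  set.seed(seed)
  nulls <- matrix(NA_real_, n_rand, length(obs))
  for (r in seq_len(n_rand)) {
    perm <- sample.int(npool)
    nulls[r, ] <- rao_all_plots(P, d[perm, perm])
  }
  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2, stats::sd)
  list(observed = obs, null_mean = null_mean, null_sd = null_sd,
       ses = standardize_effect(obs, null_mean, null_sd))
}

# (obs - mean)/sd with a relative floor on sd: a null whose spread is pure
# floating-point noise is degenerate, giving SES 0 when the observed value
# sits on the null mean and NA otherwise
standardize_effect <- function(obs, null_mean, null_sd) {
  scale <- pmax(abs(obs), abs(null_mean), 1e-12)
  degenerate <- null_sd <= 1e-9 * scale
  ifelse(!degenerate, (obs - null_mean) / null_sd,
         ifelse(abs(obs - null_mean) <= 1e-9 * scale, 0, NA_real_))
}

ses_result_frame <- function(plots, metric, res, n_rand, seed, richness) {
  reason <- rep(NA_character_, length(plots))
  reason[richness < 2] <- "fewer than 2 species"
  degenerate <- res$null_sd <=
    1e-9 * pmax(abs(res$observed), abs(res$null_mean), 1e-12)
  reason[degenerate & richness >= 2] <- "degenerate null (SD = 0)"
  ses <- res$ses
  ses[richness < 2] <- NA_real_
  data.frame(plot = plots, metric = metric,
             observed = res$observed, null_mean = res$null_mean,
             null_sd = res$null_sd, ses = ses,
             n_randomizations = n_rand, seed = seed, reason = reason,
             row.names = NULL)
}

#' Standardized effect size of phylogenetic diversity (raoD)
#'
#' Per plot, SES = (observed raoD - mean null raoD) / SD(null raoD), the
#' null obtained by shuffling species labels across the tips of the
#' phylogeny (restricted to the study species pool), 999 times by default.
#' Negative SES indicates lineage clustering (convergence), positive SES
#' overdispersion. With a set of grafted topologies the SES is computed per
#' topology and averaged; the across-topology SD is reported as
#' \code{ses_sd}.
#'
#' @param comm community matrix.
#' @param grafted \code{grafted_trees}, list of phylo, or single phylo.
#' @param n_rand number of randomizations.
#' @param seed integer seed.
#' @param convention divergence convention, see \code{\link{divergence_matrix}}.
#' @return data frame: plot, metric ("raoD"), observed, null_mean, null_sd,
#'   ses, ses_sd (across topologies), n_randomizations, seed, reason.
#' @export
ses_phylogenetic <- function(comm, grafted, n_rand = 999, seed = 1,
                             convention = "half_patristic") {
  if (inherits(grafted, "phylo")) grafted <- list(grafted)
  trees <- if (inherits(grafted, "grafted_trees")) grafted$trees else grafted
  P <- pool_weights(comm)
  pool <- colnames(P)
  seeds <- derive_seed(seed, paste0("ses_phylo_topo_", seq_along(trees)))
  per_topo <- lapply(seq_along(trees), function(k) {
    d <- divergence_matrix(trees[[k]], convention)[pool, pool]
    ses_from_distance(P, d, n_rand, seeds[k])
  })
  agg <- function(field) {
    m <- do.call(rbind, lapply(per_topo, `[[`, field))
    colMeans(m)
  }
  ses_mat <- do.call(rbind, lapply(per_topo, `[[`, "ses"))
  res <- list(observed = agg("observed"), null_mean = agg("null_mean"),
              null_sd = agg("null_sd"), ses = colMeans(ses_mat))
  out <- ses_result_frame(rownames(comm), "raoD", res, n_rand, seed,
                          rowSums(P > 0))
  out$ses_sd <- if (length(trees) > 1) apply(ses_mat, 2, stats::sd) else 0
  out
}

#' Standardized effect size of functional diversity (raoQ)
#'
#' Null model: the trait rows of the species pool are permuted across
#' species (999 times by default) and raoQ recomputed on the resulting
#' distances. Negative SES indicates trait convergence (habitat
#' filtering), positive SES divergence (limiting similarity).
#'
#' @param comm community matrix.
#' @param traits complete trait table covering the pool.
#' @param n_rand number of randomizations.
#' @param seed integer seed.
#' @param distance_method see \code{\link{functional_distance}}.
#' @return data frame as in \code{\link{ses_phylogenetic}} with metric
#'   "raoQ".
#' @export
ses_functional <- function(comm, traits, n_rand = 999, seed = 1,
                           distance_method = "gower") {
  P <- pool_weights(comm)
  pool <- colnames(P)
  d <- functional_distance(traits, distance_method)[pool, pool]
  res <- ses_from_distance(P, d, n_rand, derive_seed(seed, "ses_functional"))
  out <- ses_result_frame(rownames(comm), "raoQ", res, n_rand, seed,
                          rowSums(P > 0))
  out$ses_sd <- 0
  out
}

#' Standardized effect size of community-weighted means
#'
#' Null model: all trait columns are permuted jointly by row across the
#' species pool (preserving trait covariance), the CWM of every plot
#' recomputed per permutation, and SES formed per plot and trait. A
#' positive CWM SES means the community is dominated by species with
#' higher-than-random values of that trait.
#'
#' @param comm community matrix.
#' @param traits complete trait table.
#' @param n_rand number of randomizations.
#' @param seed integer seed.
#' @return data frame: plot, metric ("cwm_<trait>"), observed, null_mean,
#'   null_sd, ses, n_randomizations, seed, reason.
#' @export
ses_cwm <- function(comm, traits, n_rand = 999, seed = 1) {
  P <- pool_weights(comm)
  pool <- colnames(P)
  X <- unclass(traits)[pool, , drop = FALSE]
  obs <- P %*% X
  set.seed(derive_seed(seed, "ses_cwm"))
  # accumulate deviations from the observed CWM: numerically stable when
  # the null barely moves (e.g. a plot holding the whole pool)
  sums <- matrix(0, nrow(obs), ncol(obs))
  sq <- matrix(0, nrow(obs), ncol(obs))
  for (r in seq_len(n_rand)) {
    dev <- P %*% X[sample.int(length(pool)), , drop = FALSE] - obs
    sums <- sums + dev
    sq <- sq + dev^2
  }
  mean_dev <- sums / n_rand
  null_mean <- obs + mean_dev
  null_var <- (sq - n_rand * mean_dev^2) / (n_rand - 1)
  null_sd <- sqrt(pmax(null_var, 0))
  ses <- standardize_effect(obs, null_mean, null_sd)
  richness <- rowSums(P > 0)
  rows <- lapply(seq_len(ncol(X)), function(j) {
    res <- list(observed = obs[, j], null_mean = null_mean[, j],
                null_sd = null_sd[, j], ses = ses[, j])
    ses_result_frame(rownames(comm), paste0("cwm_", colnames(X)[j]),
                     res, n_rand, seed, richness)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$ses_sd <- 0  # CWMs do not depend on the phylogeny; no topology spread
  out
}

#' One-sample t test against zero
#'
#' Classical two-sided one-sample t test of the mean against mu = 0, used
#' to ask whether per-plot SES values within a land-use category differ
#' systematically from the null expectation.
#'
#' @param values numeric vector, n >= 2, finite, non-constant.
#' @return list: \code{t}, \code{p_value}, \code{df}, \code{mean}.
#' @export
one_sample_t <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 finite values")
  if (stats::var(values) == 0) stop("zero variance; t statistic undefined")
  ht <- stats::t.test(values, mu = 0)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), mean = mean(values))
}

#' Per-category SES summary with one-sample t tests
#'
#' @param ses_table data frame from one of the \code{ses_*} functions (rows
#'   from several metrics may be concatenated).
#' @param design named category factor covering the plots.
#' @return data frame: category, metric, n, mean_ses, t, p_value.
#' @export
ses_summary <- function(ses_table, design) {
  ses_table$category <- as.character(design[ses_table$plot])
  groups <- split(ses_table, list(ses_table$category, ses_table$metric),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    v <- g$ses[is.finite(g$ses)]
    tt <- if (length(v) >= 2 && stats::var(v) > 0) one_sample_t(v)
          else list(t = NA_real_, p_value = NA_real_)
    data.frame(category = g$category[1], metric = g$metric[1],
               n = length(v), mean_ses = mean(v),
               t = tt$t, p_value = tt$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$metric, out$category), ]
}
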