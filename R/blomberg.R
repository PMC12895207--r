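#' Blomberg's K phylogenetic signal
#'
#' Ratio-based statistic comparing the observed partitioning of trait
#' variance on a phylogeny with its Brownian-motion (BM) expectation.
#' With C the phylogenetic covariance matrix (shared branch length from the
#' root) and a-hat the GLS estimate of the root state,
#' \deqn{K = \frac{(MSE_0/MSE)_{obs}}{(tr(C) - n/\sum C^{-1}) / (n-1)}}
#' where MSE0 is the mean squared deviation of tip values from a-hat and
#' MSE the GLS mean squared error under C. K is near 1 when the trait
#' evolved by BM on the tree and near 0 when close relatives are no more
#' similar than distant ones.
#'
#' Significance is assessed by permuting trait values across tips: the
#' p-value is the proportion of permutations whose MSE is less than or
#' equal to the observed MSE (low MSE = strong signal), the observed
#' configuration counting in both numerator and denominator.
#'
#' @param tree phylo object with branch lengths and positive depth.
#' @param trait named numeric vector of tip values (names matched to tip
#'   labels) or unnamed vector in tip order.
#' @param n_permutations number of tip permutations for the p-value; 0
#'   skips the test.
#' @param seed integer seed for the permutations.
#' @return list of class \code{phylo_signal}: \code{K}, \code{p_value},
#'   \code{n_permutations}, \code{MSE0}, \code{MSE}.
#' @export
blomberg_k <- function(tree, trait, n_permutations = 999, seed = 1) {
  tree <- validate_tree(tree)
  n <- ape::Ntip(tree)
  if (!is.null(names(trait))) {
    if (!all(tree$tip.label %in% names(trait)))
      stop("trait values missing for tips: ",
           paste(setdiff(tree$tip.label, names(trait)), collapse = ", "))
    x <- trait[tree$tip.label]
  } else {
    if (length(trait) != n) stop("unnamed trait vector must have one value per tip")
    x <- trait
  }
  if (stats::var(x) == 0)
    stop("trait is constant across tips; K is undefined")

  C <- ape::vcv.phylo(tree)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("phylogenetic covariance matrix is singular"))
  ones <- rep(1, n)
  denom_sum <- sum(Cinv)

  mse_pair <- function(x) {
    ahat <- sum(Cinv %*% x) / denom_sum
    dev <- x - ahat
    mse0 <- sum(dev^2) / (n - 1)
    mse <- drop(crossprod(dev, Cinv %*% dev)) / (n - 1)
    c(mse0 = mse0, mse = mse)
  }

  obs <- mse_pair(x)
  expected_ratio <- (sum(diag(C)) - n / denom_sum) / (n - 1)
  K <- (obs["mse0"] / obs["mse"]) / expected_ratio

  p <- NA_real_
  if (n_permutations > 0) {
    set.seed(seed)
    null_mse <- vapply(seq_len(n_permutations), function(i) {
      mse_pair(x[sample.int(n)])[["mse"]]
    }, numeric(1))
    p <- (sum(null_mse <= obs[["mse"]]) + 1) / (n_permutations + 1)
  }

  structure(list(K = unname(K), p_value = p, n_permutations = n_permutations,
                 MSE0 = unname(obs["mse0"]), MSE = unname(obs["mse"])),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f", x$K))
  if (!is.na(x$p_value))
    cat(sprintf("  (p = %.4f, %d permutations)", x$p_value, x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Blomberg's K for every trait in a table
#'
#' @param tree phylo object.
#' @param traits trait table (species rows must cover the tips; extra
#'   species are ignored).
#' @param n_permutations permutations per trait.
#' @param seed global seed; per-trait seeds are derived from it.
#' @return data frame: trait, K, p_value.
#' @export
phylo_signal_table <- function(tree, traits, n_permutations = 999, seed = 1) {
  seeds <- derive_seed(seed, paste0("blomberg_", colnames(traits)))
  rows <- lapply(seq_len(ncol(traits)), function(j) {
    x <- traits[, j]
    names(x) <- rownames(traits)
    res <- blomberg_k(tree, x, n_permutations, seeds[j])
    data.frame(trait = colnames(traits)[j], K = res$K, p_value = res$p_value)
  })
  do.call(rbind, rows)
}
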