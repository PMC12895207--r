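#' Gini-Simpson taxonomic diversity
#'
#' D = 1 - sum(p_i^2): the probability that two individuals drawn at random
#' from a plot belong to different species. The inverse-Simpson form
#' 1/sum(p_i^2) is available via \code{variant}.
#'
#' @param abund non-negative abundance vector with positive sum.
#' @param variant \code{"gini_simpson"} (default) or \code{"inverse"}.
#' @return a single number; in [0, 1) for the Gini-Simpson form.
#' @export
simpson_d <- function(abund, variant = c("gini_simpson", "inverse")) {
  variant <- match.arg(variant)
  p <- rel_abund(abund)
  lambda <- sum(p^2)
  if (variant == "gini_simpson") 1 - lambda else 1 / lambda
}

#' Rao's quadratic entropy
#'
#' Q = sum_ij p_i p_j d_ij: the expected dissimilarity between two
#' individuals drawn at random from the community. With phylogenetic
#' divergences d it is the phylogenetic diversity raoD; with functional
#' (Gower) distances it is the functional diversity raoQ. With the 0/1
#' distance (d_ij = 1 for i != j) it reduces exactly to the Gini-Simpson
#' index.
#'
#' @param abund named non-negative abundance vector (names = species), or
#'   unnamed vector aligned with \code{d}.
#' @param d square symmetric dissimilarity matrix with zero diagonal and
#'   dimnames covering the species with positive abundance.
#' @return a single non-negative number.
#' @export
rao_q <- function(abund, d) {
  if (!is.null(names(abund)) && !is.null(rownames(d))) {
    keep <- names(abund)[abund > 0]
    missing <- setdiff(keep, rownames(d))
    if (length(missing) > 0)
      stop("species absent from distance matrix: ", paste(missing, collapse = ", "))
    p <- rel_abund(abund[keep])
    dd <- d[keep, keep, drop = FALSE]
  } else {
    if (length(abund) != nrow(d)) stop("abundance/distance dimension mismatch")
    p <- rel_abund(abund)
    dd <- d
  }
  drop(crossprod(p, dd %*% p))
}

#' Functional distance matrix from a trait table
#'
#' Default is the Gower dissimilarity on the (log-scale) traits: per trait
#' |x_i - x_j| / range, averaged over traits, so entries lie in [0, 1].
#' Traits with zero range carry no information and are dropped with a
#' warning. Alternative scalings: \code{"euclidean_z"} (Euclidean on
#' z-scored traits) and \code{"euclidean_log"} (Euclidean on the stored
#' log values), provided because published Rao magnitudes may reflect
#' unscaled trait distances.
#'
#' @param traits complete trait table (no NAs).
#' @param method \code{"gower"}, \code{"euclidean_z"} or \code{"euclidean_log"}.
#' @return square symmetric matrix, dimnames = species, attribute
#'   \code{kind = "functional-gower"} (or the method name).
#' @export
functional_distance <- function(traits,
                                method = c("gower", "euclidean_z", "euclidean_log")) {
  method <- match.arg(method)
  x <- unclass(traits)
  if (anyNA(x)) stop("trait table has missing values; impute first")
  rng <- apply(x, 2, function(v) diff(range(v)))
  if (method == "gower") {
    zero <- rng == 0
    if (all(zero)) {
      # all species functionally identical: a valid (if degenerate) input
      warning("all traits have zero range; functional distances are all 0")
      d <- matrix(0, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
      attr(d, "kind") <- "functional-gower"
      return(d)
    }
    if (any(zero)) {
      warning("zero-range trait(s) excluded from Gower distance: ",
              paste(colnames(x)[zero], collapse = ", "))
      x <- x[, !zero, drop = FALSE]
      rng <- rng[!zero]
    }
    xs <- sweep(x, 2, rng, "/")
    d <- matrix(0, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
    for (j in seq_len(ncol(xs))) {
      d <- d + abs(outer(xs[, j], xs[, j], "-"))
    }
    d <- d / ncol(xs)
    attr(d, "kind") <- "functional-gower"
  } else {
    if (method == "euclidean_z") x <- scale(x)
    d <- as.matrix(stats::dist(x))
    attr(d, "kind") <- paste0("functional-", method)
  }
  d
}

#' Community-weighted mean traits of one plot
#'
#' CWM_t = sum_i p_i x_it with p_i the relative abundances.
#'
#' @param abund named abundance vector (names = species).
#' @param traits complete trait table covering all species with positive
#'   abundance.
#' @return named numeric vector, one value per trait.
#' @export
cwm <- function(abund, traits) {
  keep <- names(abund)[abund > 0]
  missing <- setdiff(keep, rownames(traits))
  if (length(missing) > 0)
    stop("species with positive abundance lacking traits: ",
         paste(missing, collapse = ", "))
  p <- rel_abund(abund[keep])
  drop(p %*% unclass(traits)[keep, , drop = FALSE])
}

#' Phylogenetic Rao entropy averaged over a set of grafted topologies
#'
#' raoD of one plot computed on the divergence matrix of each alternative
#' topology, then summarized by mean and SD. Plots containing no grafted
#' species give SD 0 since all topologies agree on the backbone.
#'
#' @param abund named abundance vector for one plot.
#' @param grafted \code{grafted_trees} object (or a list of phylo trees).
#' @param convention divergence convention, see \code{\link{divergence_matrix}}.
#' @return list: \code{mean}, \code{sd}, \code{values} (per topology).
#' @export
phylo_rao_over_topologies <- function(abund, grafted,
                                      convention = "half_patristic") {
  trees <- if (inherits(grafted, "grafted_trees")) grafted$trees else grafted
  vals <- vapply(trees, function(tr) {
    rao_q(abund, divergence_matrix(tr, convention))
  }, numeric(1))
  list(mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else 0,
       values = vals)
}

#' Per-plot diversity profile
#'
#' Assembles the per-plot taxonomic (Gini-Simpson D), phylogenetic (raoD,
#' averaged over grafted topologies) and functional (raoQ on Gower trait
#' distances) diversity plus the six community-weighted means, tagged by
#' land-use category.
#'
#' @param comm community matrix.
#' @param traits complete trait table.
#' @param grafted \code{grafted_trees} object, a list of phylo trees, or a
#'   single phylo tree.
#' @param design named category factor covering all plots (see
#'   \code{\link{read_design}}); NULL leaves the category column NA.
#' @param distance_method functional distance scaling, see
#'   \code{\link{functional_distance}}.
#' @param simpson_variant see \code{\link{simpson_d}}.
#' @param convention divergence convention for raoD.
#' @return data frame with one row per plot: plot, category, D, raoD,
#'   raoD_sd, raoQ, and one CWM column per trait (\code{cwm_<trait>}).
#' @export
diversity_profile <- function(comm, traits, grafted, design = NULL,
                              distance_method = "gower",
                              simpson_variant = "gini_simpson",
                              convention = "half_patristic") {
  if (inherits(grafted, "phylo")) grafted <- list(grafted)
  trees <- if (inherits(grafted, "grafted_trees")) grafted$trees else grafted
  species <- colnames(comm)
  present <- species[colSums(comm) > 0]
  for (tr in trees[1]) {
    miss <- setdiff(present, tr$tip.label)
    if (length(miss) > 0)
      stop("species missing from phylogeny: ", paste(miss, collapse = ", "))
  }
  dfun <- functional_distance(traits, distance_method)
  pd <- lapply(trees, divergence_matrix, convention = convention)

  if (!is.null(design)) design <- align_design(comm, design)

  rows <- lapply(rownames(comm), function(pl) {
    a <- comm[pl, ]
    names(a) <- species
    rao_phylo <- {
      vals <- vapply(pd, function(d) rao_q(a, d), numeric(1))
      c(mean(vals), if (length(vals) > 1) stats::sd(vals) else 0)
    }
    cw <- cwm(a, traits)
    out <- data.frame(plot = pl,
                      category = if (is.null(design)) NA_character_
                                 else as.character(design[pl]),
                      D = simpson_d(a, simpson_variant),
                      raoD = rao_phylo[1], raoD_sd = rao_phylo[2],
                      raoQ = rao_q(a, dfun))
    cwdf <- as.data.frame(as.list(cw))
    names(cwdf) <- paste0("cwm_", names(cw))
    cbind(out, cwdf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
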