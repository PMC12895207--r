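# shared fixtures built in code

# ultrametric cherry: two tips at depth t
cherry <- function(t = 1, labels = c("A_x", "B_y")) {
  tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g):0;",
                                      labels[1], t, labels[2], t))
  tr
}

# star phylogeny with n tips, all terminal branches of length t (C = t * I)
star_tree <- function(n = 20, t = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(t, nrow(tr$edge))
  tr$tip.label <- sprintf("G%02d_sp%02d", seq_len(n), seq_len(n))
  tr$root.edge <- 0  # mark the basal polytomy as a true root
  tr
}

# random named abundance vector over k species (some zeros allowed)
random_abund <- function(k, zero_frac = 0.2) {
  a <- stats::rexp(k)
  a[stats::runif(k) < zero_frac] <- 0
  if (all(a == 0)) a[1] <- 1
  stats::setNames(a, paste0("sp", seq_len(k)))
}

# random symmetric distance matrix with zero diagonal over given ids
random_dist <- function(ids) {
  k <- length(ids)
  m <- matrix(stats::runif(k * k), k, k)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  m
}

# brute-force Rao Q by explicit double loop
rao_brute <- function(abund, d) {
  p <- unname(abund / sum(abund))
  q <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      q <- q + p[i] * p[j] * d[i, j]
    }
  }
  q
}

# brute-force Gower dissimilarity by explicit pairwise loop
gower_brute <- function(x) {
  rng <- apply(x, 2, function(v) diff(range(v)))
  keep <- rng > 0
  x <- x[, keep, drop = FALSE]
  rng <- rng[keep]
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- mean(abs(x[i, ] - x[j, ]) / rng)
    }
  }
  d
}

# naive patristic distance: sum edge lengths along the tip-to-tip node path
patristic_brute <- function(tree) {
  n <- ape::Ntip(tree)
  edge_len <- function(a, b) {
    hit <- which((tree$edge[, 1] == a & tree$edge[, 2] == b) |
                 (tree$edge[, 1] == b & tree$edge[, 2] == a))
    tree$edge.length[hit]
  }
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      path <- ape::nodepath(tree, i, j)
      s <- 0
      for (k in seq_len(length(path) - 1)) s <- s + edge_len(path[k], path[k + 1])
      d[i, j] <- d[j, i] <- s
    }
  }
  d
}

# small complete trait table over given species
toy_traits <- function(species, n_traits = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(length(species) * n_traits), length(species),
              dimnames = list(species, paste0("trait", seq_len(n_traits))))
  divdim::trait_table(x)
}
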