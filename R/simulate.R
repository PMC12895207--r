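#' Simulate an ultrametric pure-birth phylogeny
#'
#' Yule (pure-birth) tree rescaled so every root-to-tip depth equals
#' \code{depth}. Tips are labeled \code{G<genus>_sp<number>}, genera being
#' contiguous blocks of tips in cladewise order so that congeners are
#' clustered in the tree, as in a real flora.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @param depth root-to-tip depth after rescaling (e.g. 100 for a
#'   Myr-scale angiosperm tree).
#' @param n_genera number of genera to carve the tips into.
#' @return a validated ultrametric \code{phylo} object.
#' @export
simulate_tree <- function(n_tips, seed = 1, depth = 1,
                          n_genera = max(1, round(n_tips / 7))) {
  if (n_tips < 2) stop("need at least 2 tips")
  if (n_genera > n_tips) stop("more genera than tips")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length *
    (depth / max(ape::node.depth.edgelength(tree)[seq_len(n_tips)]))
  # genera are true clades: split the largest clade until n_genera remain,
  # so every genus is monophyletic
  clades <- list(seq_len(n_tips))
  if (n_genera > 1) {
    kids <- split(tree$edge[, 2], tree$edge[, 1])
    tips_below <- function(node) {
      if (node <= n_tips) return(node)
      unlist(lapply(kids[[as.character(node)]], tips_below))
    }
    root <- n_tips + 1L
    nodes <- list(root)
    while (length(nodes) < n_genera) {
      sizes <- vapply(nodes, function(nd) length(tips_below(nd)), integer(1))
      splittable <- which(sizes > 1)
      i <- splittable[which.max(sizes[splittable])]
      nodes <- c(nodes[-i], as.list(kids[[as.character(nodes[[i]])]]))
    }
    clades <- lapply(nodes, tips_below)
    clades <- clades[order(vapply(clades, min, integer(1)))]
  }
  labels <- character(n_tips)
  for (g in seq_along(clades)) {
    labels[clades[[g]]] <- sprintf("G%03d_sp%04d", g, clades[[g]])
  }
  tree$tip.label <- labels
  validate_tree(tree)
}

#' Simulate continuous traits with tunable phylogenetic signal
#'
#' Each trait is a mixture of a Brownian-motion realization on the tree and
#' iid Gaussian noise: both components are standardized to unit sample
#' variance across tips, then combined as
#' \code{signal * BM + (1 - signal) * noise}. \code{signal = 1} gives pure
#' BM (Blomberg's K near 1); \code{signal = 0} gives phylogeny-free traits
#' (K near 0).
#'
#' @param tree ultrametric phylo object.
#' @param n_traits number of independent traits.
#' @param signal mixing weight in [0, 1].
#' @param seed integer seed.
#' @param trait_names column names; defaults to the six standard traits
#'   when \code{n_traits == 6}.
#' @return a complete \code{trait_table} (tips x traits).
#' @export
simulate_traits <- function(tree, n_traits = 6, signal = 0.1, seed = 1,
                            trait_names = NULL) {
  if (signal < 0 || signal > 1) stop("signal must be in [0, 1]")
  n <- ape::Ntip(tree)
  if (is.null(trait_names)) {
    trait_names <- if (n_traits == 6) default_traits()
                   else paste0("trait", seq_len(n_traits))
  }
  set.seed(seed)
  L <- chol(ape::vcv.phylo(tree))
  std <- function(v) (v - mean(v)) / stats::sd(v)
  X <- sapply(seq_len(n_traits), function(j) {
    bm <- std(drop(crossprod(L, stats::rnorm(n))))
    wn <- stats::rnorm(n)
    wn <- wn - mean(wn)
    wn <- std(wn - bm * sum(wn * bm) / sum(bm * bm))  # orthogonal to the BM part
    signal * bm + (1 - signal) * wn
  })
  dimnames(X) <- list(tree$tip.label, trait_names)
  trait_table(X)
}

#' Assembly scenario for the community simulator
#'
#' @param regime \code{"neutral"}, \code{"filtering"} (environmental
#'   filtering toward a per-plot trait optimum) or
#'   \code{"limiting_similarity"} (greedy functional max-min spacing).
#' @param strength non-negative; 0 reduces any regime to neutral. For
#'   filtering, selection weights are exp(-strength * (t_i - optimum)^2) on
#'   the z-scored filter trait; for limiting similarity, each added species
#'   is the greedy max-min choice with probability 1 - exp(-strength), else
#'   uniform.
#' @param richness species per plot.
#' @param meanlog,sdlog lognormal abundance parameters.
#' @param filter_trait trait (name or index) the filtering regime acts on.
#' @return list of class \code{assembly_scenario}.
#' @export
assembly_scenario <- function(regime = c("neutral", "filtering",
                                         "limiting_similarity"),
                              strength = 0, richness = 30,
                              meanlog = 0, sdlog = 1, filter_trait = 1) {
  regime <- match.arg(regime)
  if (strength < 0) stop("strength must be non-negative")
  structure(list(regime = regime, strength = strength, richness = richness,
                 meanlog = meanlog, sdlog = sdlog,
                 filter_trait = filter_trait),
            class = "assembly_scenario")
}

#' Assemble plot communities under a given regime
#'
#' Species are drawn from the pool without replacement: uniformly
#' (neutral), with Gaussian weights around a per-plot trait optimum
#' (filtering; the optimum is drawn once per plot, uniformly over the
#' observed range of the z-scored filter trait), or by greedy max-min
#' functional spacing (limiting similarity). Lognormal abundances are then
#' assigned to the selected species.
#'
#' @param tree phylo object for the pool (tips define the pool).
#' @param traits complete trait table for the pool.
#' @param scenario an \code{\link{assembly_scenario}}.
#' @param n_plots number of plots to assemble.
#' @param seed integer seed.
#' @param plot_ids optional plot names.
#' @return a \code{community_matrix} (n_plots x pool).
#' @export
assemble_community <- function(tree, traits, scenario, n_plots, seed = 1,
                               plot_ids = sprintf("plot%03d", seq_len(n_plots))) {
  pool <- tree$tip.label
  if (!all(pool %in% rownames(traits)))
    stop("traits missing for pool species")
  S <- length(pool)
  k <- scenario$richness
  if (k > S) stop("richness exceeds pool size")
  set.seed(seed)
  tz <- NULL
  dfun <- NULL
  if (scenario$regime == "filtering") {
    t0 <- unclass(traits)[pool, scenario$filter_trait]
    tz <- (t0 - mean(t0)) / stats::sd(t0)
  } else if (scenario$regime == "limiting_similarity") {
    dfun <- functional_distance(traits)[pool, pool]
  }
  p_greedy <- 1 - exp(-scenario$strength)

  M <- matrix(0, n_plots, S, dimnames = list(plot_ids, pool))
  for (i in seq_len(n_plots)) {
    sel <- switch(scenario$regime,
      neutral = sample.int(S, k),
      filtering = {
        optimum <- stats::runif(1, min(tz), max(tz))
        w <- pmax(exp(-scenario$strength * (tz - optimum)^2), 1e-300)
        sample.int(S, k, prob = w)
      },
      limiting_similarity = {
        sel <- sample.int(S, 1)
        while (length(sel) < k) {
          rest <- setdiff(seq_len(S), sel)
          if (stats::runif(1) < p_greedy) {
            mind <- apply(dfun[rest, sel, drop = FALSE], 1, min)
            best <- rest[mind == max(mind)]
            sel <- c(sel, if (length(best) > 1) sample(best, 1) else best)
          } else {
            sel <- c(sel, if (length(rest) > 1) sample(rest, 1) else rest)
          }
        }
        sel
      })
    M[i, sel] <- stats::rlnorm(k, scenario$meanlog, scenario$sdlog)
  }
  community_matrix(M)
}

#' Default configuration of the simulated grazing study
#'
#' 292 species in ~42 genera on a 100-unit-deep Yule tree, six
#' log-scale traits with weak phylogenetic signal (0.1), and 24 plots of
#' richness 30 in each of the five land-use categories. Grazed categories
#' assemble under environmental filtering whose strength increases with
#' grazing pressure; recent abandonment is neutral (stochastic
#' colonization) and past abandonment is intermediately filtered, echoing
#' field expectations of convergence under disturbance.
#'
#' @param seed global seed.
#' @return a named list accepted by \code{\link{simulate_study}}.
#' @export
default_study_config <- function(seed = 1) {
  list(
    n_species = 292,
    n_genera = 42,
    tree_depth = 100,
    n_traits = 6,
    signal = 0.1,
    plots_per_category = stats::setNames(rep(24L, 5), land_use_categories()),
    scenarios = list(
      intensive = assembly_scenario("filtering", strength = 8),
      intermediate = assembly_scenario("filtering", strength = 2),
      extensive = assembly_scenario("filtering", strength = 1),
      recent_abandonment = assembly_scenario("neutral"),
      past_abandonment = assembly_scenario("filtering", strength = 4)
    ),
    seed = seed
  )
}

#' Simulate a full grazing study
#'
#' Generates the species pool (tree + traits) and one community per plot
#' under the per-category assembly scenarios, with every stage seeded
#' deterministically from the global seed.
#'
#' @param config list as returned by \code{\link{default_study_config}}
#'   (any subset of fields may be overridden).
#' @return object of class \code{simulated_study}: \code{tree},
#'   \code{traits}, \code{comm}, \code{design}, \code{config}.
#' @export
simulate_study <- function(config = default_study_config()) {
  defaults <- default_study_config(seed = config$seed %||% 1)
  config <- utils::modifyList(defaults, config)
  counts <- unlist(config$plots_per_category)  # accept list from YAML configs
  if (is.null(names(counts)) || anyNA(names(counts)) || any(names(counts) == ""))
    stop("plots_per_category must be named by category")
  if (any(counts <= 0)) stop("plot counts must be positive")

  tree <- simulate_tree(config$n_species,
                        seed = derive_seed(config$seed, "tree"),
                        depth = config$tree_depth,
                        n_genera = config$n_genera)
  traits <- simulate_traits(tree, config$n_traits, config$signal,
                            seed = derive_seed(config$seed, "traits"))
  comms <- list(); design <- list()
  offset <- 0L
  for (cat in names(counts)) {
    sc <- config$scenarios[[cat]]
    if (is.null(sc)) stop("no assembly scenario for category: ", cat)
    ids <- sprintf("plot%03d", offset + seq_len(counts[[cat]]))
    offset <- offset + counts[[cat]]
    comms[[cat]] <- assemble_community(tree, traits, sc, counts[[cat]],
                                       seed = derive_seed(config$seed,
                                                          paste0("comm_", cat)),
                                       plot_ids = ids)
    design[[cat]] <- stats::setNames(rep(cat, length(ids)), ids)
  }
  comm <- community_matrix(do.call(rbind, lapply(comms, unclass)))
  design <- structure(factor(unlist(unname(design)),
                             levels = names(counts)),
                      names = unlist(lapply(design, names)))
  structure(list(tree = tree, traits = traits, comm = comm,
                 design = design, config = config),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("Simulated study: %d plots x %d species, %d traits, %d categories (seed %d)\n",
              nrow(x$comm), ncol(x$comm), ncol(x$traits),
              nlevels(x$design), x$config$seed))
  invisible(x)
}

#' Write the four input files of a simulated study
#'
#' Emits community.csv, traits.csv, tree.nwk, design.csv and a JSON
#' manifest recording the configuration and seeds.
#'
#' @param study a \code{simulated_study}.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_community(study$comm, file.path(dir, "community.csv"))
  write_traits(study$traits, file.path(dir, "traits.csv"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(data.frame(plot = names(study$design),
                              category = as.character(study$design)),
                   file.path(dir, "design.csv"), row.names = FALSE)
  cfg <- study$config
  cfg$scenarios <- lapply(cfg$scenarios, unclass)
  cfg$plots_per_category <- as.list(cfg$plots_per_category)
  manifest <- list(generator = "divdim::write_study",
                   version = as.character(utils::packageVersion("divdim")),
                   seed = cfg$seed, config = cfg,
                   files = c("community.csv", "traits.csv", "tree.nwk",
                             "design.csv"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
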