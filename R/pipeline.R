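#' Pipeline run configuration
#'
#' @param community,traits,tree,design input file paths (CSV/CSV/Newick/CSV)
#'   or the corresponding in-memory objects.
#' @param taxonomy optional taxonomy data frame (species, genus, family)
#'   for imputation and family-level grafting.
#' @param log_transform_traits whether trait values on disk are raw and
#'   must be log-transformed on read (ignored for in-memory trait tables).
#' @param n_topologies grafted topologies for phylogenetic metrics.
#' @param n_rand randomizations per null model.
#' @param n_boot bootstrap resamples for IV-evenness CIs.
#' @param distance_method functional distance scaling
#'   (gower | euclidean_z | euclidean_log).
#' @param simpson_variant gini_simpson | inverse.
#' @param iv_variant r2 | abs_r.
#' @param adjust pairwise p adjustment (holm | BH | none).
#' @param convention phylogenetic divergence convention.
#' @param seed global seed; all stage seeds derive from it.
#' @param out_dir output directory; NULL disables file output.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(community, traits, tree, design, taxonomy = NULL,
                       log_transform_traits = FALSE,
                       n_topologies = 1000, n_rand = 999, n_boot = 999,
                       distance_method = "gower",
                       simpson_variant = "gini_simpson",
                       iv_variant = "r2", adjust = "holm",
                       convention = "half_patristic",
                       seed = 1, out_dir = NULL) {
  counts <- c(n_topologies = n_topologies, n_rand = n_rand, n_boot = n_boot)
  if (any(counts[c("n_topologies", "n_rand")] < 1) || n_boot < 0)
    stop("randomization counts must be positive")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full diversity-analysis pipeline
#'
#' Stages, in order: read and validate the four inputs; impute missing
#' traits; reconcile the species pool (community species absent from the
#' phylogeny are grafted into their genus clade, species that cannot be
#' placed or lack traits are dropped with a warning); per-plot diversity
#' profiles and community-weighted means; Blomberg's K per trait;
#' permutation SES for raoD, raoQ and the CWMs with per-category one-sample
#' t tests; Kruskal-Wallis and pairwise Wilcoxon comparisons across
#' land-use categories; per-category dimensionality (EE, IVs, IV evenness
#' with bootstrap CI). Identical config and seed give identical results.
#'
#' @param config a \code{\link{run_config}}.
#' @return list of class \code{pipeline_result} with elements
#'   \code{profile}, \code{phylo_signal}, \code{ses}, \code{ses_summary},
#'   \code{group_tests}, \code{letters}, \code{dimensionality},
#'   \code{dropped_species}, \code{config}. Written to \code{out_dir} as
#'   tidy CSVs plus a JSON manifest when configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) message(sprintf(paste0("[divdim] ", fmt), ...))

  t0 <- Sys.time()
  comm <- if (is.character(config$community)) read_community(config$community)
          else community_matrix(config$community)
  traits <- if (is.character(config$traits))
              read_traits(config$traits, config$log_transform_traits)
            else trait_table(config$traits)
  tree <- if (is.character(config$tree)) read_tree(config$tree)
          else validate_tree(config$tree)
  design <- if (is.character(config$design)) read_design(config$design)
            else config$design
  design <- align_design(comm, design)
  say("inputs: %d plots, %d species, %d traits, %d tips",
      nrow(comm), ncol(comm), ncol(traits), ape::Ntip(tree))

  traits <- impute_traits(traits, config$taxonomy)
  imp <- attr(traits, "imputation")
  say("imputation: %d cells filled", if (is.null(imp)) 0L else nrow(imp))

  # reconcile pool: graft tree-missing species, drop unplaceable ones
  present <- colnames(comm)[colSums(comm) > 0]
  dropped <- character(0)
  no_traits <- setdiff(present, rownames(traits))
  if (length(no_traits) > 0) {
    warning("species without trait data dropped: ",
            paste(no_traits, collapse = ", "))
    dropped <- c(dropped, no_traits)
  }
  missing_tree <- setdiff(setdiff(present, dropped), tree$tip.label)
  grafted <- NULL
  if (length(missing_tree) > 0) {
    grafted <- graft_missing_species(tree, missing_tree,
                                     n_topologies = config$n_topologies,
                                     seed = derive_seed(config$seed, "graft"),
                                     taxonomy = config$taxonomy)
    dropped <- c(dropped, grafted$skipped)
    say("grafting: %d species into %d topologies, %d unplaceable",
        length(grafted$grafted), config$n_topologies,
        length(grafted$skipped))
  } else {
    grafted <- structure(list(trees = list(tree), grafted = character(0),
                              skipped = character(0), seed = config$seed),
                         class = "grafted_trees")
  }
  if (length(dropped) > 0) comm <- community_matrix(comm[, !colnames(comm) %in% dropped, drop = FALSE])
  pool <- colnames(comm)[colSums(comm) > 0]

  profile <- diversity_profile(comm, traits, grafted, design,
                               distance_method = config$distance_method,
                               simpson_variant = config$simpson_variant,
                               convention = config$convention)
  say("profiles: %d plots", nrow(profile))

  ps <- phylo_signal_table(grafted$trees[[1]],
                           unclass(traits)[intersect(rownames(traits),
                                                     grafted$trees[[1]]$tip.label), ,
                                           drop = FALSE],
                           n_permutations = config$n_rand,
                           seed = derive_seed(config$seed, "signal"))

  ses_p <- ses_phylogenetic(comm, grafted, config$n_rand,
                            derive_seed(config$seed, "ses_phylo"),
                            config$convention)
  ses_f <- ses_functional(comm, traits, config$n_rand,
                          derive_seed(config$seed, "ses_func"),
                          config$distance_method)
  ses_c <- ses_cwm(comm, traits, config$n_rand,
                   derive_seed(config$seed, "ses_cwm"))
  common <- intersect(names(ses_p), names(ses_f))
  ses_all <- rbind(ses_p[common], ses_f[common], ses_c[common])
  sesum <- ses_summary(ses_all, design)
  say("SES: %d randomizations x %d metrics", config$n_rand,
      length(unique(ses_all$metric)))

  responses <- c("D", "raoD", "raoQ",
                 grep("^cwm_", names(profile), value = TRUE))
  gt <- group_tests(profile, responses, config$adjust)

  dim_res <- dimensionality_by_category(profile, config$n_boot,
                                        derive_seed(config$seed, "boot"),
                                        config$iv_variant)
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- structure(list(profile = profile, phylo_signal = ps,
                           ses = ses_all, ses_summary = sesum,
                           group_tests = gt$tests, letters = gt$letters,
                           dimensionality = dim_res,
                           dropped_species = dropped, config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_results(result, config$out_dir)
  result
}

#' Write pipeline results as tidy CSVs plus a JSON manifest
#'
#' @param result a \code{pipeline_result}.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                           row.names = FALSE)
  w(result$profile, "diversity_profile.csv")
  w(result$profile[, c("plot", "category",
                       grep("^cwm_", names(result$profile), value = TRUE))],
    "cwm.csv")
  w(result$phylo_signal, "phylo_signal.csv")
  w(result$ses, "ses.csv")
  w(result$ses_summary, "ses_summary.csv")
  w(result$group_tests, "group_tests.csv")
  w(result$letters, "letters.csv")
  w(result$dimensionality, "dimensionality.csv")
  cfg <- result$config
  manifest <- list(
    package = "divdim",
    version = as.character(utils::packageVersion("divdim")),
    seed = cfg$seed,
    parameters = cfg[c("n_topologies", "n_rand", "n_boot", "distance_method",
                       "simpson_variant", "iv_variant", "adjust",
                       "convention")],
    inputs = lapply(cfg[c("community", "traits", "tree", "design")],
                    function(x) if (is.character(x)) x else "<in-memory>"),
    dropped_species = result$dropped_species,
    outputs = c("diversity_profile.csv", "cwm.csv", "phylo_signal.csv",
                "ses.csv", "ses_summary.csv", "group_tests.csv",
                "letters.csv", "dimensionality.csv"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("divdim pipeline result: %d plots, %d categories\n",
              nrow(x$profile), length(unique(x$profile$category))))
  cat("Per-category dimensionality:\n")
  print(x$dimensionality, digits = 3)
  invisible(x)
}
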