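#' Read and validate a phylogenetic tree
#'
#' Reads a rooted Newick tree with branch lengths. Tip labels are the
#' species ids; genera are parsed from the binomial labels.
#'
#' @param path Newick file path.
#' @return an \code{ape} \code{phylo} object, validated.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  validate_tree(tree)
}

#' Validate a phylo object for use in diversity analyses
#'
#' Checks rootedness, branch lengths, unique non-empty tip labels, and
#' records the maximum deviation of root-to-tip depths in the
#' \code{"ultrametric_deviation"} attribute.
#'
#' @param tree a \code{phylo} object.
#' @return the tree, with the deviation attribute set.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree has missing or negative branch lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  lbl <- tree$tip.label
  if (any(is.na(lbl)) || any(lbl == "")) stop("tree has unlabeled tips")
  if (anyDuplicated(lbl))
    stop("duplicate tip labels: ", paste(unique(lbl[duplicated(lbl)]), collapse = ", "))
  d <- tip_depths(tree)
  attr(tree, "ultrametric_deviation") <- max(d) - min(d)
  tree
}

#' Root-to-tip depths
#'
#' @param tree phylo object with branch lengths.
#' @return named numeric vector of root-to-tip path lengths, one per tip.
#' @export
tip_depths <- function(tree) {
  nt <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)[seq_len(nt)]
  names(depth) <- tree$tip.label
  depth
}

#' Phylogenetic divergence matrix
#'
#' Pairwise divergence between species: half the patristic (path) distance,
#' which for an ultrametric tree is the time since the most recent common
#' ancestor. This is the distance that phylogenetic Rao entropy (raoD) is
#' computed on. Set \code{convention = "patristic"} for the full path
#' distance instead.
#'
#' @param tree phylo object with branch lengths.
#' @param convention \code{"half_patristic"} (default, time since MRCA on
#'   ultrametric trees) or \code{"patristic"}.
#' @return square symmetric matrix with zero diagonal, dimnames = tips,
#'   attribute \code{kind = "phylogenetic-divergence"}.
#' @export
divergence_matrix <- function(tree, convention = c("half_patristic", "patristic")) {
  convention <- match.arg(convention)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- ape::cophenetic.phylo(tree)
  if (convention == "half_patristic") d <- d / 2
  attr(d, "kind") <- "phylogenetic-divergence"
  d
}

#' Graft species missing from a tree into their genus (or family) clade
#'
#' Each missing species is attached at a uniformly random point along the
#' branches of the smallest clade spanning its congeners, including the
#' clade's stem edge (edges chosen with probability proportional to their
#' length, then a uniform position along the edge). The new tip is extended
#' to the depth of the tree's deepest tip, so an ultrametric input stays
#' ultrametric. Species whose genus is absent fall back to their family
#' clade when a taxonomy is supplied; otherwise they are skipped with a
#' warning. Repeating the draw gives a set of alternative topologies whose
#' spread measures placement uncertainty.
#'
#' @param tree backbone phylo object.
#' @param missing character vector of species to add (binomial labels).
#' @param n_topologies number of independent grafted topologies to draw.
#' @param seed integer seed; each topology uses a sub-seed derived from it.
#' @param taxonomy optional data frame (\code{species}, \code{genus},
#'   \code{family}) enabling the family fallback; families of backbone tips
#'   must be resolvable through it.
#' @return object of class \code{grafted_trees}: list with \code{trees}
#'   (list of phylo), \code{grafted} (species actually added),
#'   \code{skipped} (species that could not be placed), \code{seed}.
#' @export
graft_missing_species <- function(tree, missing, n_topologies = 1000, seed = 1,
                                  taxonomy = NULL) {
  tree <- validate_tree(tree)
  missing <- setdiff(missing, tree$tip.label)
  tip_genus <- genus_of(tree$tip.label)
  tip_family <- NULL
  fam_of <- NULL
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    fam_of <- function(sp) {
      i <- match(sp, taxonomy$species)
      if (any(is.na(i))) {
        # resolve by genus when the species itself is not listed
        j <- match(genus_of(sp), taxonomy$genus)
        i[is.na(i)] <- j[is.na(i)]
      }
      as.character(taxonomy$family[i])
    }
    tip_family <- fam_of(tree$tip.label)
  }

  placeable <- character(0)
  skipped <- character(0)
  for (sp in missing) {
    if (genus_of(sp) %in% tip_genus) {
      placeable <- c(placeable, sp)
    } else if (!is.null(fam_of) && !is.na(fam_of(sp)) && fam_of(sp) %in% tip_family) {
      placeable <- c(placeable, sp)
    } else {
      skipped <- c(skipped, sp)
    }
  }
  if (length(skipped) > 0)
    warning("species without congeners (and no family match) not grafted: ",
            paste(skipped, collapse = ", "))

  sub_seeds <- derive_seed(seed, paste0("graft_topology_", seq_len(n_topologies)))
  trees <- vector("list", n_topologies)
  for (k in seq_len(n_topologies)) {
    set.seed(sub_seeds[k])
    tr <- tree
    for (sp in placeable) {
      g <- genus_of(sp)
      cur_genus <- genus_of(tr$tip.label)
      if (g %in% cur_genus) {
        clade_tips <- which(cur_genus == g)
      } else {
        cur_family <- fam_of(tr$tip.label)
        clade_tips <- which(cur_family == fam_of(sp))
      }
      tr <- graft_one(tr, sp, clade_tips)
    }
    trees[[k]] <- tr
  }
  structure(list(trees = trees, grafted = placeable, skipped = skipped,
                 seed = seed),
            class = "grafted_trees")
}

# Attach `label` along a random edge of the clade spanning `clade_tips`
# (tip indices), including the clade's stem; keeps tip depth equal to the
# tree's maximum depth.
graft_one <- function(tree, label, clade_tips) {
  nt <- ape::Ntip(tree)
  all_depth <- ape::node.depth.edgelength(tree)
  max_depth <- max(all_depth[seq_len(nt)])
  if (length(clade_tips) == 1L) {
    clade_node <- clade_tips   # single congener: its terminal edge is the clade
    inner <- integer(0)
  } else {
    clade_node <- ape::getMRCA(tree, clade_tips)
    desc <- phangorn::Descendants(tree, clade_node, type = "all")
    inner <- desc
  }
  # candidate edges: those whose child is in the clade, plus the stem edge
  children <- c(clade_node, inner)
  cand <- which(tree$edge[, 2] %in% children)
  len <- tree$edge.length[cand]
  if (sum(len) <= 0) {
    edge_i <- cand[1]
    pos <- 0
  } else {
    edge_i <- cand[sample.int(length(cand), 1, prob = len)]
    pos <- stats::runif(1, 0, tree$edge.length[edge_i])
  }
  child <- tree$edge[edge_i, 2]
  attach_depth <- all_depth[child] - pos
  tip_len <- max(max_depth - attach_depth, 0)
  phytools::bind.tip(tree, label, edge.length = tip_len,
                     where = child, position = pos)
}

#' @export
print.grafted_trees <- function(x, ...) {
  cat(sprintf("Grafted tree set: %d topologies, %d species grafted",
              length(x$trees), length(x$grafted)))
  if (length(x$skipped) > 0)
    cat(sprintf(", %d skipped", length(x$skipped)))
  cat("\n")
  invisible(x)
}

#' Write a grafted tree set as a multi-tree Newick file
#'
#' @param grafted a \code{grafted_trees} object.
#' @param path output path.
#' @export
write_grafted <- function(grafted, path) {
  ape::write.tree(do.call(c, grafted$trees), path)
  invisible(path)
}
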