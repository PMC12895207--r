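#' Default functional trait names
#'
#' The six traits of the leaf-economics and plant/organ-size spectra:
#' specific leaf area (SLA, mm^2/mg), leaf dry matter content (LDMC, mg/g),
#' leaf nitrogen content (LNC, mg/g), leaf area (LA, mm^2), seed mass
#' (SM, mg) and plant height (PH, cm). All are stored natural-log
#' transformed.
#'
#' @return character vector of trait names.
#' @export
default_traits <- function() c("SLA", "LDMC", "LNC", "LA", "SM", "PH")

#' Construct and validate a trait table
#'
#' @param x numeric matrix, species rows x trait columns, values on the
#'   natural-log scale. NAs mark missing values (fill with
#'   \code{\link{impute_traits}} before analysis).
#' @return matrix with class \code{"trait_table"}.
#' @export
trait_table <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("trait table needs species row names and trait column names")
  if (anyDuplicated(rownames(x))) stop("duplicate species ids in trait table")
  if (anyDuplicated(colnames(x))) stop("duplicate trait names")
  class(x) <- c("trait_table", class(x))
  x
}

#' Read a species x trait CSV
#'
#' @param path CSV path; species ids in the first column, trait names in
#'   the header.
#' @param log_transform if TRUE (default) values are raw trait measurements
#'   and are natural-log transformed on read; non-positive raw values are
#'   rejected. If FALSE values are taken as already on the log scale.
#' @return a \code{trait_table} on the natural-log scale.
#' @export
read_traits <- function(path, log_transform = TRUE) {
  df <- utils::read.csv(path, header = TRUE, row.names = 1, check.names = FALSE)
  x <- as.matrix(df)
  storage.mode(x) <- "double"
  if (log_transform) {
    bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-positive raw trait value at species '%s', trait '%s'; cannot log-transform",
                   rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
    x <- log(x)
  }
  trait_table(x)
}

#' Write a trait table to CSV
#'
#' Values are written as stored (natural-log scale).
#'
#' @param traits trait table.
#' @param path output path.
#' @export
write_traits <- function(traits, path) {
  df <- data.frame(species = rownames(traits), unclass(traits)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Taxonomy-based gap filling of a trait table
#'
#' Fills each missing cell with the genus mean of the trait, falling back
#' to the family mean, then the global mean. Observed cells are never
#' altered. Provenance of every filled cell is recorded in the
#' \code{"imputation"} attribute (species, trait, tier used).
#'
#' @param traits trait table (log scale) possibly containing NAs.
#' @param taxonomy data frame with columns \code{species}, \code{genus} and
#'   optionally \code{family}. If NULL, genus is parsed from the species
#'   label (first token before underscore or space) and the family tier is
#'   unavailable.
#' @return a complete \code{trait_table}.
#' @export
impute_traits <- function(traits, taxonomy = NULL) {
  x <- unclass(traits)
  if (!anyNA(x)) {
    attr(x, "imputation") <- data.frame(species = character(), trait = character(),
                                        tier = character())
    return(trait_table(x))
  }
  sp <- rownames(x)
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(species = sp, genus = genus_of(sp), family = NA_character_)
  }
  taxonomy <- as.data.frame(taxonomy)
  if (!"family" %in% names(taxonomy)) taxonomy$family <- NA_character_
  idx <- match(sp, taxonomy$species)
  genus <- as.character(taxonomy$genus[idx])
  family <- as.character(taxonomy$family[idx])

  zero_obs <- colnames(x)[colSums(!is.na(x)) == 0]
  if (length(zero_obs) > 0)
    stop("trait(s) with no observed values: ", paste(zero_obs, collapse = ", "))

  prov <- list()
  for (j in seq_len(ncol(x))) {
    miss <- which(is.na(x[, j]))
    if (length(miss) == 0) next
    gmean <- tapply(x[, j], genus, mean, na.rm = TRUE)
    fmean <- tapply(x[, j], family, mean, na.rm = TRUE)
    global <- mean(x[, j], na.rm = TRUE)
    for (i in miss) {
      g <- gmean[genus[i]]
      f <- if (!is.na(family[i])) fmean[family[i]] else NA_real_
      if (!is.na(g)) {
        x[i, j] <- g; tier <- "genus"
      } else if (!is.na(f)) {
        x[i, j] <- f; tier <- "family"
      } else {
        x[i, j] <- global; tier <- "global"
      }
      prov[[length(prov) + 1L]] <- data.frame(species = sp[i],
                                              trait = colnames(x)[j],
                                              tier = tier)
    }
  }
  out <- trait_table(x)
  attr(out, "imputation") <- do.call(rbind, prov)
  out
}

#' Genus of binomial species labels
#'
#' First token of the label, split on underscore or whitespace
#' (\code{"Festuca_rubra"} and \code{"Festuca rubra"} both give
#' \code{"Festuca"}).
#'
#' @param species character vector of species labels.
#' @return character vector of genera.
#' @export
genus_of <- function(species) {
  sub("[_ ].*$", "", species)
}
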