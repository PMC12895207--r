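#' Construct and validate a community matrix
#'
#' A community matrix is a plots x species numeric matrix of non-negative
#' abundances (cover or counts), with unique plot row names and unique
#' species column names. Relative abundances p_i within a plot are obtained
#' by dividing each row by its sum.
#'
#' @param x numeric matrix, plots in rows, species in columns; must carry
#'   row and column names.
#' @return the validated matrix with class \code{"community_matrix"}.
#'   Species columns that are all zero are retained and recorded in the
#'   \code{"zero_species"} attribute.
#' @export
community_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("community matrix needs plot row names and species column names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate plot ids: ", paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate species ids: ", paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x)) stop("community matrix contains missing values")
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative abundance at plot '%s', species '%s'",
                 rownames(x)[neg[1, 1]], colnames(x)[neg[1, 2]]))
  if (any(rowSums(x) <= 0))
    stop("plot(s) with no positive abundance: ",
         paste(rownames(x)[rowSums(x) <= 0], collapse = ", "))
  attr(x, "zero_species") <- colnames(x)[colSums(x) == 0]
  class(x) <- c("community_matrix", class(x))
  x
}

#' Read a community matrix from CSV
#'
#' Expects a header row of species ids and a first column of plot ids.
#'
#' @param path CSV file path.
#' @return a validated \code{community_matrix}.
#' @export
read_community <- function(path) {
  df <- utils::read.csv(path, header = TRUE, row.names = 1, check.names = FALSE)
  community_matrix(as.matrix(df))
}

#' Write a community matrix to CSV
#'
#' @param comm community matrix.
#' @param path output path.
#' @export
write_community <- function(comm, path) {
  df <- data.frame(plot = rownames(comm), unclass(comm)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read or validate a plot-to-land-use design table
#'
#' @param x either a CSV path (columns \code{plot}, \code{category}) or a
#'   data frame with those columns.
#' @param categories allowed category levels.
#' @return named factor of categories, names = plot ids.
#' @export
read_design <- function(x, categories = land_use_categories()) {
  df <- if (is.character(x)) utils::read.csv(x, header = TRUE) else as.data.frame(x)
  if (!all(c("plot", "category") %in% names(df)))
    stop("design table needs columns 'plot' and 'category'")
  if (anyDuplicated(df$plot))
    stop("plot assigned more than one category: ",
         paste(unique(df$plot[duplicated(df$plot)]), collapse = ", "))
  bad <- setdiff(unique(df$category), categories)
  if (length(bad) > 0)
    stop("unknown land-use category: ", paste(bad, collapse = ", "))
  structure(factor(df$category, levels = categories), names = as.character(df$plot))
}

#' Land-use category levels
#'
#' Three grazing-pressure degrees plus two abandonment periods (recent:
#' less than 10 years; past: more than 10 years).
#'
#' @return character vector of the five category names.
#' @export
land_use_categories <- function() {
  c("intensive", "intermediate", "extensive",
    "recent_abandonment", "past_abandonment")
}

#' Check that a design covers a community matrix
#'
#' @param comm community matrix.
#' @param design named factor from \code{\link{read_design}}.
#' @return the design, subset and ordered to the plots of \code{comm}.
#' @export
align_design <- function(comm, design) {
  missing <- setdiff(rownames(comm), names(design))
  if (length(missing) > 0)
    stop("plots without land-use category: ", paste(missing, collapse = ", "))
  design[rownames(comm)]
}

#' Optimal cattle load of a pastureland
#'
#' Head count sustainable on an area over one grazing season:
#' \deqn{OL = \frac{SP \cdot A \cdot kUt/100}{I_d \cdot T}}
#' where SP is standardized grass production (kg ss/ha), A the unit area
#' (ha), kUt the utilization coefficient (percent of standing phytomass
#' actually ingested), I_d the daily ingestion per head (kg/day) and T the
#' grazing-season length (days).
#'
#' @param SP standardized grass production, kg ss/ha.
#' @param A unit area, ha.
#' @param kUt utilization coefficient in (0, 100].
#' @param Id daily ingestion per head, kg/day.
#' @param T_days grazing season length, days.
#' @return optimal load (head per area-season), a single number.
#' @export
optimal_cattle_load <- function(SP, A, kUt, Id, T_days) {
  vals <- c(SP = SP, A = A, kUt = kUt, Id = Id, T_days = T_days)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all grazing-load parameters must be strictly positive")
  if (kUt > 100) stop("kUt is a percentage and cannot exceed 100")
  (SP * A * kUt / 100) / (Id * T_days)
}
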