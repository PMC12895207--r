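#' Kruskal-Wallis test across land-use categories
#'
#' Rank-based H statistic with tie correction and chi-square p-value on
#' k - 1 degrees of freedom (wraps \code{stats::kruskal.test}).
#'
#' @param values numeric response.
#' @param groups factor or character grouping.
#' @return list: \code{H}, \code{p_value}, \code{df}.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("group(s) with fewer than 2 observations: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  ht <- stats::kruskal.test(values, groups)
  list(H = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Pairwise Wilcoxon rank-sum tests with adjustment and letters
#'
#' Mann-Whitney/Wilcoxon rank-sum test for every unordered pair of groups.
#' The exact null distribution is used when both groups have at most 10
#' tie-free observations; otherwise the normal approximation with
#' continuity correction. P-values are adjusted (Holm by default) and
#' summarized as a compact letter display at alpha: categories sharing a
#' letter are not significantly different.
#'
#' @param values numeric response.
#' @param groups factor or character grouping.
#' @param adjust p-value adjustment: "holm" (default), "BH" or "none".
#' @param alpha significance level for the letter display.
#' @return list: \code{p_matrix} (symmetric adjusted p-values),
#'   \code{letters} (named character vector per group).
#' @export
pairwise_wilcoxon <- function(values, groups, adjust = c("holm", "BH", "none"),
                              alpha = 0.05) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(length(lev), 2)
  raw <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- values[groups == lev[pairs[1, i]]]
    b <- values[groups == lev[pairs[2, i]]]
    use_exact <- length(a) <= 10 && length(b) <= 10 &&
      !any(duplicated(c(a, b)))
    raw[i] <- suppressWarnings(
      stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)$p.value)
  }
  adj <- stats::p.adjust(raw, method = if (adjust == "BH") "BH" else adjust)
  pm <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  diag(pm) <- 1
  for (i in seq_len(ncol(pairs))) {
    pm[pairs[1, i], pairs[2, i]] <- adj[i]
    pm[pairs[2, i], pairs[1, i]] <- adj[i]
  }
  list(p_matrix = pm, letters = compact_letters(pm, alpha))
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: groups sharing a letter are not
#' significantly different at \code{alpha}; every significant pair is
#' separated by at least one letter.
#'
#' @param p_matrix symmetric matrix of (adjusted) pairwise p-values with
#'   group names as dimnames.
#' @param alpha significance level.
#' @return named character vector of letter strings.
#' @export
compact_letters <- function(p_matrix, alpha = 0.05) {
  g <- rownames(p_matrix)
  k <- length(g)
  # columns of `sets` are candidate letter groups (logical membership)
  sets <- matrix(TRUE, nrow = k, ncol = 1)
  pairs <- utils::combn(k, 2)
  for (idx in seq_len(ncol(pairs))) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    if (is.na(p_matrix[i, j]) || p_matrix[i, j] >= alpha) next
    conflict <- which(sets[i, ] & sets[j, ])
    for (col in conflict) {
      a <- sets[, col]; a[j] <- FALSE
      b <- sets[, col]; b[i] <- FALSE
      sets <- cbind(sets[, -col, drop = FALSE], a, b)
      # absorb columns that are subsets of another
      keep <- rep(TRUE, ncol(sets))
      for (c1 in seq_len(ncol(sets))) {
        for (c2 in seq_len(ncol(sets))) {
          if (c1 != c2 && keep[c1] && keep[c2] &&
              all(sets[, c1] <= sets[, c2]) && any(sets[, c2] & !sets[, c1])) {
            keep[c1] <- FALSE
          } else if (c1 < c2 && keep[c1] && keep[c2] &&
                     all(sets[, c1] == sets[, c2])) {
            keep[c2] <- FALSE
          }
        }
      }
      sets <- sets[, keep, drop = FALSE]
    }
  }
  # order letter groups by first member for stable output
  ord <- order(apply(sets, 2, which.max))
  sets <- sets[, ord, drop = FALSE]
  letters_out <- vapply(seq_len(k), function(i) {
    paste0(letters[which(sets[i, ])], collapse = "")
  }, character(1))
  stats::setNames(letters_out, g)
}

#' Group comparisons for every response column
#'
#' Kruskal-Wallis plus pairwise Wilcoxon with letters, for each response
#' (diversity metric or CWM) against the land-use categories.
#'
#' @param profile data frame with a \code{category} column and numeric
#'   response columns.
#' @param responses names of the response columns.
#' @param adjust pairwise adjustment method.
#' @param alpha significance level for letters.
#' @return list: \code{tests} (data frame response, H, p_value),
#'   \code{letters} (data frame response x category),
#'   \code{pairwise} (named list of adjusted p matrices).
#' @export
group_tests <- function(profile, responses, adjust = "holm", alpha = 0.05) {
  tests <- list(); letter_rows <- list(); pw <- list()
  for (resp in responses) {
    kw <- kruskal_wallis(profile[[resp]], profile$category)
    pq <- pairwise_wilcoxon(profile[[resp]], profile$category, adjust, alpha)
    tests[[resp]] <- data.frame(response = resp, H = kw$H,
                                p_value = kw$p_value, df = kw$df)
    letter_rows[[resp]] <- data.frame(response = resp,
                                      category = names(pq$letters),
                                      letters = unname(pq$letters))
    pw[[resp]] <- pq$p_matrix
  }
  list(tests = do.call(rbind, c(tests, make.row.names = FALSE)),
       letters = do.call(rbind, c(letter_rows, make.row.names = FALSE)),
       pairwise = pw)
}
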