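#' Derive stage seeds from a global seed
#'
#' Deterministically maps (global seed, label) to an integer seed in
#' [1, 2^31 - 2] via a polynomial string hash, so that every pipeline stage
#' is reproducible in isolation from the one user-facing seed.
#'
#' @param seed integer global seed.
#' @param labels character vector of stage labels.
#' @return integer vector of derived seeds, one per label.
#' @export
derive_seed <- function(seed, labels) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  vapply(labels, function(lbl) {
    h <- as.numeric(seed) %% m
    for (code in utf8ToInt(lbl)) {
      h <- (h * 131 + code) %% m
    }
    as.integer(h %% (m - 1)) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

# relative abundances of one community row, restricted to positive species
rel_abund <- function(abund) {
  s <- sum(abund)
  if (s <= 0) stop("community row has no positive abundance")
  abund / s
}
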