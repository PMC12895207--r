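test_that("metric matrix extraction enforces the contract", {
  prof <- data.frame(plot = paste0("p", 1:10),
                     category = rep(c("intensive", "extensive"), each = 5),
                     raoQ = rnorm(10), D = rnorm(10), raoD = rnorm(10))
  M <- metric_matrix(prof, "intensive")
  expect_equal(dim(M), c(5, 3))
  expect_equal(colnames(M), c("D", "raoD", "raoQ"))  # fixed order
  expect_error(metric_matrix(prof, "recent_abandonment"), "no plots")
  prof$raoD[prof$category == "extensive"] <- 1
  expect_error(metric_matrix(prof, "extensive"), "raoD")
  expect_error(metric_matrix(prof[1:5, ][1:3, ], "intensive"), "at least 4")
})

test_that("correlation PCA matches an independent eigendecomposition", {
  set.seed(100)
  # three nearly uncorrelated metrics
  M <- matrix(rnorm(5000 * 3), ncol = 3, dimnames = list(NULL, c("D", "raoD", "raoQ")))
  p <- pca_correlation(M)
  expect_equal(p$eigenvalues, rep(1, 3), tolerance = 0.1)
  expect_equal(sum(p$eigenvalues), 3, tolerance = 1e-10)

  # two collinear metrics plus one independent
  a <- rnorm(2000); b <- rnorm(2000)
  M2 <- cbind(D = a, raoD = 2 * a + 1, raoQ = b)
  p2 <- pca_correlation(M2)
  expect_equal(p2$eigenvalues, c(2, 1, 0), tolerance = 0.1)

  # oracle: correlations via explicit formula, eigenvalues via SVD of the
  # centered/scaled data (an independent route to the same spectrum)
  M3 <- matrix(rnorm(50 * 3), ncol = 3, dimnames = list(NULL, c("D", "raoD", "raoQ")))
  p3 <- pca_correlation(M3)
  Z <- scale(M3)
  lam_svd <- svd(Z)$d^2 / (nrow(Z) - 1)
  expect_equal(p3$eigenvalues, lam_svd, tolerance = 1e-10)
  # r_mk columns satisfy sum_m r^2 = lambda_k, rows satisfy sum_k r^2 = 1
  expect_equal(colSums(p3$correlations^2), p3$eigenvalues,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(rowSums(p3$correlations^2), rep(1, 3),
               tolerance = 1e-10, ignore_attr = TRUE)
  # r_mk is the Pearson correlation between metric and component score
  scores <- Z %*% eigen(cor(M3), symmetric = TRUE)$vectors
  expect_equal(abs(cor(M3, scores)), abs(p3$correlations),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Camargo evenness matches arithmetic and its brute-force form", {
  expect_equal(camargo_evenness(c(2, 2, 2, 2)), 1)
  expect_equal(camargo_evenness(c(1, 0, 0)), 1 / 3)
  expect_equal(camargo_evenness(c(0.6, 0.3, 0.1)),
               1 - (0.3 + 0.5 + 0.2) / 3)
  set.seed(21)
  for (i in 1:20) {
    v <- rexp(sample(3:8, 1))
    q <- v / sum(v); S <- length(q)
    tot <- 0
    for (a in 1:(S - 1)) for (b in (a + 1):S) tot <- tot + abs(q[a] - q[b])
    expect_equal(camargo_evenness(v), 1 - tot / S, tolerance = 1e-12)
  }
  expect_error(camargo_evenness(c(0, 0)), "sum to zero")
})

test_that("eigenvalue evenness separates complementarity from redundancy", {
  expect_equal(evenness_of_eigenvalues(c(1, 1, 1)), 1)
  expect_equal(evenness_of_eigenvalues(c(3, 0, 0)), 1 / 3)

  # perfectly collinear metric profile
  x <- rnorm(100)
  M <- cbind(D = x, raoD = 3 * x + 2, raoQ = -x)
  expect_equal(evenness_of_eigenvalues(pca_correlation(M)$eigenvalues), 1 / 3,
               tolerance = 1e-10)
})

test_that("importance values match the hand loop and sum to 1", {
  set.seed(31)
  for (i in 1:10) {
    M <- matrix(rnorm(40 * 3), ncol = 3, dimnames = list(NULL, c("D", "raoD", "raoQ")))
    p <- pca_correlation(M)
    iv <- importance_values(p$eigenvalues, p$correlations)
    expect_equal(sum(iv), 1, tolerance = 1e-12)
    # hand loop: raw_m = sum_k (lambda_k / sum(lambda)) * r_mk^2
    raw <- numeric(3)
    for (m in 1:3) for (k in 1:3) {
      raw[m] <- raw[m] + (p$eigenvalues[k] / sum(p$eigenvalues)) *
        p$correlations[m, k]^2
    }
    expect_equal(unname(iv), raw / sum(raw), tolerance = 1e-12)

    iv_abs <- importance_values(p$eigenvalues, p$correlations, "abs_r")
    expect_equal(sum(iv_abs), 1, tolerance = 1e-12)
  }

  # mutually uncorrelated metrics share importance equally
  M0 <- matrix(rnorm(20000 * 3), ncol = 3,
               dimnames = list(NULL, c("D", "raoD", "raoQ")))
  p0 <- pca_correlation(M0)
  expect_equal(unname(importance_values(p0$eigenvalues, p0$correlations)),
               rep(1 / 3, 3), tolerance = 0.05)
})

test_that("IV evenness matches the published-style arithmetic", {
  expect_equal(iv_evenness(c(1 / 3, 1 / 3, 1 / 3)), 1)
  expect_equal(iv_evenness(c(1, 0, 0)), 1 / 3)
  expect_equal(iv_evenness(c(0.04, 0.48, 0.48)),
               1 - (0.44 + 0.44 + 0) / 3, tolerance = 1e-12)
  expect_equal(round(iv_evenness(c(0.04, 0.48, 0.48)), 4), 0.7067)
})

test_that("EE and IV evenness are invariant to metric order and affine transforms", {
  set.seed(41)
  M <- matrix(rnorm(60 * 3), ncol = 3, dimnames = list(NULL, c("D", "raoD", "raoQ")))
  ch <- function(M) {
    p <- pca_correlation(M)
    c(EE = evenness_of_eigenvalues(p$eigenvalues),
      ive = iv_evenness(sort(importance_values(p$eigenvalues, p$correlations))))
  }
  base <- ch(M)
  Mt <- cbind(D = 5 - 2 * M[, 1], raoD = M[, 2] / 10, raoQ = M[, 3] + 100)
  expect_equal(ch(Mt), base, tolerance = 1e-10)
  expect_equal(unname(ch(M[, c(3, 1, 2)])[["EE"]]), unname(base[["EE"]]),
               tolerance = 1e-10)
})

test_that("for two metrics EE decreases monotonically with |correlation|", {
  set.seed(51)
  # exactly orthonormal zero-mean pair, so cor(m1, m2) is exactly r
  z <- qr.Q(qr(scale(matrix(rnorm(200 * 2), ncol = 2), scale = FALSE)))
  ee <- sapply(seq(0, 0.95, by = 0.05), function(r) {
    M <- cbind(m1 = z[, 1], m2 = r * z[, 1] + sqrt(1 - r^2) * z[, 2])
    evenness_of_eigenvalues(pca_correlation(M)$eigenvalues)
  })
  expect_true(all(diff(ee) < 1e-10))
  expect_equal(ee[1], 1, tolerance = 1e-8)
})

test_that("the IV-evenness bootstrap is deterministic and brackets the estimate", {
  set.seed(61)
  M <- matrix(rnorm(24 * 3), ncol = 3, dimnames = list(NULL, c("D", "raoD", "raoQ")))
  b0 <- bootstrap_iv_evenness(M, n_boot = 0)
  expect_true(is.na(b0$ci_low))
  b1 <- bootstrap_iv_evenness(M, n_boot = 99, seed = 5)
  b2 <- bootstrap_iv_evenness(M, n_boot = 99, seed = 5)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$ci_high)

  # coverage of the point estimate on neutral simulated studies
  covered <- 0
  for (i in 1:20) {
    tr <- simulate_tree(60, seed = derive_seed(9000 + i, "tree"),
                        depth = 100, n_genera = 12)
    tt <- simulate_traits(tr, 6, 0.1, seed = derive_seed(9000 + i, "traits"))
    cm <- assemble_community(tr, tt,
                             assembly_scenario("neutral", richness = 15), 24,
                             seed = derive_seed(9000 + i, "comm"))
    prof <- diversity_profile(cm, tt, tr)
    Mi <- as.matrix(prof[, c("D", "raoD", "raoQ")])
    b <- bootstrap_iv_evenness(Mi, n_boot = 99, seed = i)
    covered <- covered + (b$point >= b$ci_low && b$point <= b$ci_high)
  }
  expect_gte(covered, 19)
})

test_that("per-category dimensionality table is complete", {
  cfg <- default_study_config(seed = 14)
  cfg$n_species <- 40; cfg$n_genera <- 8
  cfg$plots_per_category <- setNames(rep(6L, 5), land_use_categories())
  cfg$scenarios <- lapply(cfg$scenarios, function(s) { s$richness <- 10; s })
  st <- simulate_study(cfg)
  prof <- diversity_profile(st$comm, st$traits, st$tree, st$design)
  dd <- dimensionality_by_category(prof, n_boot = 49, seed = 9)
  expect_equal(nrow(dd), 5)
  expect_true(all(dd$EE >= 1 / 3 & dd$EE <= 1))
  expect_equal(dd$IV_D + dd$IV_raoD + dd$IV_raoQ, rep(1, 5), tolerance = 1e-10)
  expect_true(all(dd$ci_low <= dd$iv_evenness + 1e-10 &
                  dd$iv_evenness <= dd$ci_high + 1e-10))
})
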