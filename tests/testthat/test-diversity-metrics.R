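test_that("Gini-Simpson diversity matches forced arithmetic", {
  expect_equal(simpson_d(c(sp1 = 5)), 0)
  expect_equal(simpson_d(c(2, 2)), 0.5)
  expect_equal(simpson_d(c(2, 3, 5)), 1 - (0.04 + 0.09 + 0.25))
  expect_equal(simpson_d(c(2, 2), variant = "inverse"), 2)
  expect_error(simpson_d(c(0, 0)), "no positive")
})

test_that("Rao Q matches closed forms and the brute-force double loop", {
  ids <- paste0("sp", 1:4)
  d0 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  expect_equal(rao_q(setNames(rep(1, 4), ids), d0), 0)

  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(ids[1:2], ids[1:2]))
  expect_equal(rao_q(setNames(c(1, 1), ids[1:2]), d2), 0.5 * 3)

  # S equally abundant, equidistant species: Q = d (1 - 1/S)
  for (S in c(3, 5, 8)) {
    sp <- paste0("s", seq_len(S))
    d <- matrix(2.5, S, S, dimnames = list(sp, sp)); diag(d) <- 0
    a <- setNames(rep(1, S), sp)
    expect_equal(rao_q(a, d), 2.5 * (1 - 1 / S))
    expect_equal(rao_q(a, d), rao_brute(rep(1 / S, S), d))
  }

  set.seed(42)
  for (i in 1:20) {
    a <- random_abund(7)
    d <- random_dist(names(a))
    keep <- a > 0
    expect_equal(rao_q(a, d),
                 rao_brute(a[keep], d[keep, keep, drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("Rao Q with the 0/1 distance equals Gini-Simpson exactly", {
  set.seed(8)
  for (i in 1:50) {
    a <- random_abund(10)
    ids <- names(a)
    d01 <- 1 - diag(length(ids)); dimnames(d01) <- list(ids, ids)
    expect_equal(rao_q(a, d01), simpson_d(a), tolerance = 1e-14)
  }
})

test_that("Rao Q is invariant to abundance rescaling and zero-abundance species", {
  set.seed(13)
  a <- random_abund(6, zero_frac = 0)
  d <- random_dist(names(a))
  expect_equal(rao_q(a, d), rao_q(7.3 * a, d), tolerance = 1e-12)
  a2 <- c(a, sp_extra = 0)
  d2 <- random_dist(names(a2))
  d2[names(a), names(a)] <- d
  expect_equal(rao_q(a2, d2), rao_q(a, d), tolerance = 1e-12)
})

test_that("Gower distances match definition bounds and the pairwise-loop oracle", {
  x <- matrix(c(1, 1, 5,
                2, 2, 9), 3, 2,
              dimnames = list(c("a_a", "b_b", "c_c"), c("t1", "t2")))
  d <- functional_distance(trait_table(x))
  expect_equal(d["a_a", "b_b"], 0)          # identical trait rows
  expect_equal(d["a_a", "c_c"], 1)          # opposite extremes of every trait

  set.seed(77)
  x2 <- matrix(rnorm(5 * 4), 5, 4,
               dimnames = list(paste0("s", 1:5), paste0("t", 1:4)))
  d2 <- functional_distance(trait_table(x2))
  expect_equal(unclass(d2)[, ], gower_brute(x2), tolerance = 1e-12)
  expect_true(all(d2 >= 0 & d2 <= 1))

  # Rao on Gower is bounded by 1
  a <- setNames(rexp(5), rownames(x2))
  expect_lte(rao_q(a, d2), 1)

  # zero-range trait excluded with warning
  x3 <- cbind(x2, const = 1)
  expect_warning(d3 <- functional_distance(trait_table(x3)), "zero-range")
  expect_equal(unclass(d3)[, ], unclass(d2)[, ], tolerance = 1e-12)
})

test_that("Gower agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(3)
  x <- matrix(rnorm(8 * 5), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:5)))
  ours <- functional_distance(trait_table(x))
  ref <- as.matrix(vegan::vegdist(x, method = "gower"))
  expect_equal(unclass(ours)[, ], ref[rownames(ours), colnames(ours)],
               tolerance = 1e-10)
})

test_that("CWM matches forced arithmetic and stays in the convex hull", {
  tt <- trait_table(matrix(c(2, 4, 10, 0), 2, 2,
                           dimnames = list(c("a_a", "b_b"), c("t1", "t2"))))
  expect_equal(unname(cwm(c(a_a = 1, b_b = 0), tt)), c(2, 10))
  expect_equal(unname(cwm(c(a_a = 1, b_b = 1), tt)["t1"]), 3)
  expect_equal(unname(cwm(c(a_a = 0.2, b_b = 0.8), tt)["t2"]), 2.0)
  expect_error(cwm(c(a_a = 1, c_c = 1), tt), "lacking traits")

  set.seed(19)
  tt2 <- toy_traits(paste0("s", 1:6), 4)
  for (i in 1:10) {
    a <- random_abund(6)
    names(a) <- rownames(tt2)
    v <- cwm(a, tt2)
    keep <- a > 0
    lo <- apply(unclass(tt2)[keep, , drop = FALSE], 2, min)
    hi <- apply(unclass(tt2)[keep, , drop = FALSE], 2, max)
    expect_true(all(v >= lo - 1e-12 & v <= hi + 1e-12))
  }
})

test_that("phylogenetic Rao agrees with an independent implementation", {
  skip_if_not_installed("picante")
  tr <- simulate_tree(20, seed = 3, depth = 50, n_genera = 4)
  tt <- simulate_traits(tr, 3, 0.5, seed = 4)
  cm <- assemble_community(tr, tt, assembly_scenario("neutral", richness = 8),
                           5, seed = 5)
  ours <- sapply(rownames(cm), function(p) {
    rao_q(cm[p, ], divergence_matrix(tr))
  })
  ref <- picante::raoD(unclass(cm), tr)$Dkk
  expect_equal(ours, ref[names(ours)], tolerance = 1e-10)
})

test_that("Rao over grafted topologies averages per-topology values", {
  tr <- simulate_tree(20, seed = 41, depth = 10, n_genera = 4)
  g <- graft_missing_species(tr, paste0(genus_of(tr$tip.label)[1], "_zz"),
                             n_topologies = 10, seed = 6)
  a <- setNames(rep(0, 21), g$trees[[1]]$tip.label)
  a[g$grafted] <- 1
  a[sample(tr$tip.label, 5)] <- 1

  res <- phylo_rao_over_topologies(a, g)
  hand <- sapply(g$trees, function(t2) rao_q(a, divergence_matrix(t2)))
  expect_equal(res$values, hand)
  expect_equal(res$mean, mean(hand))
  expect_gt(res$sd, 0)

  # a plot with no grafted species is identical across topologies
  a0 <- a; a0[g$grafted] <- 0
  res0 <- phylo_rao_over_topologies(a0, g)
  expect_equal(res0$sd, 0)

  # single topology: mean equals the single value
  res1 <- phylo_rao_over_topologies(a, list(g$trees[[1]]))
  expect_equal(res1$mean, res1$values[1])
})

test_that("the diversity profile is well-formed and order-invariant", {
  cfg <- default_study_config(seed = 10)
  cfg$n_species <- 40; cfg$n_genera <- 8
  cfg$plots_per_category <- setNames(rep(4L, 5), land_use_categories())
  cfg$scenarios <- lapply(cfg$scenarios, function(s) { s$richness <- 10; s })
  st <- simulate_study(cfg)

  prof <- diversity_profile(st$comm, st$traits, st$tree, st$design)
  expect_equal(nrow(prof), 20)
  expect_true(all(is.finite(as.matrix(prof[, -(1:2)]))))
  expect_true(all(prof$D >= 0 & prof$D < 1))
  expect_true(all(prof$raoQ >= 0 & prof$raoQ <= 1))
  expect_true(all(prof$raoD >= 0))
  expect_equal(sum(startsWith(names(prof), "cwm_")), 6)

  perm <- sample(nrow(st$comm))
  prof2 <- diversity_profile(community_matrix(unclass(st$comm)[perm, ]),
                             st$traits, st$tree, st$design)
  expect_equal(prof2[match(prof$plot, prof2$plot), ], prof,
               ignore_attr = TRUE)
})
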