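test_that("betaMPD and Bray-Curtis match hand calculations and brute force", {
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(beta_mpd(c(1, 0), c(1, 0), d2), 0)
  expect_equal(beta_mpd(c(1, 0), c(0, 1), d2), 0.3)
  dAB2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(beta_mpd(c(0.5, 0.5), c(0.5, 0.5), dAB2), 1.0)
  expect_true(is.na(beta_mpd(c(0, 0), c(1, 0), d2)))

  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(1, 3), c(3, 1)), 0.5)

  # brute-force double-loop oracle on random 10-taxon bins
  set.seed(5)
  for (i in 1:5) {
    n <- 10
    d <- as.matrix(stats::dist(matrix(runif(n * 2), n)))
    u <- runif(n); v <- runif(n)
    brute <- 0; den <- 0
    for (a in 1:n) for (b in 1:n) {
      brute <- brute + u[a] * v[b] * d[a, b]
      den <- den + u[a] * v[b]
    }
    expect_equal(beta_mpd(u, v, d), brute / den, tolerance = 1e-12)
    expect_equal(bray_curtis(u, v), sum(abs(u - v)) / sum(u + v),
                 tolerance = 1e-12)
  }

  # invariance to uniform rescaling of abundance vectors
  u <- c(1, 2, 3, 4); v <- c(4, 3, 2, 1)
  d4 <- as.matrix(stats::dist(matrix(1:8, 4)))
  expect_equal(beta_mpd(u * 7, v * 3, d4), beta_mpd(u, v, d4))
  expect_equal(bray_curtis(u * 5, v * 5), bray_curtis(u, v))
})

test_that("betaMPD agrees with picante's abundance-weighted comdist", {
  tr <- simulate_tree(12, seed = 2, death = 0.5)
  tab <- random_table(tr, n_samples = 3, seed = 3)
  d <- cophenetic_distances(tr)
  rel <- sweep(unclass(tab), 2, colSums(tab), "/")
  pc <- as.matrix(picante::comdist(t(unclass(tab)), d, abundance.weighted = TRUE))
  for (u in 1:2) for (v in (u + 1):3) {
    expect_equal(beta_mpd(rel[, u], rel[, v], d), pc[u, v], tolerance = 1e-9)
  }
})

test_that("taxa shuffle preserves the distance multiset and explores all permutations", {
  tr <- simulate_tree(4, seed = 1, death = 0)
  d <- cophenetic_distances(tr)
  perm_d <- taxa_shuffle(d, scope = "across_all", seed = 3)
  expect_equal(sort(perm_d[upper.tri(perm_d)]), sort(d[upper.tri(d)]))
  expect_identical(dimnames(perm_d), dimnames(d))

  # all 24 permutations of 4 taxa appear over many seeds
  seen <- character(0)
  set.seed(10)
  for (i in 1:1000) {
    p <- asmbin:::shuffle_indices(4, NULL, "across_all")
    seen <- union(seen, paste(p, collapse = ""))
  }
  expect_equal(length(seen), 24)

  # within-bin scope never moves a taxon across bins
  bins <- asmbin:::new_binset(rep(1:2, each = 2), rownames(d),
                              rep(TRUE, 2), rep(NA, 2), "manual")
  for (i in 1:20) {
    p <- asmbin:::shuffle_indices(4, bins, "within_bin")
    expect_true(all(p[1:2] %in% 1:2) && all(p[3:4] %in% 3:4))
  }
})

test_that("taxonomic null preserves richness, totals, and tracks occupancy", {
  tr <- simulate_tree(20, seed = 4, death = 0.9)
  tab <- random_table(tr, n_samples = 5, seed = 6)
  m <- unclass(tab)
  m[sample(length(m), 40)] <- 0
  m[, colSums(m) == 0] <- 1
  tab <- community_table(m)
  for (s in 1:3) {
    nul <- taxonomic_null(tab, seed = s)
    expect_equal(colSums(nul > 0), colSums(tab > 0))
    expect_equal(colSums(nul), colSums(tab))
  }

  # a taxon occurring everywhere is drawn almost always at high richness
  m2 <- matrix(rpois(10 * 6, 3) + 1, 10,
               dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  m2[1, ] <- 50                      # ubiquitous and abundant
  m2[8:10, 2:6] <- 0                 # rare taxa
  t2 <- community_table(m2)
  hit <- mean(vapply(1:200, function(s)
    unclass(taxonomic_null(t2, seed = s))[1, 1] > 0, logical(1)))
  expect_gt(hit, 0.9)
})

test_that("betaNRI, RC and the direct test follow their definitions", {
  ens <- null_ensemble("betaMPD", observed = 5, nulls = c(1, 2, 3, 4, 5))
  expect_equal(beta_nri(ens), (5 - 3) / stats::sd(1:5))
  ens2 <- null_ensemble("betaMPD", observed = 3, nulls = rep(3, 10))
  expect_warning(z <- beta_nri(ens2), "zero variance")
  expect_equal(z, 0)
  ens3 <- null_ensemble("x", observed = 2, nulls = c(0, 2, 4, 6))
  expect_equal(beta_nri(ens3), (2 - 3) / stats::sd(c(0, 2, 4, 6)))

  # RC: all below -> 1; all above -> -1; 475/50/475 at N_r = 1000 -> 0
  expect_equal(rc_metric(null_ensemble("BC", 10, rep(1, 1000))), 1)
  expect_equal(rc_metric(null_ensemble("BC", 0, rep(1, 1000))), -1)
  nulls <- c(rep(0, 475), rep(0.5, 50), rep(1, 475))
  expect_equal(rc_metric(null_ensemble("BC", 0.5, nulls)), 0)
  # tie detection is robust to 1e-12 jitter
  expect_equal(rc_metric(null_ensemble("BC", 0.5, nulls + 1e-12)), 0)

  set.seed(8)
  nul <- rnorm(1000)
  expect_equal(direct_significance(null_ensemble("x", 10, nul)), "high")
  expect_equal(direct_significance(null_ensemble("x", -10, nul)), "low")
  expect_equal(direct_significance(null_ensemble("x", median(nul), nul)), "ns")
  expect_warning(direct_significance(null_ensemble("x", 0, rnorm(10))),
                 "too few")

  # on Gaussian ensembles the direct test matches the 1.96-threshold rule
  agree <- 0
  for (i in 1:400) {
    nul <- rnorm(400)
    obs <- rnorm(1, sd = 2)
    ses <- (obs - mean(nul)) / sd(nul)
    cls <- if (ses > 1.96) "high" else if (ses < -1.96) "low" else "ns"
    agree <- agree + (direct_significance(null_ensemble("x", obs, nul)) == cls)
  }
  expect_gt(agree / 400, 0.95)
})

test_that("betaNRI is ~N(0,1) and RC ~U(-1,1) when the observation comes from the null", {
  # observations generated by the same shuffle / taxonomic-null process
  set.seed(21)
  tr <- simulate_tree(30, seed = 12, death = 0.9)
  d <- cophenetic_distances(tr)
  tab <- random_table(tr, n_samples = 2, seed = 13)
  rel <- sweep(unclass(tab), 2, colSums(tab), "/")

  bnri_vals <- replicate(500, {
    vals <- vapply(1:60, function(i) {
      p <- sample.int(30)
      beta_mpd(rel[p, 1], rel[p, 2], d)
    }, numeric(1))
    (vals[1] - mean(vals[-1])) / stats::sd(vals[-1])
  })
  expect_lt(abs(mean(bnri_vals)), 0.1)
  expect_gt(stats::sd(bnri_vals), 0.8)
  expect_lt(stats::sd(bnri_vals), 1.2)

  m6 <- community_table(matrix(rpois(8 * 4, 6) + 1, 8,
    dimnames = list(paste0("t", 1:8), paste0("s", 1:4))))
  rc_vals <- replicate(500, {
    obs <- taxonomic_null(m6)
    bc_obs <- bray_curtis(unclass(obs)[, 1], unclass(obs)[, 2])
    nulls <- vapply(1:60, function(i) {
      nl <- taxonomic_null(m6)
      bray_curtis(unclass(nl)[, 1], unclass(nl)[, 2])
    }, numeric(1))
    rc_metric(null_ensemble("BC", bc_obs, nulls))
  })
  ks <- suppressWarnings(stats::ks.test(rc_vals, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("the vectorised pair-bin engine matches the scalar operations", {
  tr <- simulate_tree(24, seed = 9, death = 0.9)
  tab <- random_table(tr, n_samples = 4, seed = 10)
  d <- cophenetic_distances(tr)
  bins <- bin_by_tree(tr, ds = 0.4, nmin = 6, dist = d)
  met <- asmbin:::icamp_pair_bin_metrics(tab, d, bins, n_rand = 50, seed = 3)
  rel <- sweep(unclass(tab), 2, colSums(tab), "/")
  for (r in sample(nrow(met), 6)) {
    row <- met[r, ]
    idx <- which(bins$bin_id == row$bin)
    if (!row$two_sided) next
    expect_equal(row$bmpd,
                 beta_mpd(rel[idx, row$sample_u], rel[idx, row$sample_v],
                          d[idx, idx]), tolerance = 1e-9)
    expect_equal(row$bc,
                 round(bray_curtis(rel[idx, row$sample_u],
                                   rel[idx, row$sample_v]), 9),
                 tolerance = 1e-9)
  }
  # reproducibility with the same seed
  met2 <- asmbin:::icamp_pair_bin_metrics(tab, d, bins, n_rand = 50, seed = 3)
  expect_identical(met, met2)
})
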