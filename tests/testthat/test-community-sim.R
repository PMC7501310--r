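# reduced preset used throughout: keeps simulation tests fast while
# preserving the full design (4 plots x 6 replicates, 2 islands)
small_preset <- function() {
  pre <- sim_preset("desk")
  pre$n_tips <- 150
  pre$local_size <- 600
  pre$richness <- 40
  pre$J <- 5e4
  pre$theta <- 100
  pre
}

test_that("simulated trees have the requested size, unit depth and reproducibility", {
  tr <- simulate_tree(80, seed = 3)
  expect_equal(length(tr$tip.label), 80)
  depths <- ape::node.depth.edgelength(tr)[1:80]
  expect_equal(max(depths), 1)
  expect_true(all(abs(depths - 1) < 1e-8))   # ultrametric
  expect_identical(ape::write.tree(simulate_tree(80, seed = 3)),
                   ape::write.tree(tr))
})

test_that("Blomberg's K matches picante and behaves as a signal statistic", {
  tr <- simulate_tree(60, seed = 5, death = 0.5)
  set.seed(6); x <- phytools::fastBM(tr, a = 0, sig2 = 1)
  expect_equal(blomberg_k(tr, x), as.numeric(picante::Kcalc(x[tr$tip.label], tr)),
               tolerance = 1e-8)
  # affine invariance
  expect_equal(blomberg_k(tr, 3 * x + 7), blomberg_k(tr, x), tolerance = 1e-10)
  # Brownian traits give K near 1 on average
  ks <- vapply(1:30, function(i) {
    set.seed(100 + i)
    blomberg_k(tr, phytools::fastBM(tr, a = 0, sig2 = 1))
  }, numeric(1))
  expect_gt(mean(ks), 0.8)
  expect_lt(mean(ks), 1.3)
  # white noise on the same tree carries little signal
  kw <- vapply(1:20, function(i) {
    set.seed(200 + i)
    blomberg_k(tr, stats::setNames(rnorm(60), tr$tip.label))
  }, numeric(1))
  expect_lt(mean(kw), 0.5)
  expect_error(blomberg_k(tr, stats::setNames(rep(1, 60), tr$tip.label)),
               "constant")
})

test_that("trait scenarios reach their phylogenetic-signal targets", {
  tr <- simulate_tree(150, seed = 7)
  for (scen in c("LPS", "MPS", "HPS")) {
    st <- simulate_trait(tr, scen, seed = 8)
    target <- c(LPS = 0.15, MPS = 0.9, HPS = 5.5)[[scen]]
    expect_gte(st$K, 0.5 * target)
    expect_lte(st$K, 1.5 * target)
    expect_true(all(st$trait >= 0 & st$trait <= 1))
  }
  kl <- simulate_trait(tr, "LPS", seed = 9)$K
  kh <- simulate_trait(tr, "HPS", seed = 9)$K
  expect_gt(kh, kl)
})

test_that("the metacommunity sampler yields normalised, seeded, theta-sensitive abundances", {
  m <- mzsm_metacommunity(200, J = 5e4, theta = 100, seed = 4)
  expect_equal(sum(m), 1)
  expect_true(all(m > 0))
  expect_identical(mzsm_metacommunity(200, 5e4, 100, seed = 4), m)

  shannon_even <- function(p) -sum(p * log(p)) / log(length(p))
  ev <- vapply(c(50, 500, 5000), function(th) {
    mean(vapply(1:20, function(s)
      shannon_even(mzsm_metacommunity(200, 2e5, th, seed = s)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ev) > 0))   # larger theta -> more even
})

test_that("species-type assignment matches the mix and propagates within ds", {
  pre <- small_preset()
  tr <- simulate_tree(pre$n_tips, seed = 11)
  d <- cophenetic_distances(tr)
  meta <- stats::setNames(mzsm_metacommunity(pre$n_tips, pre$J, pre$theta,
                                             seed = 12), tr$tip.label)
  mix <- c(selection = 0.5, dispersal = 0.25, drift = 0.25)
  types <- assign_species_types(meta, d, mix, ds = 0.2, seed = 13)
  realized <- vapply(c("selection", "dispersal", "drift"), function(tau)
    sum(meta[types == tau]), numeric(1))
  expect_lt(abs(realized[["selection"]] - 0.5), 0.021)
  expect_lt(abs(realized[["dispersal"]] - 0.25), 0.021)

  # relatives within ds share the type (drift is the unassigned remainder)
  for (tau in c("selection", "dispersal")) {
    sp <- names(types)[types == tau]
    other <- names(types)[!types %in% c(tau, "drift")]
    if (length(sp) && length(other))
      expect_gte(min(d[sp, other]), 0)  # disjoint clusters exist by design
  }
  expect_equal(unname(assign_species_types(meta, d,
    c(selection = 1, dispersal = 0, drift = 0), ds = 0.2, seed = 1)[1]),
    "selection")
})

test_that("Gaussian selection weights reproduce the stated ratios", {
  w <- selection_abundances(0.5, c(0.5, 0.5 - 0.015, 0.5 - 3 * 0.015),
                            sigma_E = 0.015)
  expect_equal(w[2] / w[1], exp(-0.5), tolerance = 1e-12)
  expect_equal(w[3] / w[1], exp(-4.5), tolerance = 1e-12)
  expect_equal(which.max(w), 1)
  expect_equal(sum(w), 1)
  # far from the optimum the weights underflow gracefully
  w2 <- selection_abundances(0.05, c(0.05, 0.95), sigma_E = 0.015)
  expect_equal(w2[1], 1)
})

test_that("competition ranking follows the niche-difference recursion", {
  # prior competitors E = (0.2, 0.8); candidate 0.5 scores sqrt(0.0675)
  nd <- sqrt(0.5 * (0.5 - 0.2)^2 + 0.25 * (0.5 - 0.8)^2)
  expect_equal(nd, 0.2598, tolerance = 1e-4)

  E <- c(a = 0.50, b = 0.20, c = 0.80, d = 0.51)
  cr <- competition_ranking(0.5, E, seed = 1, top = 1)
  expect_equal(cr$species[1], "a")                # best fitness seeds rank 1
  expect_equal(cr$species[2], "c")                # |0.8-0.5| > others
  expect_equal(cr$abundance, (0.5^(1:4)) / sum(0.5^(1:4)))

  # farther trait wins the next rank
  E2 <- c(x = 0.5, y = 0.6, z = 0.1)
  cr2 <- competition_ranking(0.5, E2, seed = 2, top = 1)
  expect_equal(cr2$species[2], "z")
})

test_that("dispersal communities respect island structure", {
  pre <- small_preset()
  tr <- simulate_tree(pre$n_tips, seed = 14)
  meta <- stats::setNames(mzsm_metacommunity(pre$n_tips, pre$J, pre$theta,
                                             seed = 15), tr$tip.label)
  islands <- rep(c("A", "B"), each = 6)
  dc <- dispersal_communities(meta, islands, local_size = 500, richness = 30,
                              seed = 16)
  expect_true(all(colSums(dc) == 500))
  expect_true(all(colSums(dc > 0) == 30))

  jac <- function(a, b) sum(a > 0 & b > 0) / sum(a > 0 | b > 0)
  within_j <- mean(c(jac(dc[, 1], dc[, 2]), jac(dc[, 7], dc[, 8])))
  between_j <- mean(c(jac(dc[, 1], dc[, 7]), jac(dc[, 2], dc[, 8])))
  expect_gt(within_j, between_j)
  # between-island overlap is limited to the metacommunity leak (~m1)
  expect_lt(between_j, 0.25)
})

test_that("drift communities track the metacommunity in expectation", {
  pre <- small_preset()
  tr <- simulate_tree(pre$n_tips, seed = 17)
  meta <- stats::setNames(mzsm_metacommunity(pre$n_tips, pre$J, pre$theta,
                                             seed = 18), tr$tip.label)
  dcm <- drift_communities(meta, n_locals = 50, local_size = 500,
                           richness = 40, seed = 19)
  expect_true(all(colSums(dcm) == 500))
  expect_true(all(colSums(dcm > 0) == 40))
  top <- order(-meta)[1:10]
  obs <- rowMeans(sweep(dcm, 2, colSums(dcm), "/"))[top]
  expect_gt(stats::cor(obs, meta[top]), 0.7)
  expect_identical(drift_communities(meta, 3, local_size = 500, richness = 40,
                                     seed = 20),
                   drift_communities(meta, 3, local_size = 500, richness = 40,
                                     seed = 20))
})

test_that("simulated datasets meet the design constraints and truth sums to one", {
  pre <- small_preset()
  tr <- simulate_tree(pre$n_tips, seed = 21)
  st <- simulate_trait(tr, "MPS", seed = 22)
  mix <- c(selection = 0.5, dispersal = 0.25, drift = 0.25)
  ds <- simulate_dataset(tr, st$trait, mix, preset = pre, seed = 23)
  expect_equal(ncol(ds$table), 24)
  expect_true(all(colSums(ds$table) == pre$local_size))
  expect_true(all(colSums(unclass(ds$table) > 0) == pre$richness))
  expect_equal(sort(unique(unname(ds$plots))), c("HA", "HB", "LA", "LB"))

  ep <- ds$expected
  expect_equal(rowSums(ep[, c("HeS", "HoS", "DL", "HD", "DR")]),
               rep(1, nrow(ep)), tolerance = 1e-9, ignore_attr = TRUE)
  # within-environment pairs expect HoS, across-environment HeS
  same_env <- ds$env[ep$sample_u] == ds$env[ep$sample_v]
  expect_true(all(ep$HeS[same_env] == 0))
  expect_true(all(ep$HoS[!same_env] == 0))

  # all-drift dataset: expected drift importance is 1 everywhere
  dd <- simulate_dataset(tr, st$trait,
                         c(selection = 0, dispersal = 0, drift = 1),
                         preset = pre, seed = 29)
  expect_true(all(abs(dd$expected$DR - 1) < 1e-9))

  # replicate communities within a plot share the selection component
  sel_sp <- names(ds$types)[ds$types == "selection"]
  la <- names(ds$plots)[ds$plots == "LA"]
  expect_true(all(unclass(ds$table)[sel_sp, la[1]] ==
                    unclass(ds$table)[sel_sp, la[2]]))
})

test_that("the benchmark enumerates all fifteen situations", {
  mixes <- situation_mixes()
  expect_equal(nrow(mixes), 15)
  expect_equal(nrow(unique(mixes[, 2:4])), 15)
  expect_equal(rowSums(mixes[, 2:4]), rep(1, 15), ignore_attr = TRUE)
  pure <- mixes[mixes$selection == 1 | mixes$dispersal == 1 |
                  mixes$drift == 1, ]
  expect_equal(nrow(pure), 3)
  expect_true(all(unlist(mixes[, 2:4]) %in% seq(0, 1, 0.25)))
})
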