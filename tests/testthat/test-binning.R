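brute_force_radius_ok <- function(bins, dist, ds) {
  all(vapply(seq_along(bins$taxa), function(k) {
    if (!bins$strict[k]) return(TRUE)
    cent <- bins$centroid[k]
    if (is.na(cent)) return(TRUE)
    all(dist[cent, bins$taxa[[k]]] < ds)
  }, logical(1)))
}

brute_force_pairwise_ok <- function(bins, dist, ds) {
  all(vapply(seq_along(bins$taxa), function(k) {
    if (!bins$strict[k]) return(TRUE)
    tx <- bins$taxa[[k]]
    length(tx) == 1 || max(dist[tx, tx]) < ds
  }, logical(1)))
}

test_that("cophenetic distances equal hand-computed path sums", {
  d <- cophenetic_distances(toy_tree())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_true(all(diag(d) == 0))
  expect_identical(d, t(d))
})

test_that("centroid binning honours the radius criterion and resolves the two-clade toy", {
  tr <- two_clade_tree(within = 0.05, between = 1.0)
  d <- cophenetic_distances(tr)
  mra <- stats::setNames(rep(1 / 20, 20), tr$tip.label)
  bins <- bin_by_centroid(d, mra, ds = 0.2, nmin = 3)
  expect_equal(length(bins$taxa), 2)
  expect_setequal(bins$taxa[[which(vapply(bins$taxa, function(x)
    "a1" %in% x, logical(1)))]], paste0("a", 1:10))
  expect_true(brute_force_radius_ok(bins, d, 0.2))

  # star: everything within radius forms one bin
  star <- two_clade_tree(within = 0.1, between = 0.0)
  dstar <- cophenetic_distances(star)
  b1 <- bin_by_centroid(dstar, stats::setNames(rep(1, 20), star$tip.label),
                        ds = 0.2, nmin = 2)
  expect_equal(length(b1$taxa), 1)

  # abundance ties broken lexicographically: deterministic repeat
  b2 <- bin_by_centroid(d, mra, ds = 0.2, nmin = 3)
  expect_identical(bins$bin_id, b2$bin_id)
  expect_error(bin_by_centroid(d, mra, ds = -1, nmin = 3), "ds")
})

test_that("pairwise binning builds maximal greedy cliques", {
  tr <- two_clade_tree(within = 0.05, between = 1.0)
  d <- cophenetic_distances(tr)
  mra <- stats::setNames(rep(1 / 20, 20), tr$tip.label)
  bins <- bin_by_pairwise(d, mra, ds = 0.2, nmin = 3)
  expect_equal(length(bins$taxa), 2)
  expect_true(brute_force_pairwise_ok(bins, d, 0.2))

  # chain A-B=0.15, B-C=0.15, A-C=0.3: greedy from A takes B, leaves C
  dch <- matrix(c(0, .15, .3, .15, 0, .15, .3, .15, 0), 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  bch <- bin_by_pairwise(dch, c(A = .5, B = .3, C = .2), ds = 0.2, nmin = 1)
  expect_equal(sort(bch$taxa[[1]]), c("A", "B"))
  expect_equal(bch$taxa[[2]], "C")

  single <- matrix(0, 1, 1, dimnames = list("A", "A"))
  expect_equal(length(bin_by_pairwise(single, c(A = 1), 0.2, 1)$taxa), 1)
})

test_that("tree binning truncates at the shallowest sufficient depth", {
  tr <- two_clade_tree(within = 0.1, between = 1.0)
  bins <- bin_by_tree(tr, ds = 0.2, nmin = 3)
  expect_equal(length(bins$taxa), 2)
  d <- cophenetic_distances(tr)
  expect_true(all(vapply(bins$taxa, function(tx) max(d[tx, tx]) < 0.2,
                         logical(1))))

  # threshold above the tree diameter: a single bin
  b1 <- bin_by_tree(tr, ds = 10, nmin = 3)
  expect_equal(length(b1$taxa), 1)

  # caterpillar tree: strict bins satisfy the pairwise criterion brute-force
  cat_tr <- ape::read.tree(
    text = "((((A:0.05,B:0.05):0.2,C:0.25):0.2,D:0.45):0.2,E:0.65);")
  bc <- bin_by_tree(cat_tr, ds = 0.15, nmin = 1)
  dc <- cophenetic_distances(cat_tr)
  expect_true(all(vapply(bc$taxa, function(tx)
    length(tx) == 1 || max(dc[tx, tx]) < 0.15, logical(1))))
})

test_that("small-bin merging terminates, respects nmin, and follows nearest neighbours", {
  tr <- two_clade_tree(within = 0.05, between = 1.0)
  d <- cophenetic_distances(tr)
  mra <- stats::setNames(rep(1 / 20, 20), tr$tip.label)
  big <- bin_by_centroid(d, mra, ds = 0.2, nmin = 3)
  expect_identical(merge_small_bins(big, d, 3)$bin_id, big$bin_id)

  # 3 bins sized (2, 5, 5); bin 1 nearer bin 2 -> sizes become (7, 5)
  n <- 12
  dm <- matrix(1, n, n); diag(dm) <- 0
  ids <- paste0("t", seq_len(n))
  dimnames(dm) <- list(ids, ids)
  g1 <- 1:2; g2 <- 3:7; g3 <- 8:12
  dm[g1, g2] <- dm[g2, g1] <- 0.1
  dm[g1, g1] <- 0.01; diag(dm) <- 0
  dm[g2, g2] <- 0.01; diag(dm) <- 0
  dm[g3, g3] <- 0.01; diag(dm) <- 0
  strict <- asmbin:::new_binset(rep(1:3, c(2, 5, 5)), ids,
                                rep(TRUE, 3), rep(NA, 3), "manual")
  merged <- merge_small_bins(strict, dm, nmin = 3)
  expect_equal(unname(sort(lengths(merged$taxa))), c(5, 7))
  expect_true(all(ids[g1] %in%
    merged$taxa[[which(vapply(merged$taxa, function(x) ids[3] %in% x,
                              logical(1)))]]))
  expect_false(all(merged$strict))

  expect_warning(fb <- merge_small_bins(strict, dm, nmin = 50), "single bin")
  expect_equal(length(fb$taxa), 1)
})

test_that("bins always partition the taxon set", {
  set.seed(31)
  for (rep in 1:5) {
    tr <- simulate_tree(60, seed = rep, death = 0.9)
    d <- cophenetic_distances(tr)
    mra <- stats::setNames(runif(60), tr$tip.label)
    for (bins in list(bin_by_centroid(d, mra, 0.3, 5),
                      bin_by_pairwise(d, mra, 0.3, 5),
                      bin_by_tree(tr, 0.3, 5, dist = d))) {
      expect_equal(sum(lengths(bins$taxa)), 60)
      expect_setequal(unlist(bins$taxa), tr$tip.label)
      expect_true(all(lengths(bins$taxa) >= 5))
    }
  }
})

test_that("niche values reproduce the worked temperature example", {
  # relative abundances 10%, 20%, 10% at 10, 20, 30 degrees -> 20 degrees
  m <- matrix(c(0.10, 0.90, 0.20, 0.80, 0.10, 0.90) * 10, nrow = 2,
              dimnames = list(c("OTU1", "other"), c("s1", "s2", "s3")))
  tab <- community_table(m)
  env <- cbind(temperature = c(s1 = 10, s2 = 20, s3 = 30))
  v <- niche_values(tab, env)
  expect_equal(v["OTU1", "temperature"], 20)

  # taxon present in a single sample takes that sample's value
  m2 <- community_table(matrix(c(1, 1, 0, 2), 2,
    dimnames = list(c("x", "y"), c("s1", "s2"))))
  v2 <- niche_values(m2, cbind(f = c(s1 = 5, s2 = 9)))
  expect_equal(v2["x", "f"], 5)

  # constant factor: every niche value equals the constant
  v3 <- niche_values(tab, cbind(f = c(s1 = 3, s2 = 3, s3 = 3)))
  expect_true(all(abs(v3 - 3) < 1e-12))
})

test_that("within-bin phylogenetic signal detects and calibrates", {
  # points on a line: niche differences equal distances exactly -> R = 1
  x <- stats::setNames(as.numeric(1:8), paste0("t", 1:8))
  dline <- abs(outer(x, x, "-"))
  bins <- asmbin:::new_binset(rep(1L, 8), names(x), TRUE, NA, "manual")
  rep1 <- bin_phylo_signal(bins, dline, cbind(f = x),
                           permutations = 199, seed = 4)
  expect_equal(rep1$R[1], 1)
  expect_lte(rep1$p[1], 1 / 200 + 1e-12)
  expect_true(rep1$significant[1])

  # degenerate all-equal distances are flagged not significant
  dd <- matrix(0.1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dd) <- 0
  b1 <- asmbin:::new_binset(rep(1L, 4), letters[1:4], TRUE, NA, "manual")
  rep2 <- bin_phylo_signal(b1, dd, cbind(f = stats::setNames(1:4, letters[1:4])),
                           permutations = 99, seed = 1)
  expect_false(any(rep2$significant))

  # null calibration: shuffled niche values are significant ~5% of the time
  set.seed(9)
  hits <- 0; nrep <- 120
  dbig <- cophenetic_distances(simulate_tree(12, seed = 3, death = 0.5))
  bb <- asmbin:::new_binset(rep(1L, 12), rownames(dbig), TRUE, NA, "manual")
  for (i in seq_len(nrep)) {
    nv <- cbind(f = stats::setNames(rnorm(12), rownames(dbig)))
    r <- bin_phylo_signal(bb, dbig, nv, permutations = 99, seed = i)
    hits <- hits + as.integer(isTRUE(r$significant[1]))
  }
  expect_lt(hits / nrep, 0.15)
})

test_that("nmin optimization follows count, mean R, then size", {
  tab <- data.frame(nmin = c(6, 12, 24), n_significant = c(10, 10, 7),
                    mean_R = c(0.3, 0.4, 0.9))
  ord <- order(-tab$n_significant, -tab$mean_R, tab$nmin)
  expect_equal(tab$nmin[ord[1]], 12)

  tr <- two_clade_tree(within = 0.1, between = 1, n_each = 6)
  d <- cophenetic_distances(tr)
  niche <- cbind(f = stats::setNames(seq_len(12) / 12, tr$tip.label))
  res <- optimize_nmin(c(3), tree = tr, dist = d, ds = 0.2, niche = niche,
                       permutations = 49, seed = 2)
  expect_equal(res$nmin, 3)
  expect_equal(nrow(res$table), 1)
})
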