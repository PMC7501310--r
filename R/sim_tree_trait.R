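#' Simulate a regional-pool phylogeny
#'
#' A birth-death tree with the requested number of tips, branch lengths
#' rescaled so the root-to-tip depth is 1. The default high relative
#' extinction (death = 0.98 x birth) mimics a pool at speciation-extinction
#' equilibrium: coalescences concentrate near the present, producing the
#' compact crown clades (tens of close relatives) that phylogenetic binning
#' relies on, as in real marker-gene trees. With unit depth the
#' phylogenetic signal threshold `ds` is directly interpretable as a
#' fraction of total depth.
#'
#' @param n_tips Number of species (default 1140).
#' @param seed Integer seed.
#' @param death Extinction rate relative to a birth rate of 1 (default
#'   0.95).
#' @return An ultrametric `phylo` with tips `t1..tN` and depth 1.
#' @export
simulate_tree <- function(n_tips = 1140, seed = 1, death = 0.98) {
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_tips, birth = 1, death = death)
  depth <- max(node_depths_from_root(tr)[seq_len(n_tips)])
  tr$edge.length <- tr$edge.length / depth
  tr
}

# precomputed pieces for repeated Blomberg K evaluation on one tree
k_stat_precompute <- function(tree) {
  V <- ape::vcv.phylo(tree)
  Vinv <- solve(V)
  n <- nrow(V)
  list(n = n, trV = sum(diag(V)), rsum = rowSums(Vinv),
       ssum = sum(Vinv), Vinv = Vinv, tips = rownames(V))
}

k_stat <- function(pre, x) {
  x <- x[pre$tips]
  ahat <- sum(pre$rsum * x) / pre$ssum
  d <- x - ahat
  mse0 <- sum(d^2)
  mse <- as.numeric(d %*% pre$Vinv %*% d)
  expected_ratio <- (pre$trV - pre$n / pre$ssum) / (pre$n - 1)
  (mse0 / mse) / expected_ratio
}

#' Blomberg's K phylogenetic signal statistic
#'
#' Ratio of the observed mean squared error of the trait (about the
#' phylogenetically corrected mean) to the error under the tree's
#' variance-covariance structure, standardised by its Brownian-motion
#' expectation. K near 1 matches Brownian evolution; K >> 1 indicates
#' stronger-than-Brownian conservatism and K near 0 phylogenetic
#' independence. Invariant to affine transforms of the trait.
#'
#' @param tree A `phylo`.
#' @param trait Named numeric vector over the tips.
#' @return Blomberg's K.
#' @export
blomberg_k <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait must be named by tip label")
  if (stats::sd(trait) == 0) stop("constant trait: K undefined")
  k_stat(k_stat_precompute(tree), trait)
}

# early-burst branch-length transform: relative evolutionary rate
# r(t) = g^((T - t)/T), so the rate declines by a factor g from root to tips;
# Brownian motion on the transformed tree yields a high-K trait
acdc_rescale <- function(tree, g) {
  depth <- node_depths_from_root(tree)
  Tmax <- max(depth)
  t0 <- depth[tree$edge[, 1]] / Tmax
  t1 <- depth[tree$edge[, 2]] / Tmax
  lg <- log(g)
  new_len <- Tmax * (g^(1 - t0) - g^(1 - t1)) / lg
  tr2 <- tree
  tr2$edge.length <- new_len
  tr2
}

rescale01 <- function(x) (x - min(x)) / (max(x) - min(x))

#' Simulate a niche-optimum trait with a target phylogenetic signal
#'
#' The trait E_i in `[0, 1]` is each species' optimal environment. Three
#' scenarios are supported: `"MPS"` (medium signal, bounded Brownian motion
#' with ancestral state 0.5 and rate 0.25, target K = 0.9), `"HPS"` (high
#' signal, Brownian motion on an early-burst rescaled tree with rate factor
#' g = 2000, target K = 5.5), and `"LPS"` (low signal, Brownian motion plus
#' independent noise whose variance is tuned by bisection, target K = 0.15).
#' Simulation is retried until the achieved K falls within +-50% of the
#' target (at most `max_attempts` tries).
#'
#' @param tree A `phylo`.
#' @param scenario `"LPS"`, `"MPS"`, or `"HPS"`.
#' @param seed Integer seed.
#' @param g Early-burst rate factor for HPS (default 2000).
#' @param max_attempts Retry limit (default 20).
#' @return `list(trait = named vector in [0,1], K = achieved K)`.
#' @export
simulate_trait <- function(tree, scenario = c("MPS", "HPS", "LPS"), seed = 1,
                           g = 2000, max_attempts = 20) {
  scenario <- match.arg(scenario)
  target <- c(LPS = 0.15, MPS = 0.9, HPS = 5.5)[[scenario]]
  pre <- k_stat_precompute(tree)
  set.seed(as.integer(seed))
  K <- NA_real_
  for (attempt in seq_len(max_attempts)) {
    trait <- switch(scenario,
      MPS = phytools::fastBM(tree, a = 0.5, sig2 = 0.25, bounds = c(0, 1)),
      HPS = {
        x <- phytools::fastBM(acdc_rescale(tree, g), a = 0, sig2 = 1)
        stats::setNames(rescale01(x), names(x))
      },
      LPS = {
        x <- phytools::fastBM(tree, a = 0, sig2 = 1)
        noise <- stats::rnorm(length(x))
        # K decreases monotonically with the noise share; bisect on it
        lo <- 0; hi <- 10 * stats::sd(x)
        y <- x
        for (it in seq_len(30)) {
          mid <- (lo + hi) / 2
          y <- x + mid * noise
          kk <- k_stat(pre, stats::setNames(y, names(x)))
          if (abs(kk - target) < 0.005) break
          if (kk > target) lo <- mid else hi <- mid
        }
        stats::setNames(rescale01(y), names(x))
      })
    if (stats::sd(trait) == 0) next
    K <- k_stat(pre, trait)
    if (K >= 0.5 * target && K <= 1.5 * target)
      return(list(trait = trait, K = K))
    if (scenario == "HPS") {
      # the rate factor giving the target K depends on the tree shape;
      # adapt it multiplicatively between attempts
      g <- max(2, g * (target / K)^1.5)
    }
  }
  stop(sprintf("could not reach target K = %.2f within %d attempts (last K = %.3f)",
               target, max_attempts, K))
}

#' Metacommunity species abundances from the zero-sum multinomial model
#'
#' Species relative abundances in the regional pool are drawn i.i.d. from
#' the metacommunity zero-sum multinomial (mZSM) species-abundance
#' distribution of neutral theory, p(n) proportional to
#' (theta/n) (1 - n/J)^(theta-1) for n = 1..J-1, with J the metacommunity
#' size in individuals and theta the fundamental biodiversity number.
#' For very large J the support is approximated on a log-spaced grid.
#'
#' @param n_species Number of species to draw.
#' @param J Metacommunity size (individuals).
#' @param theta Fundamental biodiversity number.
#' @param seed Integer seed.
#' @return Numeric vector of relative abundances summing to 1.
#' @export
mzsm_metacommunity <- function(n_species, J = 2e5, theta = 500, seed = 1) {
  set.seed(as.integer(seed))
  if (J <= 1e6) {
    n <- seq_len(J - 1)
    w <- rep(1, length(n))
  } else {
    n <- unique(round(exp(seq(0, log(J - 1), length.out = 2e5))))
    # multiplicity of each grid point (integers it stands for)
    edges <- c(0, n)
    w <- diff(edges)
  }
  logp <- log(theta) - log(n) + (theta - 1) * log1p(-n / J) + log(w)
  p <- exp(logp - max(logp))
  draws <- sample(n, n_species, replace = TRUE, prob = p)
  draws / sum(draws)
}
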