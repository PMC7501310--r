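#' Abundance-weighted beta mean pairwise distance (betaMPD)
#'
#' betaMPD between communities u and v over a set of taxa is
#' sum_ij f_iu f_jv d_ij / sum_ij f_iu f_jv, with f the taxon relative
#' abundances. The ratio is invariant to uniform rescaling of either
#' abundance vector, so within-bin or community-wide relative abundances
#' give the same value.
#'
#' @param u,v Non-negative abundance vectors over the same taxa.
#' @param d Phylogenetic distance matrix for those taxa.
#' @return betaMPD (branch-length units), or `NA` if either vector is all
#'   zero (metric undefined).
#' @export
beta_mpd <- function(u, v, d) {
  su <- sum(u); sv <- sum(v)
  if (su == 0 || sv == 0) return(NA_real_)
  as.numeric(u %*% d %*% v) / (su * sv)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' sum |x_iu - x_iv| / sum (x_iu + x_iv); 0 for identical communities, 1
#' for disjoint supports. Invariant to a common scaling of both vectors.
#'
#' @param x_u,x_v Non-negative abundance vectors over the same taxa.
#' @return Bray-Curtis index in `[0, 1]`, `NA` if both vectors are all zero.
#' @export
bray_curtis <- function(x_u, x_v) {
  den <- sum(x_u + x_v)
  if (den == 0) return(NA_real_)
  sum(abs(x_u - x_v)) / den
}

#' Shuffle taxa across the tips of the phylogeny
#'
#' Applies a random permutation of taxon labels to the rows and columns of
#' the phylogenetic distance matrix, randomising phylogenetic relatedness
#' while keeping the distance multiset. Scope `"within_bin"` permutes
#' labels only among members of each bin, preserving bin identity;
#' `"across_all"` permutes over the whole taxon pool.
#'
#' @param dist Phylogenetic distance matrix.
#' @param bins A `bin_set`, required for `scope = "within_bin"`.
#' @param scope `"across_all"` (default) or `"within_bin"`.
#' @param seed Optional integer seed (set it for reproducibility).
#' @return The permuted distance matrix with the original dimnames.
#' @export
taxa_shuffle <- function(dist, bins = NULL, scope = c("across_all", "within_bin"),
                         seed = NULL) {
  scope <- match.arg(scope)
  if (!is.null(seed)) set.seed(as.integer(seed))
  perm <- shuffle_indices(nrow(dist), bins, scope)
  out <- dist[perm, perm]
  dimnames(out) <- dimnames(dist)
  out
}

# permutation of 1..n honouring the shuffle scope
shuffle_indices <- function(n, bins, scope) {
  if (scope == "across_all") return(sample.int(n))
  if (is.null(bins)) stop("within_bin shuffle needs a bin set")
  perm <- seq_len(n)
  for (idx in split(seq_len(n), bins$bin_id)) {
    perm[idx] <- idx[sample.int(length(idx))]
  }
  perm
}

#' Richness- and occupancy-constrained taxonomic null community
#'
#' For every sample, draws exactly its observed richness of taxa without
#' replacement with selection probability proportional to each taxon's
#' occurrence frequency across samples, then distributes the sample's total
#' abundance over the drawn taxa: one individual each (so realised richness
#' is exact), the remainder by a multinomial draw weighted by the taxa's
#' mean relative abundances.
#'
#' @param table A `comm_table` of counts.
#' @param seed Optional integer seed.
#' @param weights `"abundance"` (default, mean relative abundance) or
#'   `"equal"` multinomial fill weights.
#' @return A null `comm_table` with the observed per-sample richness and
#'   totals.
#' @export
taxonomic_null <- function(table, seed = NULL, weights = c("abundance", "equal")) {
  weights <- match.arg(weights)
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- unclass(table)
  if (any(m != round(m))) stop("taxonomic null requires integer counts")
  occ <- rowSums(m > 0)
  w_fill <- if (weights == "abundance") mean_relative_abundance(table) else
    rep(1, nrow(m))
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  eligible <- which(occ > 0)
  for (j in seq_len(ncol(m))) {
    rich <- sum(m[, j] > 0)
    if (rich > length(eligible))
      stop("sample richness exceeds taxa with nonzero occurrence")
    drawn <- eligible[sample.int(length(eligible), rich, prob = occ[eligible])]
    total <- sum(m[, j])
    fill <- rep(1, rich)
    extra <- total - rich
    if (extra > 0)
      fill <- fill + as.vector(stats::rmultinom(1, extra, w_fill[drawn]))
    out[drawn, j] <- fill
  }
  community_table(out, is_relative = FALSE)
}

#' Build a null ensemble
#'
#' Bundles an observed metric value with its null distribution; the summary
#' mean and standard deviation are computed from the null vector.
#'
#' @param metric Metric name (e.g. `"betaMPD"`, `"BC"`).
#' @param observed Observed value.
#' @param nulls Numeric vector of null values.
#' @return A list of class `null_ensemble`.
#' @export
null_ensemble <- function(metric, observed, nulls) {
  structure(list(metric = metric, observed = observed, nulls = nulls,
                 null_mean = mean(nulls), null_sd = stats::sd(nulls)),
            class = "null_ensemble")
}

#' Beta net relatedness index (betaNRI) from a null ensemble
#'
#' (observed - null mean) / null sd. A degenerate (zero-variance) null
#' yields 0 with a warning, which downstream classification treats as
#' non-significant.
#'
#' @param ensemble A [null_ensemble()].
#' @return betaNRI (dimensionless standardized effect size).
#' @export
beta_nri <- function(ensemble) {
  if (is.na(ensemble$null_sd) || ensemble$null_sd == 0) {
    warning("null distribution has zero variance; betaNRI set to 0")
    return(0)
  }
  (ensemble$observed - ensemble$null_mean) / ensemble$null_sd
}

#' Modified Raup-Crick metric from a null ensemble
#'
#' RC = 2 * sum(delta) / N_r - 1, where delta is 1 for null values below
#' the observed, 0.5 for ties, 0 above. Ties are decided after rounding
#' both sides to 1e-9 to avoid spurious floating-point half-counts.
#'
#' @param ensemble A [null_ensemble()].
#' @return RC in `[-1, 1]`.
#' @export
rc_metric <- function(ensemble) {
  n <- length(ensemble$nulls)
  if (n == 0) stop("empty null ensemble")
  obs <- round(ensemble$observed, 9)
  nul <- round(ensemble$nulls, 9)
  delta <- sum(nul < obs) + 0.5 * sum(nul == obs)
  2 * delta / n - 1
}

#' Direct two-tail significance test on the null distribution
#'
#' Classifies the observed value against the empirical quantiles of the
#' null ensemble: above the (1 - alpha/2) quantile is `"high"`, below the
#' alpha/2 quantile is `"low"`, otherwise `"ns"`. With alpha = 0.05 this
#' mirrors the +-1.96 standardized-effect-size thresholds when the null is
#' Gaussian, but stays valid for skewed null distributions.
#'
#' @param ensemble A [null_ensemble()].
#' @param alpha Two-tail significance level (default 0.05).
#' @return `"high"`, `"low"`, or `"ns"`.
#' @export
direct_significance <- function(ensemble, alpha = 0.05) {
  n <- length(ensemble$nulls)
  if (n < 2 / alpha)
    warning("too few randomizations for stable empirical quantiles")
  q <- stats::quantile(ensemble$nulls, c(alpha / 2, 1 - alpha / 2),
                       names = FALSE, type = 7)
  if (ensemble$observed > q[2]) "high"
  else if (ensemble$observed < q[1]) "low"
  else "ns"
}

# ---------------------------------------------------------------------------
# vectorised pair-bin engine
#
# Computes, for every sample pair and bin: observed betaMPD and its
# taxa-shuffle null mean/sd (-> betaNRI), and observed bin-level Bray-Curtis
# with its taxonomic-null rank (-> RC). Used by run_icamp(); the exported
# scalar operations above define the semantics, and tests check the two
# paths against each other.
#
# Bins are anchored to tree positions: the taxa shuffle re-assigns the
# observed abundance profiles to the tips (equivalently, permutes the
# distance matrix labels) so that each bin's null betaMPD stays on the
# bin's own distance scale while the abundance-phylogeny association is
# randomised. With scope "across_all" any taxon can land in the bin; with
# "within_bin" profiles are permuted among the bin's own members.

# betaMPD matrix (samples x samples) for one bin: within-bin normalised
# abundance columns against the bin's distance submatrix. Columns where the
# bin is absent yield zero and are reported via the validity mask.
bmpd_one_bin <- function(Pk, dk) {
  ck <- colSums(Pk)
  valid <- ck > 0
  ck[!valid] <- 1
  Pn <- sweep(Pk, 2, ck, "/")
  list(b = crossprod(Pn, dk %*% Pn), valid = valid)
}

icamp_pair_bin_metrics <- function(table, dist, bins,
                                   n_rand = 1000,
                                   null_scope = c("across_all", "within_bin"),
                                   seed = 1,
                                   taxo_weights = "abundance") {
  null_scope <- match.arg(null_scope)
  m <- unclass(table)
  stopifnot(identical(rownames(m), rownames(dist)))
  n <- ncol(m)
  rel <- sweep(m, 2, colSums(m), "/")
  bin_idx <- split(seq_len(nrow(m)), bins$bin_id)
  K <- length(bin_idx)
  dk_list <- lapply(bin_idx, function(i) dist[i, i, drop = FALSE])

  # bin totals per sample (community-wide relative abundance of each bin)
  f_bk <- do.call(rbind, lapply(bin_idx, function(idx)
    colSums(rel[idx, , drop = FALSE])))          # K x n
  present <- f_bk > 0

  obs_bmpd <- lapply(seq_len(K), function(k)
    bmpd_one_bin(rel[bin_idx[[k]], , drop = FALSE], dk_list[[k]])$b)

  # taxa-shuffle null for betaMPD
  set.seed(as.integer(seed))
  zero <- function() matrix(0, n, n)
  sum_b <- replicate(K, zero(), simplify = FALSE)
  sumsq_b <- replicate(K, zero(), simplify = FALSE)
  nval_b <- replicate(K, zero(), simplify = FALSE)
  for (r in seq_len(n_rand)) {
    perm <- shuffle_indices(nrow(m), bins, null_scope)
    relp <- rel[perm, , drop = FALSE]
    for (k in seq_len(K)) {
      bn <- bmpd_one_bin(relp[bin_idx[[k]], , drop = FALSE], dk_list[[k]])
      vv <- outer(bn$valid, bn$valid, "&")
      sum_b[[k]] <- sum_b[[k]] + bn$b * vv
      sumsq_b[[k]] <- sumsq_b[[k]] + bn$b^2 * vv
      nval_b[[k]] <- nval_b[[k]] + vv
    }
  }

  # observed bin-level Bray-Curtis
  obs_bc <- lapply(seq_len(K), function(k) {
    Xk <- rel[bin_idx[[k]], , drop = FALSE]
    num <- as.matrix(stats::dist(t(Xk), method = "manhattan"))
    den <- outer(f_bk[k, ], f_bk[k, ], "+")
    den[den == 0] <- NA_real_
    round(num / den, 9)
  })

  # taxonomic null for RC (counted over draws where the bin occupies both
  # null samples, so the rank is conditional on bin presence as observed)
  below <- replicate(K, zero(), simplify = FALSE)
  equal <- replicate(K, zero(), simplify = FALSE)
  nval_t <- replicate(K, zero(), simplify = FALSE)
  for (r in seq_len(n_rand)) {
    nullc <- taxonomic_null(table, weights = taxo_weights)
    nrel <- sweep(unclass(nullc), 2, colSums(nullc), "/")
    for (k in seq_len(K)) {
      Xk <- nrel[bin_idx[[k]], , drop = FALSE]
      ck <- colSums(Xk)
      vv <- outer(ck > 0, ck > 0, "&")
      num <- as.matrix(stats::dist(t(Xk), method = "manhattan"))
      den <- outer(ck, ck, "+")
      den[den == 0] <- 1
      bc_null <- round(num / den, 9)
      below[[k]] <- below[[k]] + (bc_null < obs_bc[[k]]) * vv
      equal[[k]] <- equal[[k]] + (bc_null == obs_bc[[k]]) * vv
      nval_t[[k]] <- nval_t[[k]] + vv
    }
  }

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    nv <- pmax(nval_b[[k]], 1)
    mean_k <- sum_b[[k]] / nv
    var_k <- pmax(sumsq_b[[k]] / nv - mean_k^2, 0)
    sd_k <- sqrt(var_k * nv / pmax(nv - 1, 1))
    bnri <- (obs_bmpd[[k]] - mean_k) / sd_k
    bnri[sd_k == 0 | nval_b[[k]] < 2] <- 0
    nt <- pmax(nval_t[[k]], 1)
    rc <- 2 * (below[[k]] + 0.5 * equal[[k]]) / nt - 1
    rc[nval_t[[k]] < 1] <- 0
    u <- pairs[, 1]; v <- pairs[, 2]
    both <- present[k, u] & present[k, v]
    either <- present[k, u] | present[k, v]
    out[[k]] <- data.frame(
      sample_u = colnames(m)[u], sample_v = colnames(m)[v], bin = k,
      f_uk = f_bk[k, u], f_vk = f_bk[k, v],
      two_sided = both,
      bmpd = ifelse(both, obs_bmpd[[k]][cbind(u, v)], NA_real_),
      bnri = ifelse(both, bnri[cbind(u, v)], NA_real_),
      # a bin present in exactly one sample still has a defined (maximal)
      # Bray-Curtis and Raup-Crick rank; betaMPD needs presence in both
      bc = ifelse(either, obs_bc[[k]][cbind(u, v)], NA_real_),
      rc = ifelse(either, rc[cbind(u, v)], NA_real_))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
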