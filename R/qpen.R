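#' Abundance-weighted beta mean nearest taxon distance (betaMNTD)
#'
#' For each taxon present in one community, the distance to its nearest
#' taxon present in the other community is averaged with relative-abundance
#' weights; the two directed means are averaged.
#'
#' @param u,v Non-negative abundance vectors over the same taxa.
#' @param d Phylogenetic distance matrix for those taxa.
#' @return betaMNTD (branch-length units).
#' @export
beta_mntd <- function(u, v, d) {
  pu <- which(u > 0); pv <- which(v > 0)
  if (length(pu) == 0 || length(pv) == 0) return(NA_real_)
  fu <- u[pu] / sum(u[pu]); fv <- v[pv] / sum(v[pv])
  dmin_u <- apply(d[pu, pv, drop = FALSE], 1, min)
  dmin_v <- apply(d[pu, pv, drop = FALSE], 2, min)
  0.5 * (sum(fu * dmin_u) + sum(fv * dmin_v))
}

#' Classify a whole-community turnover (QPEN rule)
#'
#' Same decision scheme as the bin-level classifier but driven by the
#' entire-community betaNTI (threshold 2, following the original
#' entire-community literature) and Raup-Crick on Bray-Curtis.
#'
#' @param bnti betaNTI value(s).
#' @param rc RC value(s).
#' @param ses_cut betaNTI threshold (default 2).
#' @param rc_cut RC threshold (default 0.95).
#' @return Process label(s).
#' @export
qpen_classify <- function(bnti, rc, ses_cut = 2, rc_cut = 0.95) {
  classify_process(bnti, rc, ses_cut = ses_cut, rc_cut = rc_cut)
}

#' Entire-community null-model analysis (QPEN baseline)
#'
#' The baseline the bin-based framework improves on: betaMNTD with a
#' taxa-shuffle null gives betaNTI per sample pair; whole-community
#' Bray-Curtis with the richness/occupancy-constrained taxonomic null gives
#' RC; each pair is classified into one of the five processes, and the
#' relative importance of a process in a group of pairs is the fraction of
#' pairs it governs.
#'
#' @param table A `comm_table` of counts.
#' @param tree Rooted `phylo` with branch lengths.
#' @param n_rand Number of randomizations (default 1000).
#' @param seed Master seed.
#' @return List of class `qpen_result` with `pairs` (betaMNTD, betaNTI, BC,
#'   RC, label per pair).
#' @export
qpen <- function(table, tree, n_rand = 1000, seed = 1) {
  mt <- match_taxa(table, tree)
  table <- mt$table; tree <- mt$tree
  dist <- cophenetic_distances(tree)
  m <- unclass(table)
  n <- ncol(m)
  rel <- sweep(m, 2, colSums(m), "/")
  present <- lapply(seq_len(n), function(j) which(m[, j] > 0))

  bmntd_all <- function(d) {
    # min distance from every taxon to each sample's members, then weight
    dmin <- vapply(present, function(idx)
      do.call(pmin, as.data.frame(d[, idx, drop = FALSE])), numeric(nrow(d)))
    half <- crossprod(rel, dmin)      # half[u, v] = sum_i f_iu dmin(i -> v)
    0.5 * (half + t(half))
  }
  obs_mntd <- bmntd_all(dist)

  set.seed(as.integer(seed))
  s1 <- matrix(0, n, n); s2 <- matrix(0, n, n)
  for (r in seq_len(n_rand)) {
    perm <- sample.int(nrow(m))
    bn <- bmntd_all(dist[perm, perm])
    s1 <- s1 + bn; s2 <- s2 + bn^2
  }
  mean_n <- s1 / n_rand
  sd_n <- sqrt(pmax(s2 / n_rand - mean_n^2, 0) * n_rand / (n_rand - 1))
  bnti <- (obs_mntd - mean_n) / sd_n
  bnti[sd_n == 0] <- 0

  obs_bc <- round(bc_matrix(rel), 9)
  below <- matrix(0, n, n); equal <- matrix(0, n, n)
  for (r in seq_len(n_rand)) {
    nullc <- taxonomic_null(table)
    nrel <- sweep(unclass(nullc), 2, colSums(nullc), "/")
    bc_null <- round(bc_matrix(nrel), 9)
    below <- below + (bc_null < obs_bc)
    equal <- equal + (bc_null == obs_bc)
  }
  rc <- 2 * (below + 0.5 * equal) / n_rand - 1

  pr <- which(upper.tri(bnti), arr.ind = TRUE)
  pairs <- data.frame(sample_u = colnames(m)[pr[, 1]],
                      sample_v = colnames(m)[pr[, 2]],
                      bmntd = obs_mntd[pr], bnti = bnti[pr],
                      bc = obs_bc[pr], rc = rc[pr])
  pairs$label <- qpen_classify(pairs$bnti, pairs$rc)
  structure(list(pairs = pairs,
                 params = list(n_rand = n_rand, seed = seed)),
            class = "qpen_result")
}

# whole-community Bray-Curtis between all sample columns
bc_matrix <- function(rel) {
  num <- as.matrix(stats::dist(t(rel), method = "manhattan"))
  cs <- colSums(rel)
  num / outer(cs, cs, "+")
}

#' Process importance as fraction of turnovers (QPEN integration)
#'
#' @param labels Process label per pairwise turnover in a group.
#' @return Named fractions over the five processes, summing to 1.
#' @export
qpen_importance <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) stop("no classified pairs")
  vapply(PROCESSES, function(tau) mean(labels == tau), numeric(1))
}

#' Group summaries for a QPEN result
#'
#' @param result A `qpen_result`.
#' @param grouping Named character vector (sample -> group).
#' @param between_group Also summarise cross-group pair sets.
#' @return Data frame: group, n_pairs, the five process fractions,
#'   stochasticity, and the dominant process.
#' @export
qpen_groups <- function(result, grouping, between_group = FALSE) {
  p <- result$pairs
  gu <- grouping[p$sample_u]; gv <- grouping[p$sample_v]
  sets <- list()
  for (g in sort(unique(grouping)))
    sets[[g]] <- which(gu == g & gv == g)
  if (between_group) {
    cmb <- utils::combn(sort(unique(grouping)), 2)
    for (i in seq_len(ncol(cmb))) {
      nm <- paste(cmb[1, i], cmb[2, i], sep = "_vs_")
      sets[[nm]] <- which((gu == cmb[1, i] & gv == cmb[2, i]) |
                          (gu == cmb[2, i] & gv == cmb[1, i]))
    }
  }
  rows <- lapply(names(sets), function(nm) {
    idx <- sets[[nm]]
    if (length(idx) == 0) return(NULL)
    fr <- qpen_importance(p$label[idx])
    data.frame(group = nm, n_pairs = length(idx), t(fr),
               stochasticity = sum(fr[c("HD", "DL", "DR")]),
               dominant = dominant_process(fr), check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Dominant process of an importance vector
#'
#' Ties are broken by the fixed order HeS, HoS, DL, HD, DR.
#'
#' @param p Named numeric vector over the five processes.
#' @return The process label with the highest importance.
#' @export
dominant_process <- function(p) {
  p <- p[PROCESSES]
  PROCESSES[which.max(p)]
}
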