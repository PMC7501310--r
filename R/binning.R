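#' @name phylo-binning
#' @title Phylogenetic binning
#'
#' @description Taxa are partitioned into phylogenetic bins -- groups of
#' close relatives within which niche preferences can be assumed
#' phylogenetically conserved -- and each bin is later analysed by its own
#' null models. Three algorithms are provided: distance-to-centroid,
#' all-pairwise-distance, and tree truncation. Strict bins satisfy their
#' defining criterion at the signal threshold `ds`; bins smaller than
#' `nmin` are then merged into their nearest-neighbour bin (losing the
#' strict flag) so that every bin has enough taxa for statistical power.
#'
#' A bin set is a list with elements `bin_id` (integer per taxon, named),
#' `taxa` (list of member IDs per bin), `strict` (logical per bin),
#' `centroid` (taxon ID or NA per bin), and `algorithm`.
NULL

new_binset <- function(bin_id, taxa_ids, strict, centroid, algorithm) {
  names(bin_id) <- taxa_ids
  k <- max(bin_id)
  members <- split(taxa_ids, bin_id)
  structure(list(bin_id = bin_id,
                 taxa = members,
                 sizes = lengths(members),
                 strict = strict,
                 centroid = centroid,
                 algorithm = algorithm),
            class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("Bin set (%s): %d taxa in %d bins, sizes %s\n",
              x$algorithm, length(x$bin_id), length(x$taxa),
              paste(range(x$sizes), collapse = "-")))
  invisible(x)
}

check_bin_args <- function(dist, ds, nmin) {
  if (!isSymmetric(unname(dist))) stop("distance matrix must be symmetric")
  if (ds <= 0) stop("ds must be positive")
  if (nmin < 1) stop("nmin must be >= 1")
}

# abundance-descending taxon order with lexicographic tie-break
abundance_order <- function(mean_ra, taxa) order(-mean_ra, taxa)

#' Bin taxa by distance to abundant centroid taxa
#'
#' The most abundant unassigned taxon seeds a bin; every unassigned taxon
#' closer than `ds` to the centroid joins it. This repeats until all taxa
#' are assigned, after which small bins are merged ([merge_small_bins()]).
#'
#' @param dist Cophenetic distance matrix (taxa as dimnames).
#' @param mean_ra Mean relative abundance per taxon, aligned with `dist`.
#' @param ds Phylogenetic signal threshold (branch-length units).
#' @param nmin Minimal bin size after merging.
#' @return A `bin_set`.
#' @export
bin_by_centroid <- function(dist, mean_ra, ds, nmin) {
  check_bin_args(dist, ds, nmin)
  taxa <- rownames(dist)
  if (nmin >= 2 && length(taxa) == 1) nmin <- 1
  ord <- abundance_order(mean_ra, taxa)
  assigned <- integer(length(taxa))
  centroid <- character(0)
  k <- 0
  for (i in ord) {
    if (assigned[i] > 0) next
    k <- k + 1
    members <- which(assigned == 0 & dist[, i] < ds)
    assigned[members] <- k
    assigned[i] <- k
    centroid[k] <- taxa[i]
  }
  strict <- rep(TRUE, k)
  bs <- new_binset(assigned, taxa, strict, centroid, "centroid")
  merge_small_bins(bs, dist, nmin)
}

#' Bin taxa by all-pairwise distances
#'
#' The first bin holds the most abundant taxon plus the greedy set of taxa
#' (considered in descending abundance) each within `ds` of every current
#' member, so all pairwise distances inside a strict bin are below `ds`.
#' Remaining taxa seed further bins; small bins are then merged.
#'
#' @inheritParams bin_by_centroid
#' @return A `bin_set`.
#' @export
bin_by_pairwise <- function(dist, mean_ra, ds, nmin) {
  check_bin_args(dist, ds, nmin)
  taxa <- rownames(dist)
  if (nmin >= 2 && length(taxa) == 1) nmin <- 1
  ord <- abundance_order(mean_ra, taxa)
  assigned <- integer(length(taxa))
  centroid <- character(0)
  k <- 0
  for (i in ord) {
    if (assigned[i] > 0) next
    k <- k + 1
    members <- i
    assigned[i] <- k
    for (j in ord) {
      if (assigned[j] > 0) next
      if (all(dist[j, members] < ds)) {
        members <- c(members, j)
        assigned[j] <- k
      }
    }
    centroid[k] <- taxa[i]
  }
  bs <- new_binset(assigned, taxa, rep(TRUE, k), centroid, "pairwise")
  merge_small_bins(bs, dist, nmin)
}

node_depths_from_root <- function(tree) {
  # depth (sum of branch lengths) of every node from the root
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  depth <- numeric(n_node)
  # edges in preorder so parents are visited first
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    depth[ch] <- depth[p] + ord$edge.length[e]
  }
  depth
}

#' Bin taxa by truncating the phylogenetic tree
#'
#' The tree is cut at the smallest distance from the root such that, within
#' every resulting tip cluster (tips descending from an edge crossing the
#' cut), all pairwise cophenetic distances are below `ds`. Clusters form the
#' strict bins; small bins are merged into the bin holding their nearest
#' relatives.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param ds Phylogenetic signal threshold.
#' @param nmin Minimal bin size after merging.
#' @param dist Optional precomputed cophenetic matrix (computed if missing).
#' @return A `bin_set`.
#' @export
bin_by_tree <- function(tree, ds, nmin, dist = NULL) {
  validate_tree(tree)
  if (is.null(dist)) dist <- cophenetic_distances(tree)
  check_bin_args(dist, ds, nmin)
  taxa <- tree$tip.label
  if (nmin >= 2 && length(taxa) == 1) nmin <- 1
  n_tip <- length(taxa)
  depth <- node_depths_from_root(tree)

  clusters_at <- function(x) {
    # tips grouped by the edge crossing depth x (parent depth < x <= child)
    parent <- tree$edge[, 1]; child <- tree$edge[, 2]
    crossing <- which(depth[parent] < x & depth[child] >= x)
    cl <- integer(n_tip)
    for (ci in seq_along(crossing)) {
      tips <- tips_under(tree, child[crossing[ci]])
      cl[tips] <- ci
    }
    # tips shallower than the cut stand alone
    loose <- which(cl == 0)
    if (length(loose))
      cl[loose] <- max(cl) + seq_along(loose)
    cl
  }
  ok_at <- function(cl) {
    for (g in split(seq_len(n_tip), cl)) {
      if (length(g) > 1 && max(dist[g, g]) >= ds) return(FALSE)
    }
    TRUE
  }
  # no truncation needed when the whole tree already meets the criterion
  if (n_tip == 1 || max(dist) < ds) {
    bs <- new_binset(rep(1L, n_tip), taxa, TRUE, NA_character_, "tree")
    return(merge_small_bins(bs, dist, nmin))
  }
  # candidate cuts: just past each node depth; condition is monotone in x
  cand <- sort(unique(depth)) + 1e-12
  cand <- cand[cand <= max(depth[seq_len(n_tip)])]
  cl <- NULL
  for (x in cand) {
    cl <- clusters_at(x)
    if (ok_at(cl)) break
    cl <- NULL
  }
  if (is.null(cl)) cl <- seq_len(n_tip)  # fall back to singletons
  # renumber bins in order of appearance
  cl <- match(cl, unique(cl))
  bs <- new_binset(cl, taxa, rep(TRUE, max(cl)), rep(NA_character_, max(cl)),
                   "tree")
  merge_small_bins(bs, dist, nmin)
}

tips_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  out <- integer(0)
  stack <- node
  children <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- children[[as.character(nd)]]
    tips <- ch[ch <= n_tip]
    out <- c(out, tips)
    stack <- c(stack, ch[ch > n_tip])
  }
  out
}

#' Merge undersized bins into their nearest-neighbour bins
#'
#' While any bin has fewer than `nmin` taxa, the smallest such bin (ties:
#' lowest bin index) is merged into the bin minimising the between-bin
#' distance (single linkage, i.e. minimum cross-pair cophenetic distance;
#' ties: lower index). Merged bins lose the strict flag. If the whole taxon
#' set is smaller than `nmin` a single bin is returned with a warning.
#'
#' @param bins A `bin_set` of strict bins.
#' @param dist Cophenetic distance matrix.
#' @param nmin Minimal bin size.
#' @param linkage `"single"` (default) or `"mean"` between-bin distance.
#' @return A `bin_set` meeting the size requirement.
#' @export
merge_small_bins <- function(bins, dist, nmin, linkage = c("single", "mean")) {
  linkage <- match.arg(linkage)
  taxa <- names(bins$bin_id)
  id <- bins$bin_id
  strict <- bins$strict
  if (length(taxa) < nmin) {
    if (max(id) > 1) {
      warning("fewer taxa than nmin; returning a single bin")
      id[] <- 1L
      strict <- FALSE
    }
    return(new_binset(id, taxa, strict[1], bins$centroid[1], bins$algorithm))
  }
  idx <- split(seq_along(taxa), id)
  strict <- as.list(strict)
  repeat {
    sizes <- lengths(idx)
    small <- which(sizes < nmin)
    if (length(small) == 0) break
    s <- small[which.min(sizes[small])]       # smallest; ties -> lowest index
    others <- setdiff(seq_along(idx), s)
    dmin <- vapply(others, function(o) {
      block <- dist[idx[[s]], idx[[o]], drop = FALSE]
      if (linkage == "single") min(block) else mean(block)
    }, numeric(1))
    tgt <- others[which.min(dmin)]            # ties -> lower index via which.min
    idx[[tgt]] <- sort(c(idx[[tgt]], idx[[s]]))
    strict[[tgt]] <- FALSE
    idx[[s]] <- NULL
    strict[[s]] <- NULL
  }
  new_id <- integer(length(taxa))
  for (k in seq_along(idx)) new_id[idx[[k]]] <- k
  cent <- rep(NA_character_, length(idx))
  new_binset(new_id, taxa, unlist(strict), cent, bins$algorithm)
}

#' Abundance-weighted niche values of taxa
#'
#' The niche value of a taxon for an environmental factor is the
#' relative-abundance-weighted mean of the factor over the samples, a proxy
#' for the taxon's niche optimum. For example, a taxon with relative
#' abundances 10%, 20% and 10% in samples at 10, 20 and 30 degrees C has a
#' temperature niche value of (10*0.1 + 20*0.2 + 30*0.1) / 0.4 = 20 degrees C.
#'
#' @param table A `comm_table`.
#' @param env Numeric matrix samples x factors (or a named vector for one
#'   factor); sample IDs must cover the table's samples.
#' @return Matrix taxa x factors of niche values; `NA` for taxa absent from
#'   every sample.
#' @export
niche_values <- function(table, env) {
  if (is.null(dim(env))) env <- cbind(factor = env)
  if (!all(colnames(table) %in% rownames(env)))
    stop("env table must contain every sample")
  env <- env[colnames(table), , drop = FALSE]
  rel <- sweep(unclass(table), 2, colSums(table), "/")
  tot <- rowSums(rel)
  v <- (rel %*% env) / tot
  v[tot == 0, ] <- NA_real_
  rownames(v) <- rownames(table)
  v
}

#' Within-bin phylogenetic signal by Mantel test
#'
#' For each bin with at least 3 taxa, correlates within-bin phylogenetic
#' distances with absolute niche-value differences (Pearson), with a
#' one-tail (positive) permutation p value computed as
#' (number of permuted R >= observed + 1) / (permutations + 1).
#' A bin has significant signal when R > 0.1 and p < 0.05. With several
#' factors, each factor is tested and the best (highest R) is reported.
#'
#' @param bins A `bin_set`.
#' @param dist Cophenetic distance matrix.
#' @param niche Matrix taxa x factors from [niche_values()] (or vector).
#' @param permutations Number of Mantel permutations (default 999).
#' @param seed Integer seed.
#' @return Data frame per bin: `bin`, `size`, `factor`, `R`, `p`,
#'   `significant`.
#' @export
bin_phylo_signal <- function(bins, dist, niche, permutations = 999, seed = 1) {
  if (is.null(dim(niche))) niche <- cbind(factor = niche)
  set.seed(as.integer(seed))
  res <- lapply(seq_along(bins$taxa), function(k) {
    taxa <- bins$taxa[[k]]
    n <- length(taxa)
    if (n < 3)
      return(data.frame(bin = k, size = n, factor = NA, R = NA_real_,
                        p = NA_real_, significant = FALSE))
    dk <- dist[taxa, taxa]
    best <- list(R = -Inf, p = NA_real_, factor = NA_character_)
    for (f in colnames(niche)) {
      nd <- abs(outer(niche[taxa, f], niche[taxa, f], "-"))
      mt <- mantel_perm(dk, nd, permutations)
      if (!is.na(mt$R) && mt$R > best$R) best <- c(mt, factor = f)
    }
    if (!is.finite(best$R))
      return(data.frame(bin = k, size = n, factor = NA, R = NA_real_,
                        p = NA_real_, significant = FALSE))
    data.frame(bin = k, size = n, factor = best$factor, R = best$R,
               p = best$p,
               significant = !is.na(best$R) && best$R > 0.1 && best$p < 0.05)
  })
  do.call(rbind, res)
}

# one-tail Mantel: Pearson r between lower triangles, permutation of one
# matrix's row/column order
mantel_perm <- function(a, b, permutations) {
  lt <- lower.tri(a)
  x <- a[lt]; y <- b[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || anyNA(y))
    return(list(R = NA_real_, p = NA_real_))
  r_obs <- stats::cor(x, y)
  n <- nrow(a)
  count <- 0L
  for (i in seq_len(permutations)) {
    p <- sample.int(n)
    r_null <- stats::cor(x, b[p, p][lt])
    if (r_null >= r_obs) count <- count + 1L
  }
  list(R = r_obs, p = (count + 1) / (permutations + 1))
}

#' Choose the minimal bin size maximising significant phylogenetic signal
#'
#' Runs the binning and signal test for every candidate `nmin` and returns
#' the one giving the most bins with significant signal; ties are broken by
#' higher mean within-bin Mantel R, then by smaller `nmin`.
#'
#' @param candidates Integer vector of `nmin` values to try.
#' @param tree,dist,mean_ra,ds Binning inputs (see [bin_by_tree()]).
#' @param niche Niche values for [bin_phylo_signal()].
#' @param algorithm One of `"tree"`, `"centroid"`, `"pairwise"`.
#' @param permutations,seed Passed to [bin_phylo_signal()].
#' @return `list(nmin=, table=)` with the per-candidate summary.
#' @export
optimize_nmin <- function(candidates, tree = NULL, dist = NULL, mean_ra = NULL,
                          ds = 0.2, niche, algorithm = c("tree", "centroid", "pairwise"),
                          permutations = 999, seed = 1) {
  algorithm <- match.arg(algorithm)
  if (is.null(dist)) dist <- cophenetic_distances(tree)
  rows <- lapply(seq_along(candidates), function(i) {
    nm <- candidates[i]
    bs <- switch(algorithm,
      tree = bin_by_tree(tree, ds, nm, dist = dist),
      centroid = bin_by_centroid(dist, mean_ra, ds, nm),
      pairwise = bin_by_pairwise(dist, mean_ra, ds, nm))
    sig <- bin_phylo_signal(bs, dist, niche, permutations, seed + i)
    data.frame(nmin = nm, n_bins = length(bs$taxa),
               n_significant = sum(sig$significant, na.rm = TRUE),
               mean_R = mean(sig$R, na.rm = TRUE))
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$n_significant, -tab$mean_R, tab$nmin)
  list(nmin = tab$nmin[ord[1]], table = tab)
}
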