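#' @name benchmark-simulator
#' @title Benchmark community simulator with known assembly processes
#'
#' @description Generates datasets with per-pair ground-truth process
#' importance. The design: one region with a shared metacommunity, two
#' islands (A, B) each holding two plots under contrasting environments
#' (EV = 0.05 in the "L" plots, 0.95 in the "H" plots), six replicate local
#' communities per plot (24 samples: LA, LB, HA, HB). Species in the
#' regional pool are assigned to be governed by selection (Gaussian
#' environmental filtering, optionally competition), dispersal (island
#' pools with near-complete within-island exchange and no between-island
#' exchange), or drift (neutral sampling from the metacommunity at a
#' moderate immigration rate). Within a dataset the three fractions are
#' fixed ("situation"); across 15 situations they sweep 0 to 1 in steps
#' of 0.25.
NULL

#' Benchmark design presets
#'
#' `"desk"` (default) uses a 2e5-individual metacommunity with theta = 500
#' and 2000-individual local communities; `"full"` uses the heavier
#' 2e7 / theta = 5000 / 20000-individual configuration.
#'
#' @param preset `"desk"` or `"full"`.
#' @return Named list of simulator parameters.
#' @export
sim_preset <- function(preset = c("desk", "full")) {
  preset <- match.arg(preset)
  common <- list(n_tips = 1140, local_size_reduced = NULL, richness = 100,
                 n_reps = 6, sigma_E = 0.015, m1 = 0.01, m2 = 0.99,
                 m_drift = 0.5, ds = 0.2, ev = c(L = 0.05, H = 0.95))
  if (preset == "desk")
    c(common, list(J = 2e5, theta = 500, local_size = 2000))
  else
    c(common, list(J = 2e7, theta = 5000, local_size = 20000))
}

#' The 15 benchmark situations
#'
#' All compositions of (selection, dispersal, drift) fractions over
#' {0, 0.25, 0.5, 0.75, 1} summing to 1: exactly choose(6, 2) = 15,
#' including the three pure cases.
#'
#' @return Data frame with columns `selection`, `dispersal`, `drift` and a
#'   `situation` label.
#' @export
situation_mixes <- function() {
  g <- expand.grid(selection = seq(0, 1, 0.25), dispersal = seq(0, 1, 0.25))
  g$drift <- 1 - g$selection - g$dispersal
  g <- g[g$drift >= -1e-9, ]
  g$drift <- pmax(g$drift, 0)
  g$situation <- sprintf("s%02d_d%02d_r%02d", round(g$selection * 100),
                         round(g$dispersal * 100), round(g$drift * 100))
  rownames(g) <- NULL
  g[, c("situation", "selection", "dispersal", "drift")]
}

#' Gaussian environmental-filtering abundance weights
#'
#' Under strong abiotic filtering a species' local abundance follows a
#' Gaussian function of the mismatch between the local environment EV and
#' its optimum E_i: A_i proportional to exp(-(EV - E_i)^2 / (2 sigma_E^2)).
#' Computed in log space (the kernel underflows far from the optimum) and
#' returned normalised to sum to 1, which preserves all weight ratios.
#'
#' @param ev Environmental value of the local community.
#' @param E Vector of species optima.
#' @param sigma_E Selection width (default 0.015).
#' @return Normalised weights.
#' @export
selection_abundances <- function(ev, E, sigma_E = 0.015) {
  logw <- -(ev - E)^2 / (2 * sigma_E^2)
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' Rank competitors and assign geometric-series abundances
#'
#' The strongest competitor is drawn at random from the `top` species with
#' the smallest |EV - E_i|; each subsequent rank goes to the candidate
#' maximising the abundance-weighted Euclidean niche distance to the prior
#' competitors, nd_hi = sqrt(sum_j 0.5^j (E_i - E_j)^2) with j the prior
#' rank. Rank h receives relative abundance proportional to 0.5^h.
#'
#' @param ev Local environmental value.
#' @param E Named vector of optima for the candidate species.
#' @param n_rank How many competitors to rank (default all candidates).
#' @param top Size of the best-fitness pool for the first rank (default 10).
#' @param seed Optional integer seed.
#' @return `list(species = ranked names, abundance = normalised geometric
#'   weights)`.
#' @export
competition_ranking <- function(ev, E, n_rank = length(E), top = 10,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(!is.null(names(E)))
  n_rank <- min(n_rank, length(E))
  fit_ord <- order(abs(ev - E), names(E))
  first <- fit_ord[sample.int(min(top, length(E)), 1)]
  ranked <- names(E)[first]
  remaining <- setdiff(names(E), ranked)
  while (length(ranked) < n_rank && length(remaining) > 0) {
    h <- length(ranked)
    nd <- vapply(remaining, function(sp)
      sqrt(sum(0.5^seq_len(h) * (E[[sp]] - E[ranked])^2)), numeric(1))
    best <- remaining[order(-nd, remaining)[1]]
    ranked <- c(ranked, best)
    remaining <- setdiff(remaining, best)
  }
  ab <- 0.5^seq_along(ranked)
  list(species = ranked, abundance = ab / sum(ab))
}

#' Assign regional-pool species to assembly-process types
#'
#' Species are greedily assigned to the selection and dispersal pools in
#' whole phylogenetic clusters: when a species (picked with probability
#' proportional to metacommunity abundance) is assigned, all unassigned
#' species within `ds` of it share its type, reflecting the phylogenetic
#' conservatism of the governing process. Clusters that would overshoot the
#' target abundance fraction by more than 2% are skipped when possible.
#' Unassigned species default to drift; when the drift fraction is 0 they
#' join the dispersal pool (or selection if dispersal is also 0).
#'
#' @param meta_ra Named metacommunity relative abundances.
#' @param dist Cophenetic distance matrix over the species.
#' @param mix Named fractions `c(selection=, dispersal=, drift=)` summing
#'   to 1.
#' @param ds Phylogenetic propagation radius (default 0.2).
#' @param seed Integer seed.
#' @param competition_fraction Share of the selection pool governed by
#'   competition rather than filtering (default 0).
#' @return Named character vector: `"selection"`, `"competition"`,
#'   `"dispersal"`, or `"drift"` per species, with an integer attribute
#'   `"cluster"` recording the phylogenetic cluster each assigned species
#'   belongs to (0 for drift).
#' @export
assign_species_types <- function(meta_ra, dist, mix, ds = 0.2, seed = 1,
                                 competition_fraction = 0) {
  stopifnot(abs(sum(mix) - 1) < 1e-9)
  set.seed(as.integer(seed))
  species <- names(meta_ra)
  type <- stats::setNames(rep(NA_character_, length(species)), species)
  cluster <- stats::setNames(integer(length(species)), species)
  n_cluster <- 0L
  total <- sum(meta_ra)

  take_cluster <- function(sp) {
    un <- species[is.na(type)]
    un[dist[sp, un] < ds]
  }
  assign_pool <- function(tau, target) {
    if (target <= 0) return(invisible(NULL))
    realized <- sum(meta_ra[which(type == tau)]) / total
    blocked <- character(0)
    while (realized < target - 0.02) {
      cand <- species[is.na(type) & !(species %in% blocked)]
      if (length(cand) == 0) {
        cand <- species[is.na(type)]
        if (length(cand) == 0) break
        # nothing fits within tolerance: take the smallest-overshoot cluster
        ov <- vapply(cand, function(sp) sum(meta_ra[take_cluster(sp)]) / total,
                     numeric(1))
        sp <- cand[which.min(abs(realized + ov - target))]
        cl <- take_cluster(sp)
        n_cluster <<- n_cluster + 1L
        type[cl] <<- tau; cluster[cl] <<- n_cluster
        realized <- sum(meta_ra[which(type == tau)]) / total
        break
      }
      sp <- cand[sample.int(length(cand), 1, prob = meta_ra[cand])]
      cl <- take_cluster(sp)
      gain <- sum(meta_ra[cl]) / total
      if (realized + gain > target + 0.02) {
        blocked <- c(blocked, sp)
        next
      }
      n_cluster <<- n_cluster + 1L
      type[cl] <<- tau; cluster[cl] <<- n_cluster
      realized <- realized + gain
    }
    invisible(NULL)
  }

  assign_pool("selection", mix[["selection"]])
  assign_pool("dispersal", mix[["dispersal"]])
  left <- is.na(type)
  if (mix[["drift"]] > 0) {
    type[left] <- "drift"
  } else if (mix[["dispersal"]] > 0) {
    type[left] <- "dispersal"
    cluster[left] <- n_cluster + 1L
  } else {
    type[left] <- "selection"
    cluster[left] <- n_cluster + 1L
  }
  if (competition_fraction > 0 && any(type == "selection")) {
    # promote whole selection clusters to competition up to the target share
    sel_cl <- unique(cluster[type == "selection"])
    tgt <- competition_fraction * sum(meta_ra[type == "selection"])
    ord <- sel_cl[sample.int(length(sel_cl))]
    got <- 0
    for (cl in ord) {
      sp <- names(cluster)[cluster == cl & type == "selection"]
      if (got >= tgt) break
      type[sp] <- "competition"
      got <- got + sum(meta_ra[sp])
    }
  }
  attr(type, "cluster") <- cluster
  type
}

# Dirichlet draw; alpha entries that underflow to zero mass are kept at 0
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  s <- sum(g)
  if (s == 0) {
    # extreme drift: collapse onto one species picked by alpha weight
    g[sample.int(length(alpha), 1, prob = alpha)] <- 1
    s <- 1
  }
  g / s
}

# neutral local community under immigration rate m from a source pool:
# Dirichlet-multinomial with Etienne's concentration I = m (Jn - 1)/(1 - m)
neutral_local_freq <- function(source_p, m, local_size) {
  I <- m * (local_size - 1) / (1 - m)
  rdirichlet1(I * source_p)
}

# draw exactly `richness` species (prob ~ weights) and allocate `size`
# individuals: one each, remainder multinomial on the renormalised weights
draw_fixed_richness <- function(weights, richness, size) {
  pos <- which(weights > 0)
  if (length(pos) < richness) {
    # pad with the largest zero-weight species to honour the richness quota
    pad <- order(weights, decreasing = TRUE)
    pos <- unique(c(pos, pad))[seq_len(richness)]
    chosen <- pos
  } else {
    chosen <- pos[sample.int(length(pos), richness, prob = weights[pos])]
  }
  counts <- numeric(length(weights))
  w <- weights[chosen]
  if (sum(w) == 0) w <- rep(1, length(chosen))
  alloc <- rep(1, length(chosen))
  extra <- size - richness
  if (extra > 0)
    alloc <- alloc + as.vector(stats::rmultinom(1, extra, w))
  counts[chosen] <- alloc
  counts
}

# deterministic analogue: pick the `richness` highest weights (ties by name)
# and allocate by largest remainder, with a floor of one individual
deterministic_fixed_richness <- function(weights, richness, size, nms) {
  ord <- order(-weights, nms)
  chosen <- ord[seq_len(min(richness, length(weights)))]
  w <- weights[chosen]
  if (sum(w) == 0) w <- rep(1, length(w))
  w <- w / sum(w)
  base <- pmax(floor(w * size), 1)
  # largest-remainder correction to hit the exact total
  excess <- sum(base) - size
  if (excess > 0) {
    # remove from the smallest allocations above 1
    ord2 <- order(w * size - base)
    for (i in ord2) {
      if (excess == 0) break
      take <- min(base[i] - 1, excess)
      base[i] <- base[i] - take
      excess <- excess - take
    }
  } else if (excess < 0) {
    frac <- w * size - floor(w * size)
    add <- order(-frac)[seq_len(-excess)]
    base[add] <- base[add] + 1
  }
  counts <- numeric(length(weights))
  counts[chosen] <- base
  counts
}

#' Simulate dispersal-governed local communities
#'
#' Each island holds a unique species pool simulated as a neutral local
#' community under the metacommunity at a low immigration rate (`m1`),
#' with the two island pools constrained to share no species. Local
#' communities then draw a fraction `m2` of individuals from their island
#' pool and `m1` from the metacommunity, so within-island turnovers are
#' governed by homogenizing dispersal and between-island turnovers by
#' dispersal limitation.
#'
#' @param meta_ra Named metacommunity relative abundances of the
#'   dispersal-governed species.
#' @param islands Character vector of island labels per local community
#'   (e.g. `c("A","A","B","B")`).
#' @param m1,m2 Metacommunity and island-pool replacement rates (defaults
#'   0.01 and 0.99).
#' @param local_size Individuals per local community.
#' @param richness Species per local community.
#' @param seed Integer seed.
#' @return Matrix species x local communities of counts.
#' @export
dispersal_communities <- function(meta_ra, islands, m1 = 0.01, m2 = 0.99,
                                  local_size = 2000, richness = 100,
                                  seed = 1) {
  set.seed(as.integer(seed))
  species <- names(meta_ra)
  isl <- sort(unique(islands))
  if (length(isl) > 2) stop("at most two islands supported")
  # disjoint island species sets: alternate abundance-ranked species
  ord <- order(-meta_ra, species)
  setA <- species[ord[seq_along(ord) %% 2 == 1]]
  setB <- setdiff(species, setA)
  sets <- stats::setNames(list(setA, setB)[seq_along(isl)], isl)
  pool <- list()
  for (i in isl) {
    p_src <- meta_ra[sets[[i]]] / sum(meta_ra[sets[[i]]])
    # the island pool feeds all of the island's local communities, so its
    # effective size is the island-wide community, not a single local one
    pool_size <- local_size * max(1, sum(islands == i))
    pool[[i]] <- stats::setNames(neutral_local_freq(p_src, m1, pool_size),
                                 sets[[i]])
  }
  out <- matrix(0, length(species), length(islands),
                dimnames = list(species, NULL))
  for (j in seq_along(islands)) {
    i <- islands[j]
    w <- stats::setNames(numeric(length(species)), species)
    w[sets[[i]]] <- m2 * pool[[i]]
    w <- w + m1 * meta_ra / sum(meta_ra)
    out[, j] <- draw_fixed_richness(w, min(richness, length(species)),
                                    local_size)
  }
  out
}

#' Simulate drift-governed local communities
#'
#' Every local community is a neutral sample from the regional
#' metacommunity at a moderate immigration rate (`m`, default 0.5): half of
#' the individuals are replaced from the large regional pool, so turnovers
#' among the communities reflect ecological drift, neither homogenised nor
#' limited by dispersal.
#'
#' @param meta_ra Named metacommunity relative abundances of the
#'   drift-governed species.
#' @param n_locals Number of local communities.
#' @param m Immigration rate (default 0.5).
#' @param local_size,richness Individuals and species per local community.
#' @param seed Integer seed.
#' @return Matrix species x local communities of counts.
#' @export
drift_communities <- function(meta_ra, n_locals, m = 0.5, local_size = 2000,
                              richness = 100, seed = 1) {
  set.seed(as.integer(seed))
  species <- names(meta_ra)
  out <- matrix(0, length(species), n_locals,
                dimnames = list(species, NULL))
  for (j in seq_len(n_locals)) {
    p_loc <- neutral_local_freq(meta_ra / sum(meta_ra), m, local_size)
    out[, j] <- draw_fixed_richness(p_loc, min(richness, length(species)),
                                    local_size)
  }
  out
}

# largest-remainder split of `total` into parts proportional to fractions,
# guaranteeing a nonzero part for every nonzero fraction
split_total <- function(total, fractions) {
  raw <- total * fractions
  base <- floor(raw)
  base[fractions > 0 & base == 0] <- 1
  diffn <- total - sum(base)
  if (diffn > 0) {
    add <- order(-(raw - floor(raw)))
    for (i in add) {
      if (diffn == 0) break
      if (fractions[i] > 0) { base[i] <- base[i] + 1; diffn <- diffn - 1 }
    }
  } else if (diffn < 0) {
    rem <- order(raw - floor(raw))
    for (i in rem) {
      if (diffn == 0) break
      if (base[i] > 1) { base[i] <- base[i] - 1; diffn <- diffn + 1 }
    }
  }
  base
}

#' Simulate one benchmark dataset
#'
#' Builds the 24-sample community table (plots LA, LB, HA, HB x 6
#' replicates) for one situation: each local community holds exactly
#' `local_size` individuals of `richness` species, split across the
#' process-governed species pools in the situation's proportions.
#' Selection abundances are deterministic per plot (Gaussian filtering, or
#' the competition ranking for competition species); dispersal and drift
#' components are sampled as documented in [dispersal_communities()] and
#' [drift_communities()].
#'
#' @param tree Regional-pool phylogeny.
#' @param trait Named niche-optimum trait `E_i` in `[0, 1]`.
#' @param mix Named fractions `c(selection=, dispersal=, drift=)`.
#' @param preset Parameter list from [sim_preset()].
#' @param seed Integer seed.
#' @param competition_fraction Competition share within selection.
#' @return List of class `sim_dataset`: `table` (counts, zero rows
#'   dropped), `tree` (pruned), `trait`, `types`, `plots`, `islands`,
#'   `env`, `expected` (per-pair expected process importance), `mix`.
#' @export
simulate_dataset <- function(tree, trait, mix, preset = sim_preset("desk"),
                             seed = 1, competition_fraction = 0) {
  set.seed(as.integer(seed))
  species <- tree$tip.label
  meta_ra <- stats::setNames(
    mzsm_metacommunity(length(species), preset$J, preset$theta,
                       seed = seed + 11), species)
  dist <- cophenetic_distances(tree)
  types <- assign_species_types(meta_ra, dist, mix, ds = preset$ds,
                                seed = seed + 23,
                                competition_fraction = competition_fraction)

  plots <- rep(c("LA", "LB", "HA", "HB"), each = preset$n_reps)
  samples <- paste0(plots, seq_len(preset$n_reps))
  islands <- ifelse(plots %in% c("LA", "HA"), "A", "B")
  env <- preset$ev[substr(plots, 1, 1)]
  names(plots) <- names(islands) <- names(env) <- samples

  fr <- c(selection = mix[["selection"]], dispersal = mix[["dispersal"]],
          drift = mix[["drift"]])
  ind <- split_total(preset$local_size, fr)
  ric <- split_total(preset$richness, fr)

  comm <- matrix(0, length(species), length(samples),
                 dimnames = list(species, samples))

  # selection: deterministic per plot, identical across replicates.
  # The Gaussian filter acts on the whole filtering pool at once, so the
  # local selection component concentrates, with graded weights, on the
  # pool species whose optima lie nearest the plot's environment.
  if (fr[["selection"]] > 0) {
    sel_sp <- names(types)[types == "selection"]
    comp_sp <- names(types)[types == "competition"]
    n_comp_ind <- round(ind[["selection"]] * competition_fraction)
    n_comp_ric <- round(ric[["selection"]] * competition_fraction)
    if (length(comp_sp) == 0) { n_comp_ind <- 0; n_comp_ric <- 0 }
    n_fil_ind <- ind[["selection"]] - n_comp_ind
    n_fil_ric <- ric[["selection"]] - n_comp_ric
    for (pl in unique(plots)) {
      ev <- preset$ev[[substr(pl, 1, 1)]]
      vec <- numeric(length(species))
      if (n_fil_ric > 0 && length(sel_sp) > 0) {
        w <- selection_abundances(ev, trait[sel_sp], preset$sigma_E)
        cnt <- deterministic_fixed_richness(w, min(n_fil_ric, length(sel_sp)),
                                            n_fil_ind, sel_sp)
        vec[match(sel_sp, species)] <- cnt
      }
      if (n_comp_ric > 0 && length(comp_sp) > 0) {
        cr <- competition_ranking(ev, trait[comp_sp],
                                  n_rank = min(n_comp_ric, length(comp_sp)),
                                  seed = seed + 31 + match(pl, unique(plots)))
        cnt <- deterministic_fixed_richness(
          stats::setNames(cr$abundance, cr$species)[cr$species],
          length(cr$species), n_comp_ind, cr$species)
        vec[match(cr$species, species)] <- vec[match(cr$species, species)] + cnt
      }
      comm[, plots == pl] <- comm[, plots == pl] + vec
    }
  }

  if (fr[["dispersal"]] > 0) {
    dsp <- names(types)[types == "dispersal"]
    dc <- dispersal_communities(meta_ra[dsp], islands, preset$m1, preset$m2,
                                local_size = ind[["dispersal"]],
                                richness = ric[["dispersal"]],
                                seed = seed + 47)
    comm[match(dsp, species), ] <- comm[match(dsp, species), ] + dc
  }

  if (fr[["drift"]] > 0) {
    drf <- names(types)[types == "drift"]
    rc <- drift_communities(meta_ra[drf], length(samples), preset$m_drift,
                            local_size = ind[["drift"]],
                            richness = ric[["drift"]], seed = seed + 59)
    comm[match(drf, species), ] <- comm[match(drf, species), ] + rc
  }

  keep <- rowSums(comm) > 0
  comm <- comm[keep, , drop = FALSE]
  tree_obs <- ape::keep.tip(tree, rownames(comm))
  table <- community_table(comm[tree_obs$tip.label, , drop = FALSE])

  types_obs <- types[rownames(comm)]
  attr(types_obs, "cluster") <- attr(types, "cluster")[rownames(comm)]
  ds <- structure(list(table = table, tree = tree_obs,
                       trait = trait[rownames(comm)],
                       types = types_obs,
                       plots = plots, islands = islands, env = env,
                       mix = mix, seed = seed),
                  class = "sim_dataset")
  ds$expected <- expected_importance(ds)
  ds
}

#' Expected per-pair process importance of a simulated dataset
#'
#' For every pair of samples, the expected importance of a process is the
#' mean relative abundance of the species it governs: selection species
#' count as homogeneous selection within the same environment and
#' heterogeneous selection across environments; dispersal species as
#' homogenizing dispersal within an island and dispersal limitation across
#' islands; drift species as drift. Competition species are booked under
#' selection (HoS/HeS by pair geometry) without a separate label.
#'
#' @param dataset A `sim_dataset`.
#' @return Data frame per pair: expected importance of the five processes
#'   (summing to 1), expected stochasticity, and expected dominant process.
#' @export
expected_importance <- function(dataset) {
  m <- unclass(dataset$table)
  rel <- sweep(m, 2, colSums(m), "/")
  types <- dataset$types[rownames(m)]
  n <- ncol(m)
  samples <- colnames(m)
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  sel_mask <- types %in% c("selection", "competition")
  dsp_mask <- types == "dispersal"
  drf_mask <- types == "drift"
  mw <- (rel[, pr[, 1], drop = FALSE] + rel[, pr[, 2], drop = FALSE]) / 2
  sel_w <- colSums(mw[sel_mask, , drop = FALSE])
  dsp_w <- colSums(mw[dsp_mask, , drop = FALSE])
  drf_w <- colSums(mw[drf_mask, , drop = FALSE])
  same_env <- dataset$env[samples[pr[, 1]]] == dataset$env[samples[pr[, 2]]]
  same_isl <- dataset$islands[samples[pr[, 1]]] ==
    dataset$islands[samples[pr[, 2]]]
  ep <- data.frame(sample_u = samples[pr[, 1]], sample_v = samples[pr[, 2]],
                   HeS = ifelse(same_env, 0, sel_w),
                   HoS = ifelse(same_env, sel_w, 0),
                   DL = ifelse(same_isl, 0, dsp_w),
                   HD = ifelse(same_isl, dsp_w, 0),
                   DR = drf_w)
  ep$stochasticity <- ep$DL + ep$HD + ep$DR
  ep$dominant <- apply(as.matrix(ep[, PROCESSES]), 1, function(p)
    PROCESSES[which.max(p)])
  ep
}

#' Generate a full benchmark scenario
#'
#' One phylogeny and trait (per the scenario's phylogenetic-signal level)
#' shared across the scenario's 15 situations, each simulated with its own
#' derived seed.
#'
#' @param scenario `"LPS"`, `"MPS"`, or `"HPS"`.
#' @param seed Master seed.
#' @param preset Parameter list from [sim_preset()].
#' @param situations Data frame as from [situation_mixes()] (subsettable
#'   for quick runs).
#' @param competition_fraction Competition share within selection.
#' @return List of class `sim_benchmark`: `tree`, `trait`, `K`, `datasets`
#'   (one `sim_dataset` per situation, named by situation label).
#' @export
generate_benchmark <- function(scenario = c("MPS", "HPS", "LPS"), seed = 1,
                               preset = sim_preset("desk"),
                               situations = situation_mixes(),
                               competition_fraction = 0) {
  scenario <- match.arg(scenario)
  tree <- simulate_tree(preset$n_tips, seed = seed)
  tr <- simulate_trait(tree, scenario, seed = seed + 101)
  datasets <- list()
  for (i in seq_len(nrow(situations))) {
    mix <- c(selection = situations$selection[i],
             dispersal = situations$dispersal[i],
             drift = situations$drift[i])
    datasets[[situations$situation[i]]] <-
      simulate_dataset(tree, tr$trait, mix, preset = preset,
                       seed = seed + 1000 * i,
                       competition_fraction = competition_fraction)
  }
  structure(list(scenario = scenario, tree = tree, trait = tr$trait,
                 K = tr$K, datasets = datasets, seed = seed),
            class = "sim_benchmark")
}
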