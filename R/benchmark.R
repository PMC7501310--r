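#' Run the bin-based analysis over a benchmark and pool against truth
#'
#' Applies [run_icamp()] to every situation of a simulated benchmark and
#' joins the per-pair estimates with the simulator's expected importance.
#'
#' @param bench A `sim_benchmark` from [generate_benchmark()].
#' @param nmin,ds,n_rand,null_scope,algorithm Analysis settings (defaults:
#'   the benchmark evaluation settings nmin = 24, ds = 0.2, 200
#'   randomizations, within-bin shuffle).
#' @param seed Analysis seed.
#' @return List: `estimated` and `expected` (row-aligned pooled per-pair
#'   tables with a `situation` column).
#' @export
icamp_benchmark <- function(bench, nmin = 24, ds = 0.2, n_rand = 200,
                            null_scope = "within_bin", algorithm = "tree",
                            seed = 1) {
  est_all <- NULL; exp_all <- NULL
  for (nm in names(bench$datasets)) {
    d <- bench$datasets[[nm]]
    res <- run_icamp(d$table, d$tree, ds = ds, nmin = nmin, n_rand = n_rand,
                     null_scope = null_scope, algorithm = algorithm,
                     seed = seed)
    pw <- res$pairwise
    ex <- d$expected[match(pair_key(pw$sample_u, pw$sample_v),
                           pair_key(d$expected$sample_u,
                                    d$expected$sample_v)), ]
    pw$situation <- nm; ex$situation <- nm
    est_all <- rbind(est_all, pw); exp_all <- rbind(exp_all, ex)
  }
  list(estimated = est_all, expected = exp_all)
}

#' Score a pooled benchmark run
#'
#' Computes the quantitative (concordance-based) scores for stochasticity
#' and for each process's per-pair relative importance, and the qualitative
#' one-vs-rest scores for the dominant process, pooled over situations.
#'
#' @param pooled Output of [icamp_benchmark()].
#' @return List: `stochasticity` (qACC, qPRC), `per_process` (data frame),
#'   `qualitative` (ACC, PRC, SST, SPC), `n_pairs`.
#' @export
benchmark_scores <- function(pooled) {
  score_against_truth(pooled$estimated, pooled$expected)
}

#' Run the entire-community baseline over a benchmark
#'
#' Applies [qpen()] to every situation and scores the within-plot group
#' fractions against the expected importance averaged over each group's
#' pairs (the baseline estimates importance per group of turnovers, not
#' per turnover).
#'
#' @param bench A `sim_benchmark`.
#' @param n_rand Randomizations (default 200).
#' @param seed Analysis seed.
#' @return List: `estimated`, `expected` (group-level tables), plus
#'   `qualitative` and `per_process` scores over groups.
#' @export
qpen_benchmark <- function(bench, n_rand = 200, seed = 1) {
  est_all <- NULL; exp_all <- NULL
  for (nm in names(bench$datasets)) {
    d <- bench$datasets[[nm]]
    qr <- qpen(d$table, d$tree, n_rand = n_rand, seed = seed)
    gr <- qpen_groups(qr, d$plots)
    ex <- d$expected
    gu <- d$plots[ex$sample_u]; gv <- d$plots[ex$sample_v]
    exg <- do.call(rbind, lapply(gr$group, function(g) {
      sel <- gu == g & gv == g
      ep <- colMeans(ex[sel, PROCESSES])
      data.frame(group = g, t(ep), stochasticity = sum(ep[c("HD","DL","DR")]),
                 dominant = dominant_process(ep), check.names = FALSE)
    }))
    gr$situation <- nm; exg$situation <- nm
    est_all <- rbind(est_all, gr); exp_all <- rbind(exp_all, exg)
  }
  ql <- qualitative_scores(exp_all$dominant, est_all$dominant)
  pp <- do.call(rbind, lapply(PROCESSES, function(tau) {
    qs <- suppressWarnings(quantitative_scores(exp_all[[tau]],
                                               est_all[[tau]]))
    data.frame(process = tau, qACC = qs$qACC, qPRC = qs$qPRC)
  }))
  list(estimated = est_all, expected = exp_all, qualitative = ql,
       per_process = pp)
}
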