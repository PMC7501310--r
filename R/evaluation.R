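#' Quantitative accuracy and precision (concordance-based)
#'
#' qACC = 2 s_x s_y / (s_x^2 + s_y^2 + (m_x - m_y)^2) penalises both
#' location and scale disagreement between expected (x) and estimated (y)
#' values; qPRC = cov(x, y) / (s_x s_y) is the Pearson correlation.
#' Population moments (divide by n) are used, the concordance-
#' correlation-coefficient convention; qACC * qPRC then equals the CCC.
#'
#' @param expected,estimated Equal-length numeric vectors.
#' @return `list(qACC=, qPRC=)`; `qPRC` is `NA` (with a warning) when
#'   either vector has zero variance.
#' @export
quantitative_scores <- function(expected, estimated) {
  x <- expected; y <- estimated
  if (length(x) != length(y)) stop("expected and estimated lengths differ")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  sx <- sqrt(vx); sy <- sqrt(vy)
  qacc <- 2 * sx * sy / (vx + vy + (mx - my)^2)
  if (sx == 0 || sy == 0) {
    warning("zero variance: qPRC undefined")
    qprc <- NA_real_
  } else {
    qprc <- cxy / (sx * sy)
  }
  list(qACC = qacc, qPRC = qprc)
}

#' Qualitative performance from dominant-process labels
#'
#' One-vs-rest confusion counting over turnovers: a turnover whose true
#' dominant process is correctly identified yields a true positive for
#' that process and a true negative for each other process; a wrong call
#' yields a false positive for the called process, a false negative for
#' the true one, and true negatives for the rest. Overall accuracy,
#' precision (positive predictive value), sensitivity (true positive rate)
#' and specificity (true negative rate) are computed from the cells summed
#' over processes.
#'
#' @param expected,estimated Character vectors of dominant-process labels.
#' @param processes Label universe (default the five assembly processes).
#' @return List with overall `ACC`, `PRC`, `SST`, `SPC`, and a per-process
#'   data frame of `TP`, `TN`, `FP`, `FN`.
#' @export
qualitative_scores <- function(expected, estimated, processes = PROCESSES) {
  if (length(expected) != length(estimated)) stop("label lengths differ")
  cells <- t(vapply(processes, function(tau) {
    tp <- sum(expected == tau & estimated == tau)
    fp <- sum(expected != tau & estimated == tau)
    fn <- sum(expected == tau & estimated != tau)
    tn <- sum(expected != tau & estimated != tau)
    c(TP = tp, TN = tn, FP = fp, FN = fn)
  }, numeric(4)))
  tot <- colSums(cells)
  per <- data.frame(process = processes, cells)
  list(ACC = (tot[["TP"]] + tot[["TN"]]) / sum(tot),
       PRC = tot[["TP"]] / (tot[["TP"]] + tot[["FP"]]),
       SST = tot[["TP"]] / (tot[["TP"]] + tot[["FN"]]),
       SPC = tot[["TN"]] / (tot[["TN"]] + tot[["FP"]]),
       per_process = per)
}

#' One-side bootstrap comparison of two score vectors
#'
#' Resamples the paired situations with replacement `n_boot` times and
#' reports the fraction of replicates where mean(A) <= mean(B): a small p
#' supports A > B.
#'
#' @param scoresA,scoresB Per-situation score vectors (recycled pairing not
#'   required to be equal length; each is resampled from itself).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return One-side p value.
#' @export
bootstrap_compare <- function(scoresA, scoresB, n_boot = 1000, seed = 1) {
  set.seed(as.integer(seed))
  le <- vapply(seq_len(n_boot), function(i) {
    mean(sample(scoresA, length(scoresA), replace = TRUE)) <=
      mean(sample(scoresB, length(scoresB), replace = TRUE))
  }, logical(1))
  mean(le)
}

#' Cohen's d effect size with magnitude class
#'
#' d = (mean(x) - mean(y)) / pooled sd; the magnitude is large when
#' |d| > 0.8, medium when 0.5 < |d| <= 0.8, small when 0.2 < |d| <= 0.5,
#' and negligible when |d| <= 0.2 (boundaries belong to the lower class).
#'
#' @param x,y Numeric vectors.
#' @return `list(d=, magnitude=)`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  d <- if (sp == 0) 0 else (mean(x) - mean(y)) / sp
  a <- abs(d)
  magnitude <- if (a > 0.8) "large" else if (a > 0.5) "medium" else
    if (a > 0.2) "small" else "negligible"
  list(d = d, magnitude = magnitude)
}

#' Permutational two-sample test
#'
#' Permutes the group labels `n_perm` times and compares the absolute mean
#' difference with the observed one (two-side by default).
#'
#' @param x,y Numeric vectors.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"` (mean(x) >
#'   mean(y)).
#' @return Permutation p value in `[1/(n_perm+1), 1]`.
#' @export
permutation_test <- function(x, y, n_perm = 1000, seed = 1,
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  set.seed(as.integer(seed))
  pooled <- c(x, y)
  nx <- length(x)
  stat <- function(a, b) mean(a) - mean(b)
  obs <- stat(x, y)
  count <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), nx)
    s <- stat(pooled[idx], pooled[-idx])
    hit <- if (alternative == "two.sided") abs(s) >= abs(obs) else s >= obs
    if (hit) count <- count + 1L
  }
  (count + 1) / (n_perm + 1)
}

#' Score estimated against expected process importance
#'
#' Convenience wrapper joining an estimated per-pair importance table (as
#' in `run_icamp()$pairwise`) with the simulator's expected table and
#' computing quantitative scores for stochasticity and each process, plus
#' qualitative scores for the dominant process.
#'
#' @param estimated Data frame with `sample_u`, `sample_v`, the five
#'   process columns, and `stochasticity`.
#' @param expected Data frame from [expected_importance()].
#' @return List: `stochasticity` (qACC/qPRC), `per_process` (data frame),
#'   `qualitative` (overall ACC/PRC/SST/SPC), `n_pairs`.
#' @export
score_against_truth <- function(estimated, expected) {
  key_e <- pair_key(estimated$sample_u, estimated$sample_v)
  key_x <- pair_key(expected$sample_u, expected$sample_v)
  if (!is.null(estimated$situation) && !is.null(expected$situation)) {
    key_e <- paste(estimated$situation, key_e)
    key_x <- paste(expected$situation, key_x)
  }
  idx <- match(key_e, key_x)
  if (anyNA(idx)) stop("estimated pairs missing from expected table")
  expected <- expected[idx, ]
  st <- quantitative_scores(expected$stochasticity, estimated$stochasticity)
  pp <- do.call(rbind, lapply(PROCESSES, function(tau) {
    qs <- suppressWarnings(quantitative_scores(expected[[tau]],
                                               estimated[[tau]]))
    data.frame(process = tau, qACC = qs$qACC, qPRC = qs$qPRC)
  }))
  est_dom <- apply(as.matrix(estimated[, PROCESSES]), 1, function(p)
    PROCESSES[which.max(p)])
  ql <- qualitative_scores(expected$dominant, est_dom)
  list(stochasticity = st, per_process = pp, qualitative = ql,
       n_pairs = nrow(estimated))
}
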