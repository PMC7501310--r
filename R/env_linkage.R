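#' Pairwise difference and mean matrices for environmental factors
#'
#' For each factor, both the between-sample variation |f_u - f_v| and the
#' between-sample mean (f_u + f_v)/2 are candidate explanatory distance
#' matrices for process importance.
#'
#' @param env Numeric matrix samples x factors (or named vector).
#' @return List per factor: `list(diff = matrix, mean = matrix)`.
#' @export
pair_factor_matrices <- function(env) {
  if (is.null(dim(env))) env <- cbind(factor = env)
  out <- lapply(colnames(env), function(f) {
    x <- env[, f]
    list(diff = abs(outer(x, x, "-")),
         mean = outer(x, x, "+") / 2)
  })
  names(out) <- colnames(env)
  out
}

#' Shifted natural-log transform tolerating zero and negative values
#'
#' Subtracts the minimum value, replaces resulting zeros by 0.05 times the
#' minimum positive value (so the smallest value maps to
#' log(0.05 * next-smallest), i.e. about -3.00 natural-log units below it),
#' and takes the natural log. Monotone order is preserved.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Log-transformed vector.
#' @export
log_shift_transform <- function(x) {
  if (length(unique(x)) < 2) stop("degenerate input: all values equal")
  y <- x - min(x)
  minpos <- min(y[y > 0])
  y[y == 0] <- 0.05 * minpos
  log(y)
}

# block-restricted permutation of sample indices
block_permutation <- function(n, blocks) {
  perm <- seq_len(n)
  if (is.null(blocks)) return(sample.int(n))
  for (idx in split(seq_len(n), blocks)) {
    perm[idx] <- idx[sample.int(length(idx))]
  }
  perm
}

lower_vec <- function(m) m[lower.tri(m)]

#' Mantel test with block-constrained permutation
#'
#' Pearson correlation between the lower triangles of a process-importance
#' pair matrix and a factor pair matrix; significance by permuting sample
#' order, restricted within blocks when the design has repeated measures
#' (e.g. plot identity). `model = "logit"` applies a quasibinomial
#' logit-link regression of the fractions on the factor and correlates the
#' fitted scale instead, for importance values compressed near 0 or 1.
#'
#' @param proc Symmetric matrix of pairwise process importance.
#' @param factor_mat Symmetric factor matrix (difference or mean form).
#' @param n_perm Number of permutations (default 999).
#' @param blocks Optional block label per sample.
#' @param seed Integer seed.
#' @param model `"linear"` (default) or `"logit"`.
#' @return `list(R2=, r=, p=)` (two-side permutation p).
#' @export
mantel_constrained <- function(proc, factor_mat, n_perm = 999, blocks = NULL,
                               seed = 1, model = c("linear", "logit")) {
  model <- match.arg(model)
  set.seed(as.integer(seed))
  n <- nrow(proc)
  y <- lower_vec(proc)
  if (model == "logit") {
    # quasibinomial logit-link view of the fractions: correlate on the
    # linear-predictor (logit) scale, where the link is the identity
    eps <- 1e-6
    y <- stats::qlogis(pmin(pmax(y, eps), 1 - eps))
  }
  x <- lower_vec(factor_mat)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(R2 = NA_real_, r = NA_real_, p = NA_real_))
  r_obs <- stats::cor(x, y)
  count <- 0L
  for (i in seq_len(n_perm)) {
    p <- block_permutation(n, blocks)
    r_null <- stats::cor(lower_vec(factor_mat[p, p]), y)
    if (abs(r_null) >= abs(r_obs)) count <- count + 1L
  }
  list(R2 = r_obs^2, r = r_obs, p = (count + 1) / (n_perm + 1))
}

#' Partial Mantel test with block-constrained permutation
#'
#' Correlates the residuals of the process and factor matrices after
#' removing their linear dependence on a control matrix, with the same
#' restricted permutation scheme as [mantel_constrained()].
#'
#' @param proc,factor_mat,control Symmetric pair matrices.
#' @inheritParams mantel_constrained
#' @return `list(R2=, r=, p=)`.
#' @export
partial_mantel_constrained <- function(proc, factor_mat, control,
                                       n_perm = 999, blocks = NULL, seed = 1) {
  set.seed(as.integer(seed))
  n <- nrow(proc)
  z <- lower_vec(control)
  resid_on <- function(v) stats::resid(stats::lm(v ~ z))
  y <- resid_on(lower_vec(proc))
  x <- resid_on(lower_vec(factor_mat))
  # a factor that the control explains entirely (e.g. the control itself)
  # leaves only numerical noise: report zero partial correlation
  if (stats::sd(x) <= 1e-10 * max(stats::sd(lower_vec(factor_mat)), 1) ||
      stats::sd(y) <= 1e-10 * max(stats::sd(lower_vec(proc)), 1))
    return(list(R2 = 0, r = 0, p = NA_real_))
  r_obs <- stats::cor(x, y)
  count <- 0L
  for (i in seq_len(n_perm)) {
    p <- block_permutation(n, blocks)
    xp <- resid_on(lower_vec(factor_mat[p, p]))
    if (abs(stats::cor(xp, y)) >= abs(r_obs)) count <- count + 1L
  }
  list(R2 = r_obs^2, r = r_obs, p = (count + 1) / (n_perm + 1))
}

#' Multiple regression on distance matrices with forward AIC selection
#'
#' Regresses the vectorised process matrix on standardised (zero-mean,
#' unit-variance) vectorised factor matrices. Factors enter the model one
#' at a time, each step adding the factor that most reduces AIC, stopping
#' when no addition improves it. Per-coefficient p values come from
#' block-restricted permutation of the response matrix.
#'
#' @param proc Symmetric process-importance pair matrix.
#' @param factors Named list of symmetric factor matrices.
#' @param n_perm Number of permutations (default 999).
#' @param blocks Optional block label per sample.
#' @param seed Integer seed.
#' @return List: `terms` (selected factor names in entry order),
#'   `coefficients` (standardised b per term), `R2`, `p` (per-term
#'   permutation p), `aic`.
#' @export
mrm_forward_aic <- function(proc, factors, n_perm = 999, blocks = NULL,
                            seed = 1) {
  set.seed(as.integer(seed))
  n <- nrow(proc)
  y <- lower_vec(proc)
  Xs <- lapply(factors, function(m) {
    v <- lower_vec(m)
    if (stats::sd(v) == 0) return(NULL)
    (v - mean(v)) / stats::sd(v)
  })
  Xs <- Xs[!vapply(Xs, is.null, logical(1))]
  chosen <- character(0)
  current_aic <- stats::AIC(stats::lm(y ~ 1))
  repeat {
    remaining <- setdiff(names(Xs), chosen)
    if (length(remaining) == 0) break
    aics <- vapply(remaining, function(f) {
      X <- do.call(cbind, Xs[c(chosen, f)])
      stats::AIC(stats::lm(y ~ X))
    }, numeric(1))
    if (min(aics) >= current_aic) break
    chosen <- c(chosen, remaining[which.min(aics)])
    current_aic <- min(aics)
  }
  if (length(chosen) == 0)
    return(list(terms = character(0), coefficients = numeric(0),
                R2 = 0, p = numeric(0), aic = current_aic))
  X <- do.call(cbind, Xs[chosen])
  colnames(X) <- chosen
  fit <- stats::lm(y ~ X)
  b_obs <- stats::coef(fit)[-1]
  names(b_obs) <- chosen
  r2 <- summary(fit)$r.squared
  # permutation p per coefficient: permute the response matrix within blocks
  exceed <- stats::setNames(integer(length(chosen)), chosen)
  for (i in seq_len(n_perm)) {
    p <- block_permutation(n, blocks)
    yp <- lower_vec(proc[p, p])
    bp <- stats::coef(stats::lm(yp ~ X))[-1]
    exceed <- exceed + (abs(bp) >= abs(b_obs))
  }
  list(terms = chosen, coefficients = b_obs, R2 = r2,
       p = (exceed + 1) / (n_perm + 1), aic = current_aic)
}
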