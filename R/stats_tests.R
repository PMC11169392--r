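# All permutations of 1..n as an (n! x n) matrix; n is small (<= 8).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- nrow(sub)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * r + 1L):(i * r)
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow = r)
  }
  out
}

#' Spearman rank correlation with an exact small-sample p-value
#'
#' Ranks use the average-rank convention for ties. For `n <= exact_max`
#' (default 8) the two-sided p-value is computed by full enumeration of
#' all `n!` permutations of one margin (proportion of permutations with
#' `|r|` at least the observed `|r|`); for larger `n` the usual
#' t-approximation `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom is used. Branch and convention are recorded in the result.
#'
#' @param x,y Paired numeric vectors, finite, length >= 3.
#' @param exact_max Largest `n` for the enumeration branch.
#' @return List with `r`, `p` (two-sided), `n`, `method`.
#' @export
spearman_correlation <- function(x, y, exact_max = 8L) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("constant vector: rank correlation undefined")
  }
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    s_perm <- matrix(ryc[perms], nrow = nrow(perms)) %*% rxc
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    r_perm <- as.numeric(s_perm) / denom
    p <- mean(abs(r_perm) >= abs(r) - 1e-12)
    method <- "spearman_exact_permutation"
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "spearman_t_approximation"
  }
  list(r = r, p = min(p, 1), n = n, method = method)
}

#' Mann-Whitney U test with an exact small-sample branch
#'
#' Two-sided comparison of two independent groups on ranks (average-rank
#' ties). For combined `n <= exact_max` (default 12) the p-value is the
#' exact permutation probability over all group assignments of observing
#' a U statistic at least as far from its null mean as the observed one;
#' for larger samples the normal approximation with tie correction and
#' continuity correction is used (via [stats::wilcox.test()]).
#'
#' @param x,y Numeric vectors for the two groups.
#' @param exact_max Largest combined sample size for full enumeration.
#' @return List with `U` (for the first group), `p` (two-sided), `n1`,
#'   `n2`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("empty group")
  ranks <- rank(c(x, y))
  U <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_max) {
    mu <- n1 * n2 / 2
    combs <- utils::combn(n1 + n2, n1)
    U_perm <- colSums(matrix(ranks[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(U_perm - mu) >= abs(U - mu) - 1e-9)
    method <- "mann_whitney_exact_permutation"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    method <- "mann_whitney_normal_approximation"
  }
  list(U = U, p = min(p, 1), n1 = n1, n2 = n2, method = method)
}

#' Wilcoxon matched-pairs signed-rank test with an exact branch
#'
#' Two-sided paired test. Zero differences are dropped; ranks of the
#' absolute differences use the average-rank convention. For up to
#' `exact_max` informative pairs (default 12) the p-value is computed by
#' full enumeration of all `2^n` sign assignments; otherwise the normal
#' approximation with continuity correction is used (via
#' [stats::wilcox.test()]).
#'
#' @param x,y Paired numeric vectors.
#' @param exact_max Largest number of informative pairs for enumeration.
#' @return List with `W` (sum of positive-difference ranks), `p`
#'   (two-sided), `n` (informative pairs), `method`.
#' @export
wilcoxon_signed_rank_paired <- function(x, y, exact_max = 12L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n < 3L) {
    stop("all differences zero (or fewer than 3 informative pairs): ",
         "no difference detectable")
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    mu <- n * (n + 1) / 4
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W_perm <- as.numeric(signs %*% r)
    p <- mean(abs(W_perm - mu) >= abs(W - mu) - 1e-9)
    method <- "wilcoxon_exact_sign_flip"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                         correct = TRUE))$p.value
    method <- "wilcoxon_normal_approximation"
  }
  list(W = W, p = min(p, 1), n = n, method = method)
}

#' Age-adjust a phenotype by OLS residualisation
#'
#' Removes the linear age trend from a phenotype: the adjusted values are
#' the residuals of an ordinary least-squares regression of the value on
#' age, shifted back to the cohort mean so the adjusted variable keeps
#' the original location.
#'
#' @param values Numeric phenotype vector (e.g. BMI in kg/m^2).
#' @param age Numeric age vector (years), same length, non-constant.
#' @return Adjusted numeric vector.
#' @export
age_adjust <- function(values, age) {
  stopifnot(length(values) == length(age))
  if (length(values) < 3L) stop("need at least 3 observations")
  if (length(unique(age)) == 1L) stop("constant age: adjustment undefined")
  fit <- stats::lm(values ~ age)
  unname(stats::residuals(fit)) + mean(values)
}
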