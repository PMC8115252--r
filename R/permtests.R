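# Permutation-test containers and scalar permutation tests.

new_perm_result <- function(statistic, null, p, tails, convention, n_perm,
                            seed = NA_integer_) {
  structure(list(statistic = statistic, null = null, p = p, tails = tails,
                 convention = convention, n_perm = n_perm, seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %s-tailed): statistic = %.4g, p = %.4g (%d permutations)\n",
              x$convention, x$tails, x$statistic, x$p, x$n_perm))
  invisible(x)
}

#' @export
tidy.perm_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p, tails = x$tails,
                 convention = x$convention, n_perm = x$n_perm)
}

# All permutations of 1..n as a matrix (n! rows); used for exhaustive tests.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

one_sample_t <- function(x) {
  s <- sd(x)
  if (s == 0) stop("zero-variance input", call. = FALSE)
  mean(x) / (s / sqrt(length(x)))
}

# t statistic for sign-flipped null samples: a flip pattern can make the
# flipped values constant even when the input is not (e.g. n = 2 with
# values -1, 1); the statistic is then +/-Inf, or 0 for all-zero values.
one_sample_t_null <- function(x) {
  s <- sd(x)
  if (s == 0) {
    m <- mean(x)
    if (m == 0) return(0)
    return(sign(m) * Inf)
  }
  mean(x) / (s / sqrt(length(x)))
}

#' Sign-flip test of a group-average template expression
#'
#' One-sample t statistic on the per-subject expression values, with its
#' null generated by random sign flips (exhaustive enumeration of all 2^n
#' sign patterns when that is within the permutation budget). Two-tailed on
#' `|t|`.
#'
#' @param values Numeric vector (n >= 2) of per-subject statistics.
#' @param n_perm Permutation budget (default 10000).
#' @param seed Integer seed (Monte-Carlo mode only).
#' @return A `perm_result`.
#' @export
group_expression_test <- function(values, n_perm = 10000, seed = 1L) {
  n <- length(values)
  if (n < 2L) stop("need n >= 2", call. = FALSE)
  t_obs <- one_sample_t(values)
  eps <- 1e-12
  if (2^n <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    tnull <- apply(signs, 1, function(s) one_sample_t_null(values * s))
    p <- sum(abs(tnull) >= abs(t_obs) - eps) / nrow(signs)
    new_perm_result(t_obs, tnull, p, "two", "exhaustive", nrow(signs))
  } else {
    tnull <- with_seed(seed, {
      replicate(n_perm, one_sample_t_null(values * sample(c(-1, 1), n, TRUE)))
    })
    p <- (1 + sum(abs(tnull) >= abs(t_obs) - eps)) / (1 + n_perm)
    new_perm_result(t_obs, tnull, p, "two", "monte_carlo", n_perm, seed)
  }
}

#' Permutation test of a Pearson correlation
#'
#' Pearson r with its null generated by permuting `y` (exhaustive over all
#' n! orderings when within budget). One-tailed tests use the signed r in
#' the hypothesised direction.
#'
#' @param x,y Numeric vectors (n >= 3), both nonconstant.
#' @param tails `"two"` or `"one"`.
#' @param direction For one-tailed tests, `"positive"` or `"negative"`.
#' @param n_perm Permutation budget.
#' @param seed Integer seed (Monte-Carlo mode only).
#' @return A `perm_result`.
#' @export
perm_correlation <- function(x, y, tails = c("two", "one"),
                             direction = c("positive", "negative"),
                             n_perm = 10000, seed = 1L) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need equal-length vectors, n >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input", call. = FALSE)
  r_obs <- cor(x, y)
  eps <- 1e-12
  exceed <- function(rnull) {
    if (tails == "two") {
      sum(abs(rnull) >= abs(r_obs) - eps)
    } else if (direction == "positive") {
      sum(rnull >= r_obs - eps)
    } else {
      sum(rnull <= r_obs + eps)
    }
  }
  if (factorial(n) <= n_perm) {
    pm <- all_permutations(n)
    rnull <- apply(pm, 1, function(p) cor(x, y[p]))
    p <- exceed(rnull) / nrow(pm)
    new_perm_result(r_obs, rnull, p, tails, "exhaustive", nrow(pm))
  } else {
    rnull <- with_seed(seed, replicate(n_perm, cor(x, y[sample.int(n)])))
    p <- (1 + exceed(rnull)) / (1 + n_perm)
    new_perm_result(r_obs, rnull, p, tails, "monte_carlo", n_perm, seed)
  }
}
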