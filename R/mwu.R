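# Mann-Whitney U machinery.
#
# U is the rank-sum statistic for sample A with midranks for ties:
#   U = sum over pairs (a, b) of [a > b] + 0.5 [a == b],
# so 0 <= U <= nA*nB and U is a multiple of 0.5.  All internal arithmetic
# uses the doubled statistic 2U, which is an exact integer even under ties,
# so exact-mode and oracle p values are identical to the last bit.

# Doubled midranks of a combined sample: 2 * rank(..., "average") is integer.
doubled_midranks <- function(x) {
  as.integer(round(2 * rank(x, ties.method = "average")))
}

# Null distribution of S2 = sum of doubled midranks of sample A, over all
# C(N, nA) equally likely assignments of nA labels, by subset-sum counting.
# Returns counts[s + 1] = number of subsets of size nA with doubled-rank sum
# s.  Handles ties exactly (the DP runs on the observed midrank multiset).
mwu_null_counts <- function(d2, n_a) {
  n <- length(d2)
  smax <- sum(d2)
  # ways[k + 1, s + 1] = number of k-subsets with doubled sum s
  ways <- matrix(0, nrow = n_a + 1L, ncol = smax + 1L)
  ways[1L, 1L] <- 1
  for (di in d2) {
    kmax <- n_a  # 0/1 DP: iterate k downward implicitly via matrix shift
    upd <- ways[seq_len(kmax), , drop = FALSE]
    # shift columns right by di
    shifted <- matrix(0, nrow = kmax, ncol = smax + 1L)
    shifted[, (di + 1L):(smax + 1L)] <- upd[, seq_len(smax + 1L - di)]
    ways[2:(kmax + 1L), ] <- ways[2:(kmax + 1L), , drop = FALSE] + shifted
  }
  ways[n_a + 1L, ]
}

# Cache of untied null tail tables keyed by "nA.nB" (used by the vectorized
# per-voxel exact path, where the combined sample is tie-free).
.mwu_cache <- new.env(parent = emptyenv())

# P(2U >= u2) and P(2U <= u2) lookup tables for a tie-free comparison of
# sizes n_a, n_b.  2U ranges over even integers 0..2*nA*nB when no ties.
mwu_exact_tail_table <- function(n_a, n_b) {
  key <- paste0(n_a, ".", n_b)
  if (!is.null(.mwu_cache[[key]])) return(.mwu_cache[[key]])
  n <- n_a + n_b
  d2 <- 2L * seq_len(n)
  counts <- mwu_null_counts(d2, n_a)
  s <- seq_along(counts) - 1L
  u2 <- s - n_a * (n_a + 1L)           # 2U = S2 - nA(nA+1)
  keep <- u2 >= 0
  cnt <- counts[keep]
  total <- sum(cnt)
  tab <- list(
    u2 = u2[keep],
    p_ge = rev(cumsum(rev(cnt))) / total,
    p_le = cumsum(cnt) / total
  )
  .mwu_cache[[key]] <- tab
  tab
}

mwu_exact_p <- function(d2, n_a, s2_obs) {
  counts <- mwu_null_counts(d2, n_a)
  total <- sum(counts)
  s <- seq_along(counts) - 1L
  list(p_ge = sum(counts[s >= s2_obs]) / total,
       p_le = sum(counts[s <= s2_obs]) / total)
}

# Tie term sum(t^3 - t) over tie groups of a combined sample.
tie_term <- function(x) {
  t <- tabulate(match(x, unique(x)))
  sum(t^3 - t)
}

finish_mwu <- function(u, p_ge, p_le, alternative, method, n_a, n_b) {
  p_one <- switch(alternative,
                  a_greater = p_ge,
                  b_greater = p_le,
                  two_sided = min(p_ge, p_le))
  p_two <- min(1, 2 * min(p_ge, p_le))
  structure(list(U = u, p_one_sided = p_one, p_two_sided = p_two,
                 p = if (alternative == "two_sided") p_two else p_one,
                 alternative = alternative, method = method,
                 n_a = n_a, n_b = n_b),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (nA=%d, nB=%d), %s\n  p[%s] = %.4g, p[two-sided] = %.4g\n",
              x$U, x$n_a, x$n_b, x$method, x$alternative, x$p_one_sided,
              x$p_two_sided))
  invisible(x)
}

#' Mann-Whitney U rank test
#'
#' Two-sample rank test with midranks for ties. The exact null distribution
#' is computed by a subset-sum dynamic program over the observed (doubled)
#' midrank multiset, which is exact under arbitrary ties; for larger samples
#' the normal approximation with tie-corrected variance and a 0.5 continuity
#' correction is used. One-sided p values are tail probabilities of U in the
#' stated direction; the two-sided p is twice the smaller tail, capped at 1
#' (the midrank null distribution is symmetric about `nA*nB/2`).
#'
#' @param sample_a,sample_b Nonempty numeric vectors.
#' @param alternative `"two_sided"`, `"a_greater"` (A stochastically larger)
#'   or `"b_greater"`.
#' @param method `"auto"` chooses exact when `nA*nB <= exact_limit`,
#'   otherwise the normal approximation; `"exact"`/`"normal_approx"` force a
#'   path.
#' @param exact_limit Largest `nA*nB` for which `"auto"` uses the exact DP.
#' @param continuity Apply the 0.5 continuity correction in the normal
#'   approximation.
#' @return An object of class `mwu_result` with fields `U`, `p_one_sided`,
#'   `p_two_sided`, `p` (the one matching `alternative`), `method`, `n_a`,
#'   `n_b`.
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6), alternative = "b_greater")  # p = 0.05
#' @seealso [mwu_oracle()] for the brute-force enumeration this is verified
#'   against.
#' @export
mwu_test <- function(sample_a, sample_b,
                     alternative = c("two_sided", "a_greater", "b_greater"),
                     method = c("auto", "exact", "normal_approx"),
                     exact_limit = 400, continuity = TRUE) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  bbb_assert(length(a) >= 1 && length(b) >= 1, "bbbmap_parameter_error",
             "mwu_test: both samples must be nonempty")
  bbb_assert(all(is.finite(a)) && all(is.finite(b)), "bbbmap_data_error",
             "mwu_test: non-finite values")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  d2 <- doubled_midranks(c(a, b))
  s2 <- sum(d2[seq_len(n_a)])
  u2 <- s2 - n_a * (n_a + 1L)          # 2U, exact integer
  u <- u2 / 2

  use_exact <- method == "exact" || (method == "auto" && n_a * n_b <= exact_limit)
  if (use_exact) {
    p <- mwu_exact_p(d2, n_a, s2)
    return(finish_mwu(u, p$p_ge, p$p_le, alternative, "exact", n_a, n_b))
  }

  mu2 <- n_a * n_b                      # E[2U]
  tt <- tie_term(c(a, b))
  var2 <- 4 * (n_a * n_b / 12) * ((n + 1) - tt / (n * (n - 1)))  # Var(2U)
  if (var2 <= 0) {
    # all values identical across both samples: no evidence by convention
    bbb_log("rank_stats", "mwu_test", "degenerate all-tied samples; p = 1",
            level = "warn")
    return(finish_mwu(u, 1, 1, alternative, "normal_approx", n_a, n_b))
  }
  cc <- if (continuity) 1 else 0        # continuity correction on the 2U scale
  p_ge <- stats::pnorm((u2 - mu2 - cc) / sqrt(var2), lower.tail = FALSE)
  p_le <- stats::pnorm((u2 - mu2 + cc) / sqrt(var2), lower.tail = TRUE)
  finish_mwu(u, min(1, p_ge), min(1, p_le), alternative, "normal_approx",
             n_a, n_b)
}

#' Brute-force Mann-Whitney oracle
#'
#' Exact null p values by full enumeration of all `choose(nA+nB, nA)` label
#' assignments, with midranks for ties. Intended as an independent test
#' oracle for [mwu_test()]; limited to `nA + nB <= 12`.
#'
#' @inheritParams mwu_test
#' @return An `mwu_result` with `method = "oracle"`.
#' @export
mwu_oracle <- function(sample_a, sample_b,
                       alternative = c("two_sided", "a_greater", "b_greater")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  bbb_assert(length(a) >= 1 && length(b) >= 1, "bbbmap_parameter_error",
             "mwu_oracle: both samples must be nonempty")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  bbb_assert(n <= 12, "bbbmap_parameter_error",
             "mwu_oracle: nA + nB must be <= 12 (got %d)", n)
  d2 <- doubled_midranks(c(a, b))
  s2_obs <- sum(d2[seq_len(n_a)])
  idx <- utils::combn(n, n_a)
  s2_all <- colSums(matrix(d2[idx], nrow = n_a))
  p_ge <- mean(s2_all >= s2_obs)
  p_le <- mean(s2_all <= s2_obs)
  finish_mwu((s2_obs - n_a * (n_a + 1L)) / 2, p_ge, p_le, alternative,
             "oracle", n_a, n_b)
}
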