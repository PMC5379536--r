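#' Rank an expression profile once, with midranks and tie correction term
#'
#' Ranks a profile a single time so that many gene sets can subsequently be
#' tested against it in O(set size) each, instead of re-sorting the profile
#' for every set. Ties receive midranks (the mean of the rank positions they
#' span) and the tie correction term sum(t^3 - t) over tie groups is
#' precomputed for the rank-sum variance.
#'
#' @param values numeric vector of expression values for one sample, length
#'   >= 2.
#' @return an object of class `ranked_profile`: a list with `midranks`
#'   (numeric, same length), `tie_term` (sum over tie groups of t^3 - t) and
#'   `N` (profile length).
#' @examples
#' rp <- rank_profile(c(5, 5, 1))
#' rp$midranks  # 2.5 2.5 1.0
#' rp$tie_term  # 6
#' @export
rank_profile <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    stop("degenerate profile: need at least 2 numeric values")
  }
  if (anyNA(values)) stop("profile contains missing values")
  midranks <- rank(values, ties.method = "average")
  t <- tabulate(match(values, unique(values)))
  t <- t[t > 1L]
  structure(
    list(midranks = midranks,
         tie_term = if (length(t)) sum(t^3 - t) else 0,
         N = length(values)),
    class = "ranked_profile")
}

#' @export
print.ranked_profile <- function(x, ...) {
  cat("ranked_profile: N =", x$N, ", tie term =", x$tie_term, "\n")
  invisible(x)
}

# Shared tail machinery: log10 p from a z score, computed in log space so
# extreme z yields a finite value instead of underflowing to 0.
log10_tail <- function(z, lower) {
  stats::pnorm(z, lower.tail = lower, log.p = TRUE) / log(10)
}

#' Tie-corrected approximate Wilcoxon-Mann-Whitney test on a ranked profile
#'
#' Tests whether the values at `index` rank higher (default), lower, or
#' differently than the remaining values, using the normal approximation to
#' the Mann-Whitney U statistic with tie-corrected variance and (by default)
#' a 0.5 continuity correction applied toward the mean. The p-value is also
#' computed in log10 space, so extremely significant configurations return a
#' finite `log10_p` even when `p` underflows double precision (in which case
#' `p` is reported as 0 and `log10_p` is authoritative).
#'
#' When all values in the profile are tied the variance of U is 0 and the
#' test is maximally non-significant: p = 1.
#'
#' @param ranked a [rank_profile()] object.
#' @param index integer vector of member positions in the profile (the gene
#'   set), with 0 < length(index) < N after de-duplication.
#' @param alternative "greater" (members rank higher), "less", or
#'   "two.sided" ("two_sided" is accepted as an alias).
#' @param correct apply the 0.5 continuity correction (default TRUE).
#' @return list with `p` (in \[0, 1\]), `log10_p` (<= 0, finite), `U`, and
#'   `z`.
#' @export
wmw_test <- function(ranked, index,
                     alternative = c("greater", "less", "two.sided", "two_sided"),
                     correct = TRUE) {
  stopifnot(inherits(ranked, "ranked_profile"))
  alternative <- match.arg(alternative)
  if (alternative == "two_sided") alternative <- "two.sided"
  index <- unique(as.integer(index))
  if (length(index) == 0L) stop("empty set after matching")
  if (any(index < 1L | index > ranked$N)) stop("member index out of range")
  n1 <- length(index)
  N <- ranked$N
  if (n1 == N) stop("set covers all genes")
  n2 <- N - n1
  R1 <- sum(ranked$midranks[index])
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  varU <- (n1 * n2 / 12) * ((N + 1) - ranked$tie_term / (N * (N - 1)))
  if (varU <= 0) {
    return(list(p = 1, log10_p = 0, U = U, z = 0))
  }
  cc <- if (correct) 0.5 else 0
  sd <- sqrt(varU)
  if (alternative == "greater") {
    z <- (U - mu - cc) / sd
    lp <- log10_tail(z, lower = FALSE)
  } else if (alternative == "less") {
    z <- (U - mu + cc) / sd
    lp <- log10_tail(z, lower = TRUE)
  } else {
    z <- (U - mu - sign(U - mu) * cc) / sd
    lp <- min(0, log10(2) + min(log10_tail(z, FALSE), log10_tail(z, TRUE)))
  }
  list(p = 10^lp, log10_p = min(lp, 0), U = U, z = z)
}

#' Reference Wilcoxon-Mann-Whitney implementation (oracle)
#'
#' An independent, deliberately unoptimized implementation used for
#' cross-checking: it re-sorts the profile on every call and evaluates the
#' same tie-corrected, continuity-corrected normal approximation directly
#' from the U-statistic formulas. With `exact = TRUE` it instead enumerates
#' all subsets of the member-set size (feasible when choose(N, n1) <= 1e6)
#' and returns the exact permutation p-value of the rank sum.
#'
#' @param values numeric profile (not pre-ranked).
#' @param index member positions, 0 < n1 < N.
#' @param alternative as in [wmw_test()].
#' @param correct apply continuity correction (approximation path only).
#' @param exact enumerate all member subsets instead of approximating.
#' @return p-value (numeric scalar).
#' @export
wmw_oracle <- function(values, index,
                       alternative = c("greater", "less", "two.sided", "two_sided"),
                       correct = TRUE, exact = FALSE) {
  alternative <- match.arg(alternative)
  if (alternative == "two_sided") alternative <- "two.sided"
  index <- unique(as.integer(index))
  if (length(index) == 0L) stop("empty set after matching")
  N <- length(values)
  n1 <- length(index)
  if (n1 >= N) stop("set covers all genes")
  n2 <- N - n1
  # independent midrank computation from the sort order
  ord <- order(values)
  r <- numeric(N)
  i <- 1L
  while (i <= N) {
    j <- i
    while (j < N && values[ord[j + 1L]] == values[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  R1 <- sum(r[index])

  if (exact) {
    if (choose(N, n1) > 1e6) stop("exact enumeration infeasible: choose(N, n1) > 1e6")
    sums <- utils::combn(r, n1, FUN = sum)
    eps <- 1e-9
    p_ge <- mean(sums >= R1 - eps)
    p_le <- mean(sums <= R1 + eps)
    return(switch(alternative,
                  greater = p_ge,
                  less = p_le,
                  two.sided = min(1, 2 * min(p_ge, p_le))))
  }

  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(values)
  ties <- ties[ties > 1L]
  tie_term <- if (length(ties)) sum(as.numeric(ties)^3 - as.numeric(ties)) else 0
  varU <- (n1 * n2 / 12) * ((N + 1) - tie_term / (N * (N - 1)))
  if (varU <= 0) return(1)
  cc <- if (correct) 0.5 else 0
  sd <- sqrt(varU)
  switch(alternative,
         greater = stats::pnorm((U - mu - cc) / sd, lower.tail = FALSE),
         less = stats::pnorm((U - mu + cc) / sd, lower.tail = TRUE),
         two.sided = min(1, 2 * min(
           stats::pnorm((U - mu - cc) / sd, lower.tail = FALSE),
           stats::pnorm((U - mu + cc) / sd, lower.tail = TRUE))))
}
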