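#' Score a collection of gene sets against every sample of an expression matrix
#'
#' The workhorse of heterogeneity QC. For each sample the expression profile
#' is ranked exactly once ([rank_profile()]); every gene set is then scored
#' from the precomputed midranks via a sparse membership-indicator matrix
#' multiplication, so scoring s sets on one profile costs
#' O(m log m + sum of set sizes) rather than O(s * m log m). Each
#' signature/sample pair receives the tie-corrected, continuity-corrected
#' normal-approximation Wilcoxon-Mann-Whitney p-value and the enrichment
#' score |log10 p|: 0 means no enrichment, large values strong enrichment,
#' computed in log space so extreme enrichment never underflows to infinity
#' or zero score.
#'
#' Set members are matched to `rownames(expr)` by exact string equality
#' (after whitespace trimming at collection construction); unmatched members
#' are dropped and the effective (matched) set size is reported. Sets with
#' fewer than `min_set_size` matched members — or sets covering the whole
#' matrix, for which the test is undefined — are given score 0 with a
#' warning rather than aborting the run.
#'
#' @param expr numeric genes-by-samples matrix (see [as_expression_matrix()]).
#' @param sets a [gene_sets()] collection.
#' @param alternative "greater" (default: signature genes rank higher, i.e.
#'   positive enrichment), "less", or "two.sided".
#' @param min_set_size minimum number of matched members for a set to be
#'   tested (default 2).
#' @param correct apply the 0.5 continuity correction (default TRUE).
#' @return object of class `wmw_scores`: list with `scores` (s x n matrix of
#'   |log10 p|), `pvalues` (s x n; 0 where the p-value underflowed, with the
#'   score authoritative), `effective_set_sizes` (s x n integer),
#'   `alternative`, and `skipped` (names of sets not tested).
#' @examples
#' expr <- matrix(rnorm(200 * 4), 200, 4,
#'                dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
#' expr[1:10, 1] <- expr[1:10, 1] + 3
#' sig <- gene_sets(list(up = paste0("g", 1:10), decoy = paste0("g", 101:120)))
#' res <- score_gene_sets(expr, sig)
#' res$scores["up", "s1"] > res$scores["decoy", "s1"]
#' @export
score_gene_sets <- function(expr, sets,
                            alternative = c("greater", "less", "two.sided", "two_sided"),
                            min_set_size = 2L, correct = TRUE) {
  expr <- as_expression_matrix(expr)
  stopifnot(inherits(sets, "gene_sets"))
  alternative <- match.arg(alternative)
  if (alternative == "two_sided") alternative <- "two.sided"
  m <- nrow(expr)
  n <- ncol(expr)
  s <- length(sets)

  idx <- lapply(sets, function(g) {
    i <- match(g, rownames(expr))
    i[!is.na(i)]
  })
  n1 <- lengths(idx)
  if (all(n1 == 0L)) stop("no overlap between collection and matrix")
  testable <- n1 >= min_set_size & n1 < m
  skipped <- names(sets)[!testable]
  if (length(skipped)) {
    warning("skipping ", length(skipped), " set(s) with <", min_set_size,
            " matched members (or covering all genes): ",
            paste(utils::head(skipped, 5L), collapse = ", "),
            if (length(skipped) > 5L) ", ..." else "")
  }

  # one ranking pass per sample
  ranked <- lapply(seq_len(n), function(j) rank_profile(expr[, j]))
  ranks <- vapply(ranked, `[[`, numeric(m), "midranks")
  tie_term <- vapply(ranked, `[[`, numeric(1L), "tie_term")

  scores <- matrix(0, s, n, dimnames = list(names(sets), colnames(expr)))
  pvals <- matrix(1, s, n, dimnames = dimnames(scores))

  if (any(testable)) {
    w <- which(testable)
    ind <- Matrix::sparseMatrix(
      i = rep(seq_along(w), n1[w]),
      j = unlist(idx[w]),
      x = 1,
      dims = c(length(w), m))
    R1 <- as.matrix(ind %*% ranks)                  # s' x n rank sums
    k1 <- n1[w]
    k2 <- m - k1
    U <- R1 - k1 * (k1 + 1) / 2
    muU <- k1 * k2 / 2
    varU <- outer(k1 * k2 / 12, (m + 1) - tie_term / (m * (m - 1)))
    cc <- if (correct) 0.5 else 0
    sdU <- sqrt(pmax(varU, 0))
    lp <- matrix(0, length(w), n)
    pos <- varU > 0
    zg <- (U - muU - cc) / sdU
    zl <- (U - muU + cc) / sdU
    if (alternative == "greater") {
      lp[pos] <- log10_tail(zg[pos], lower = FALSE)
    } else if (alternative == "less") {
      lp[pos] <- log10_tail(zl[pos], lower = TRUE)
    } else {
      lp[pos] <- pmin(0, log10(2) + pmin(log10_tail(zg[pos], FALSE),
                                         log10_tail(zl[pos], TRUE)))
    }
    scores[w, ] <- abs(lp)   # lp <= 0; abs also normalises -0 to 0
    pvals[w, ] <- 10^lp
  }

  structure(
    list(scores = scores,
         pvalues = pvals,
         effective_set_sizes = matrix(as.integer(n1), s, n,
                                      dimnames = dimnames(scores)),
         alternative = alternative,
         skipped = skipped),
    class = "wmw_scores")
}

#' @export
print.wmw_scores <- function(x, ...) {
  cat("wmw_scores: ", nrow(x$scores), " signature(s) x ", ncol(x$scores),
      " sample(s), alternative = ", x$alternative, "\n", sep = "")
  top <- apply(x$scores, 2L, function(col) rownames(x$scores)[which.max(col)])
  show <- utils::head(seq_len(ncol(x$scores)), 8L)
  for (j in show) {
    cat(sprintf("  %s: top = %s (score %.3g)\n", colnames(x$scores)[j],
                top[j], max(x$scores[, j])))
  }
  if (ncol(x$scores) > 8L) cat("  ...\n")
  invisible(x)
}

#' Competition ranks of scores within each sample
#'
#' Rank 1 is the best (highest) score; tied scores share the minimum
#' (best) rank.
#'
#' @param scores numeric matrix, signatures in rows, samples in columns (or a
#'   `wmw_scores` object).
#' @return integer matrix of the same shape.
#' @export
score_ranks <- function(scores) {
  if (inherits(scores, "wmw_scores")) scores <- scores$scores
  r <- apply(scores, 2L, function(col) rank(-col, ties.method = "min"))
  matrix(as.integer(r), nrow(scores), ncol(scores), dimnames = dimnames(scores))
}

#' Write a score matrix as TSV
#'
#' Signatures in rows, samples in columns; values formatted with
#' `digits` significant digits. Optionally writes a companion TSV of
#' effective (matched) set sizes.
#'
#' @param x a `wmw_scores` object from [score_gene_sets()].
#' @param path output path.
#' @param digits significant digits (default 6).
#' @param sizes_path optional path for the effective-set-size table.
#' @export
write_scores <- function(x, path, digits = 6L, sizes_path = NULL) {
  stopifnot(inherits(x, "wmw_scores"))
  fmt <- signif(x$scores, digits)
  df <- data.frame(signature = rownames(fmt), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sizes_path)) {
    sz <- data.frame(signature = rownames(x$effective_set_sizes),
                     x$effective_set_sizes, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(sz, sizes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
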