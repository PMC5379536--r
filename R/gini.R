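#' Gini index of a non-negative expression vector
#'
#' Inequality of a gene's expression across n tissues. With the vector sorted
#' ascending to x'_1 <= ... <= x'_n,
#' G = (1/n) * (n + 1 - 2 * sum_j (n + 1 - j) x'_j / sum_j x'_j).
#' G = 0 for a uniform positive vector; exclusive expression in a single
#' tissue attains the maximum (n - 1)/n, which approaches 1 as the number of
#' tissues grows. The value is invariant under positive rescaling of the
#' vector and depends only on its multiset of values.
#'
#' `bias_correct = TRUE` multiplies by n/(n - 1) so the exclusive-expression
#' extreme maps to exactly 1 regardless of n.
#'
#' @param x non-negative numeric vector, length >= 2, positive total.
#' @param bias_correct rescale by n/(n - 1) (default FALSE).
#' @return Gini index in \[0, (n-1)/n\] (or \[0, 1\] if corrected).
#' @examples
#' gini_index(rep(5, 10))        # 0: uniform
#' gini_index(c(rep(0, 9), 7))   # 0.9: exclusive, n = 10
#' @export
gini_index <- function(x, bias_correct = FALSE) {
  if (!is.numeric(x) || length(x) < 2L) stop("need a numeric vector of length >= 2")
  if (anyNA(x)) stop("missing values in input")
  if (any(x < 0)) stop("negative entries: Gini index requires non-negative values")
  total <- sum(x)
  if (total <= 0) stop("undefined Gini (zero total)")
  n <- length(x)
  xs <- sort(x)
  g <- (n + 1 - 2 * sum((n + 1 - seq_len(n)) * xs) / total) / n
  if (bias_correct) g <- g * n / (n - 1)
  g
}

# Row-wise Gini for a matrix; same formula, vectorized over genes.
# Rows must have positive totals (callers filter zero-total rows first).
gini_rows <- function(mat, bias_correct = FALSE) {
  n <- ncol(mat)
  srt <- t(apply(mat, 1L, sort))
  w <- n + 1 - seq_len(n)
  g <- (n + 1 - 2 * as.vector(srt %*% w) / rowSums(mat)) / n
  if (bias_correct) g <- g * n / (n - 1)
  stats::setNames(g, rownames(mat))
}

#' Per-gene Gini profile of a tissue-averaged matrix
#'
#' Computes each gene's Gini index across tissue columns together with the
#' indices of its `top_k` highest-expressing tissues (ordered, ties broken by
#' column order) — the intermediate of signature derivation.
#'
#' @param mat non-negative genes-by-tissues matrix (tissue-averaged).
#' @param top_k number of top tissues to record (default 3).
#' @param bias_correct passed to the Gini computation.
#' @return list with `gene_ids`, `gini` (named numeric) and `top_tissues`
#'   (genes x top_k integer matrix of column indices).
#' @export
gini_profile <- function(mat, top_k = 3L, bias_correct = FALSE) {
  mat <- as_expression_matrix(mat)
  if (any(mat < 0)) stop("negative entries: Gini index requires non-negative values")
  zero <- rowSums(mat) <= 0
  if (any(zero)) {
    message("dropping ", sum(zero), " gene row(s) with zero total expression")
    mat <- mat[!zero, , drop = FALSE]
  }
  if (nrow(mat) == 0L) stop("undefined Gini (zero total)")
  top <- t(apply(mat, 1L, function(r) order(r, decreasing = TRUE)[seq_len(top_k)]))
  list(gene_ids = rownames(mat),
       gini = gini_rows(mat, bias_correct = bias_correct),
       top_tissues = top)
}

#' Average replicate samples per tissue
#'
#' Collapses a genes-by-samples matrix to a genes-by-tissues matrix by
#' arithmetic mean over each tissue's replicate columns, on the input scale.
#'
#' @param expr genes-by-samples matrix.
#' @param tissue_map named character vector mapping every sample identifier
#'   (names) to a tissue label (values).
#' @return genes-by-tissues matrix with tissue labels as column names.
#' @export
average_replicates <- function(expr, tissue_map) {
  expr <- as_expression_matrix(expr)
  unmapped <- setdiff(colnames(expr), names(tissue_map))
  if (length(unmapped)) {
    stop("unmapped sample(s): ", paste(unmapped, collapse = ", "))
  }
  labels <- as.character(tissue_map[colnames(expr)])
  tissues <- unique(labels)
  if (length(tissues) < 2L) stop("need at least 2 distinct tissues")
  out <- vapply(tissues, function(tt) {
    rowMeans(expr[, labels == tt, drop = FALSE])
  }, numeric(nrow(expr)))
  dimnames(out) <- list(rownames(expr), tissues)
  out
}

#' Derive tissue-enriched gene signatures by the Gini rule
#'
#' A gene is called enriched in a tissue when its Gini index across the
#' tissue-averaged matrix is at least `gini_threshold` AND its expression in
#' that tissue ranks among the `top_k` largest values of its row. A gene may
#' therefore enter up to `top_k` signatures. Ties at the `top_k`-th place
#' admit all tied tissues (inclusive rule), which makes the derivation
#' invariant to column permutation; a message is emitted when this widens a
#' gene's tissue list beyond `top_k`. Tissues where the gene is not expressed
#' at all (value 0) never qualify, so an exclusively expressed gene enters
#' only its own tissue's signature.
#'
#' The rule operates on the input scale; it is intended for linear-scale
#' signals (e.g. MAS5 intensities or CPM). Passing log-scale data changes
#' the Gini values and hence the derived sets.
#'
#' @param avg non-negative genes-by-tissues matrix, e.g. from
#'   [average_replicates()]; needs at least `top_k + 1` tissue columns.
#' @param gini_threshold minimum Gini index (default 0.7).
#' @param top_k number of top-ranking tissues admitted (default 3).
#' @param bias_correct apply the n/(n-1) Gini rescaling before thresholding.
#' @return a [gene_sets()] collection, one set per tissue column (empty sets
#'   retained and reported via `message()`), with descriptions recording the
#'   parameters.
#' @export
derive_signatures <- function(avg, gini_threshold = 0.7, top_k = 3L,
                              bias_correct = FALSE) {
  avg <- as_expression_matrix(avg)
  n <- ncol(avg)
  if (n < top_k + 1L) {
    stop("need at least top_k + 1 = ", top_k + 1L,
         " tissues; got ", n, " (top-", top_k, " rule is vacuous)")
  }
  if (any(avg < 0)) stop("negative entries: Gini index requires non-negative values")
  zero <- rowSums(avg) <= 0
  if (any(zero)) {
    message("dropping ", sum(zero), " gene row(s) with zero total expression")
    avg <- avg[!zero, , drop = FALSE]
  }
  g <- gini_rows(avg, bias_correct = bias_correct)
  pass <- g >= gini_threshold
  members <- rep(list(character(0)), n)
  names(members) <- colnames(avg)
  widened <- 0L
  for (i in which(pass)) {
    row <- avg[i, ]
    kth <- sort(row, decreasing = TRUE)[top_k]
    # inclusive at the top_k boundary, but zero expression never qualifies
    # (an exclusively expressed gene belongs to its one tissue only)
    hit <- which(row >= kth & row > 0)
    if (length(hit) > top_k) widened <- widened + 1L
    for (j in hit) members[[j]] <- c(members[[j]], rownames(avg)[i])
  }
  if (widened > 0L) {
    message(widened, " gene(s) tied at the top-", top_k,
            " boundary; all tied tissues admitted")
  }
  empty <- names(members)[lengths(members) == 0L]
  if (length(empty)) {
    message("tissue(s) with empty signatures retained: ",
            paste(empty, collapse = ", "))
  }
  gene_sets(members,
            descriptions = sprintf("gini>=%g;topk=%d", gini_threshold, top_k))
}

#' Merge two expression batches with an additive per-gene linear model
#'
#' On the intersection of gene identifiers, fits per gene the additive model
#' expression = gene mean + batch offset + residual, and subtracts the
#' estimated batch offsets so both batches share each gene's grand mean
#' (the unweighted mean of the two batch means); the adjusted columns are
#' then concatenated. Exact for purely additive batch effects.
#'
#' @param expr_a,expr_b genes-by-samples matrices with >= 2 columns each.
#' @return merged matrix over the shared genes, columns of `expr_a` first.
#' @export
merge_batches <- function(expr_a, expr_b) {
  expr_a <- as_expression_matrix(expr_a)
  expr_b <- as_expression_matrix(expr_b)
  if (ncol(expr_a) < 2L || ncol(expr_b) < 2L) {
    stop("need at least 2 samples per batch")
  }
  shared <- intersect(rownames(expr_a), rownames(expr_b))
  if (length(shared) == 0L) stop("empty gene intersection between batches")
  a <- expr_a[shared, , drop = FALSE]
  b <- expr_b[shared, , drop = FALSE]
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  grand <- (ma + mb) / 2
  merged <- cbind(a - (ma - grand), b - (mb - grand))
  if (anyDuplicated(colnames(merged))) {
    message("de-duplicating sample identifiers shared across batches")
    colnames(merged) <- make.unique(colnames(merged))
  }
  merged
}

#' Merge signatures of identically named tissues
#'
#' Union of member sets keyed by case-insensitive, whitespace-normalised
#' tissue name (e.g. signatures of the same tissue derived from two
#' platforms). Off by default in derivation; exposed as a utility.
#'
#' @param sets a [gene_sets()] collection.
#' @return a [gene_sets()] collection with one set per normalised name.
#' @export
merge_tissue_signatures <- function(sets) {
  stopifnot(inherits(sets, "gene_sets"))
  key <- tolower(gsub("[[:space:]]+", " ", trimws(names(sets))))
  out <- lapply(split(seq_along(sets), key), function(ii) {
    unique(unlist(unclass(sets)[ii], use.names = FALSE))
  })
  first <- vapply(split(seq_along(sets), key), `[`, integer(1L), 1L)
  names(out) <- names(sets)[first]
  gene_sets(out[order(first)], descriptions = "merged")
}
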