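# independent closed form: relative mean absolute difference
gini_mad <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

test_that("analytic Gini cases evaluate exactly", {
  expect_identical(gini_index(rep(5, 10)), 0)            # uniform -> 0
  expect_equal(gini_index(c(rep(0, 9), 7)), 0.9)         # exclusive, n = 10
  expect_equal(gini_index(c(rep(0, 3), 2)), 3 / 4)       # exclusive, n = 4
  expect_equal(gini_index(c(1, 2, 3, 4)), 0.25)          # hand evaluation
  # bias-corrected variant maps the exclusive extreme to exactly 1
  expect_equal(gini_index(c(rep(0, 9), 7), bias_correct = TRUE), 1)
})

test_that("Gini input contract: negatives, zero totals, degenerate lengths", {
  expect_error(gini_index(c(0, 0, 0)), "zero total")
  expect_error(gini_index(c(1, -0.5, 2)), "negative")
  expect_error(gini_index(5), "length >= 2")
  expect_error(gini_index(c(1, NA)), "missing")
})

test_that("Gini is scale-invariant, bounded, and matches the mean-absolute-difference form", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(2:50, 1L)
    x <- rexp(n) * sample(c(1, 100), 1L)
    g <- gini_index(x)
    expect_gte(g, -1e-12)
    expect_lte(g, (n - 1) / n + 1e-12)
    expect_equal(gini_index(x * runif(1, 0.01, 1000)), g, tolerance = 1e-12)
    expect_equal(g, gini_mad(x), tolerance = 1e-9)
    # value depends only on the multiset
    expect_equal(gini_index(sample(x)), g, tolerance = 1e-12)
  }
})

test_that("transferring mass from the smallest to the largest entry never decreases G", {
  set.seed(32)
  for (i in 1:20) {
    x <- rexp(10) + 0.1
    g0 <- gini_index(x)
    lo <- which.min(x); hi <- which.max(x)
    d <- x[lo] * runif(1, 0, 0.9)
    y <- x; y[lo] <- y[lo] - d; y[hi] <- y[hi] + d
    expect_gte(gini_index(y), g0 - 1e-12)
  }
})

test_that("gini_profile reports per-gene indices and top tissues, dropping zero rows", {
  mat <- rbind(
    allA  = c(9, 0, 0, 0, 0),
    grad  = c(1, 2, 3, 4, 5),
    zero  = c(0, 0, 0, 0, 0),
    flat  = c(2, 2, 2, 2, 2))
  colnames(mat) <- paste0("t", 1:5)
  expect_message(gp <- gini_profile(mat), "zero total")
  expect_identical(gp$gene_ids, c("allA", "grad", "flat"))
  expect_equal(unname(gp$gini["allA"]), 4 / 5)
  expect_equal(unname(gp$gini["flat"]), 0)
  expect_identical(gp$top_tissues[2, ], c(5L, 4L, 3L))  # grad: t5 > t4 > t3
})

test_that("average_replicates takes per-tissue means and validates the map", {
  expr <- cbind(k1 = c(1, 3), k2 = c(3, 5), p1 = c(10, 0))
  rownames(expr) <- c("gA", "gB")
  map <- c(k1 = "kidney", k2 = "kidney", p1 = "pancreas")
  avg <- average_replicates(expr, map)
  expect_equal(avg[, "kidney"], c(gA = 2, gB = 4))
  expect_equal(avg[, "pancreas"], c(gA = 10, gB = 0))
  # one sample per tissue: identity up to renaming
  avg1 <- average_replicates(expr[, c("k1", "p1")], map)
  expect_equal(unname(avg1), unname(expr[, c("k1", "p1")]))
  # equal replicates: idempotence
  expr3 <- cbind(a = c(2, 4), b = c(2, 4), c = c(2, 4), z = c(0, 1))
  rownames(expr3) <- c("gA", "gB")
  avg3 <- average_replicates(expr3, c(a = "T", b = "T", c = "T", z = "U"))
  expect_equal(avg3[, "T"], c(gA = 2, gB = 4))
  expect_error(average_replicates(expr, map[-1]), "unmapped sample.*k1")
  expect_error(average_replicates(expr[, 1:2], map), "2 distinct tissues")
})

test_that("derive_signatures applies the Gini >= 0.7 / top-3 rule", {
  n <- 10
  tissues <- paste0("t", seq_len(n))
  mat <- rbind(
    exclusiveA = c(50, rep(0, n - 1)),          # G = 0.9: only t1's signature
    uniform    = rep(8, n),                     # G = 0: nowhere
    threeTop   = c(100, 90, 80, rep(0, n - 3)), # in t1, t2, t3 if G >= 0.7
    lowG       = c(3, 2, 2, 2, 2, 2, 2, 2, 2, 2))
  colnames(mat) <- tissues
  expect_gte(gini_index(mat["threeTop", ]), 0.7)
  expect_lt(gini_index(mat["lowG", ]), 0.7)
  sigs <- suppressMessages(derive_signatures(mat))
  expect_identical(sigs[["t1"]], c("exclusiveA", "threeTop"))
  expect_identical(sigs[["t2"]], "threeTop")
  expect_identical(sigs[["t3"]], "threeTop")
  expect_true(all(lengths(unclass(sigs)[4:10]) == 0))
  expect_false(any(vapply(unclass(sigs), function(s) "uniform" %in% s, logical(1))))
  expect_false(any(vapply(unclass(sigs), function(s) "lowG" %in% s, logical(1))))
})

test_that("ties at the top-k boundary admit all tied tissues", {
  n <- 8
  mat <- rbind(tied = c(100, 50, 50, 50, rep(0, n - 4)))
  colnames(mat) <- paste0("t", 1:n)
  mat <- rbind(mat, filler = c(rep(1, n)))  # need >= 2 genes
  expect_message(sigs <- derive_signatures(mat, gini_threshold = 0.5),
                 "tied at the top-3 boundary")
  member_of <- names(sigs)[vapply(unclass(sigs), function(s) "tied" %in% s, logical(1))]
  expect_identical(member_of, c("t1", "t2", "t3", "t4"))
})

test_that("a vacuous top-k rule is rejected", {
  mat <- matrix(runif(6), 2, 3, dimnames = list(c("a", "b"), paste0("t", 1:3)))
  expect_error(derive_signatures(mat, top_k = 3), "at least top_k \\+ 1")
})

test_that("threshold 0 with top_k = n-1 admits every gene everywhere but its minimum", {
  set.seed(33)
  n <- 6
  mat <- matrix(rexp(5 * n) + 0.01, 5, n,
                dimnames = list(paste0("g", 1:5), paste0("t", 1:n)))
  sigs <- suppressMessages(derive_signatures(mat, gini_threshold = 0, top_k = n - 1))
  for (i in 1:5) {
    worst <- colnames(mat)[which.min(mat[i, ])]
    member_of <- names(sigs)[vapply(unclass(sigs),
                                    function(s) paste0("g", i) %in% s, logical(1))]
    expect_identical(sort(member_of), sort(setdiff(colnames(mat), worst)))
  }
})

test_that("merge_batches removes additive per-gene offsets exactly", {
  set.seed(34)
  m <- 50
  a <- matrix(rnorm(m * 4), m, 4,
              dimnames = list(paste0("g", 1:m), paste0("a", 1:4)))
  # constant shift per gene
  shift <- 3.7
  b <- a + shift
  colnames(b) <- paste0("b", 1:4)
  merged <- merge_batches(a, b)
  expect_equal(rowMeans(merged[, 1:4]), rowMeans(merged[, 5:8]), tolerance = 1e-12)
  # identical batches pass through unchanged
  b2 <- a; colnames(b2) <- paste0("b", 1:4)
  merged2 <- merge_batches(a, b2)
  expect_equal(unname(merged2[, 1:4]), unname(a))
  # random per-gene offsets N(0, 2^2): batch mean differences vanish post-merge
  off <- rnorm(m, 0, 2)
  b3 <- a[, 1:3] + off
  colnames(b3) <- paste0("c", 1:3)
  merged3 <- merge_batches(a, b3)
  diff <- rowMeans(merged3[, 1:4]) - rowMeans(merged3[, 5:7])
  expect_lt(max(abs(diff)), 1e-9)
  # disjoint gene universes are an error
  a2 <- a; rownames(a2) <- paste0("x", 1:m)
  expect_error(merge_batches(a, a2), "empty gene intersection")
  expect_error(merge_batches(a[, 1, drop = FALSE], b), "2 samples per batch")
})

test_that("merge_tissue_signatures unions sets keyed by normalised name", {
  sets <- gene_sets(list(Liver = c("g1", "g2"), " liver " = c("g2", "g3"),
                         Heart = "g9"))
  merged <- merge_tissue_signatures(sets)
  expect_identical(sort(merged[["Liver"]]), c("g1", "g2", "g3"))
  expect_identical(merged[["Heart"]], "g9")
  expect_length(merged, 2L)
})
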