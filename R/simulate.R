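#' Generate a null expression matrix of i.i.d. standard-normal genes
#'
#' The background model of the sensitivity simulations: every gene in every
#' sample is drawn independently from N(0, 1). Gene identifiers are
#' "g000001", "g000002", ... Reproducible given `seed`; `seed = NULL` draws
#' from the current RNG stream (used internally by the pipeline generators).
#'
#' @param m number of genes (>= 100; default 22000, genome scale).
#' @param n_samples number of samples (>= 1).
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return genes-by-samples matrix.
#' @export
generate_null_matrix <- function(m = 22000L, n_samples = 1L, seed = 0L) {
  if (m < 100L) stop("m must be >= 100")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(m * n_samples), m, n_samples,
         dimnames = list(sprintf("g%06d", seq_len(m)),
                         sprintf("sample_%02d", seq_len(n_samples))))
}

#' Spike a gene set with shifted-normal expression
#'
#' Replaces the rows of the member genes by fresh N(mu, 1) draws in every
#' sample, leaving all other rows untouched — the signal model of the
#' sensitivity simulations: the signature's genes gain mean expression mu
#' standard deviations above background.
#'
#' @param expr matrix from [generate_null_matrix()] (or compatible).
#' @param members gene identifiers (or row indices) to spike; nonempty.
#' @param mu mean shift, >= 0.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return matrix of the same shape with member rows redrawn.
#' @export
spike_signature <- function(expr, members, mu, seed = 0L) {
  if (length(members) == 0L) stop("empty member set")
  if (mu < 0) stop("mu must be >= 0")
  if (is.character(members)) {
    idx <- match(members, rownames(expr))
    if (anyNA(idx)) stop("member(s) not in gene universe: ",
                         paste(utils::head(members[is.na(idx)], 5L), collapse = ", "))
  } else {
    idx <- as.integer(members)
    if (any(idx < 1L | idx > nrow(expr))) stop("member index out of range")
  }
  if (!is.null(seed)) set.seed(seed)
  expr[idx, ] <- stats::rnorm(length(idx) * ncol(expr), mean = mu)
  expr
}

#' Random decoy gene sets
#'
#' Emulates a signature collection under the i.i.d. null: random gene sets,
#' disjoint from the spiked set, with sizes drawn uniformly from
#' `size_range` (typical tissue-signature sizes).
#'
#' @param gene_ids gene universe.
#' @param n_decoys number of decoy sets (default 154, so that together with
#'   one spiked set the collection has 155 signatures).
#' @param size_range integer range of set sizes (default 20 to 200).
#' @param exclude gene identifiers never used (the spiked set).
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return a [gene_sets()] collection named "decoy_001", ...
#' @export
make_decoy_sets <- function(gene_ids, n_decoys = 154L, size_range = c(20L, 200L),
                            exclude = character(0), seed = 0L) {
  pool <- setdiff(gene_ids, exclude)
  if (length(pool) < max(size_range)) stop("gene universe too small for decoy sizes")
  if (!is.null(seed)) set.seed(seed)
  sizes <- sample(seq(size_range[1L], size_range[2L]), n_decoys, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(pool, k))
  names(sets) <- sprintf("decoy_%03d", seq_len(n_decoys))
  gene_sets(sets, descriptions = "random decoy")
}

#' Sensitivity curve of the spiked-signature simulation
#'
#' For each shift mu in `mus`: draw a fresh `m` x `n_samples` N(0,1)
#' background, redraw one randomly chosen signature of `set_size` genes from
#' N(mu, 1), score the spiked signature together with `n_decoys` random decoy
#' signatures on every sample, and record the spiked signature's enrichment
#' score and competition rank (rank 1 = highest score; ties share the best
#' rank). The spiked set and the decoys are chosen once and reused across
#' the whole mu grid; background and signal values are redrawn per sample.
#'
#' @param mus non-negative shifts, e.g. `seq(0, 3, by = 0.25)`.
#' @param m background gene count (default 22000).
#' @param set_size spiked-signature size (default 43).
#' @param n_samples samples per mu (default 10).
#' @param n_decoys decoy signatures (default 154).
#' @param decoy_size_range decoy sizes, uniform in this range (default 20-200).
#' @param seed integer seed governing every draw (default 0).
#' @return data.frame with columns `mu`, `sample`, `score`, `rank`.
#' @export
sensitivity_curve <- function(mus, m = 22000L, set_size = 43L, n_samples = 10L,
                              n_decoys = 154L, decoy_size_range = c(20L, 200L),
                              seed = 0L) {
  if (length(mus) == 0L || any(mus < 0)) stop("mus must be nonempty and >= 0")
  set.seed(seed)
  gene_ids <- sprintf("g%06d", seq_len(m))
  spiked <- sample(gene_ids, set_size)
  decoys <- make_decoy_sets(gene_ids, n_decoys = n_decoys,
                            size_range = decoy_size_range,
                            exclude = spiked, seed = NULL)
  sets <- gene_sets(c(list(spiked = spiked), unclass(decoys)),
                    descriptions = c("spiked", attr(decoys, "descriptions")))
  out <- vector("list", length(mus))
  for (k in seq_along(mus)) {
    expr <- generate_null_matrix(m, n_samples, seed = NULL)
    expr <- spike_signature(expr, spiked, mus[k], seed = NULL)
    res <- score_gene_sets(expr, sets, alternative = "greater")
    rk <- score_ranks(res)
    out[[k]] <- data.frame(mu = mus[k],
                           sample = seq_len(n_samples),
                           score = unname(res$scores["spiked", ]),
                           rank = unname(rk["spiked", ]))
  }
  do.call(rbind, out)
}

#' Convex combination of two expression profiles
#'
#' Mixing model of in-silico contamination: Y = omega * Y_A +
#' (1 - omega) * Y_B over a shared gene universe. omega = 1 returns profile
#' A exactly; as omega decreases from 1 the profile mimics contamination of
#' A by B (and symmetrically B by A as omega rises from 0).
#'
#' @param profile_a,profile_b named numeric vectors over identical gene
#'   universes.
#' @param omega mixing weight of `profile_a`, in \[0, 1\].
#' @return named numeric vector.
#' @export
mix_profiles <- function(profile_a, profile_b, omega) {
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0 || omega > 1) {
    stop("omega must be a single value in [0, 1]")
  }
  if (length(profile_a) != length(profile_b)) stop("profiles differ in length")
  if (!is.null(names(profile_a)) && !is.null(names(profile_b)) &&
      !identical(names(profile_a), names(profile_b))) {
    stop("profiles are over different gene universes")
  }
  omega * profile_a + (1 - omega) * profile_b
}

#' Score signatures across a grid of mixing weights
#'
#' Mixes two tissue profiles at every omega in `omegas`, scores every
#' signature in `sets` on each mixture and reports scores and competition
#' ranks — the raw material for detection-threshold estimation (smallest
#' contamination fraction at which the contaminant's signature reaches a
#' score or rank cutoff; see [detection_threshold()]).
#'
#' @param profile_a,profile_b named numeric vectors (shared gene universe).
#' @param sets a [gene_sets()] collection.
#' @param omegas weights of `profile_a`, all in \[0, 1\].
#' @param ... passed to [score_gene_sets()].
#' @return data.frame with columns `omega`, `set_name`, `score`, `rank`.
#' @export
mixing_grid <- function(profile_a, profile_b, sets, omegas, ...) {
  if (length(omegas) == 0L || any(omegas < 0 | omegas > 1)) {
    stop("omegas must be nonempty and within [0, 1]")
  }
  mixtures <- vapply(omegas, function(w) mix_profiles(profile_a, profile_b, w),
                     numeric(length(profile_a)))
  rownames(mixtures) <- names(profile_a)
  colnames(mixtures) <- sprintf("omega_%g", omegas)
  res <- score_gene_sets(mixtures, sets, ...)
  rk <- score_ranks(res)
  data.frame(omega = rep(omegas, each = length(sets)),
             set_name = rep(rownames(res$scores), length(omegas)),
             score = as.vector(res$scores),
             rank = as.vector(rk))
}

#' Smallest contamination fraction at which a signature is detected
#'
#' Scans a [mixing_grid()] result for the contaminant signature and returns
#' the smallest contaminant fraction at which its enrichment score reaches
#' `score_cutoff` or its rank reaches `rank_cutoff` (the working definition
#' of a detectable contamination event).
#'
#' @param grid data.frame from [mixing_grid()].
#' @param set_name contaminant signature name.
#' @param contaminant which profile is the contaminant: `"a"` means the
#'   contaminant fraction is `omega`, `"b"` means `1 - omega`.
#' @param score_cutoff detection score (default 3.0, i.e. p < 1e-3).
#' @param rank_cutoff detection rank (default 10).
#' @return smallest detectable contaminant fraction, or NA if never detected.
#' @export
detection_threshold <- function(grid, set_name, contaminant = c("a", "b"),
                                score_cutoff = 3.0, rank_cutoff = 10L) {
  contaminant <- match.arg(contaminant)
  rows <- grid[grid$set_name == set_name, , drop = FALSE]
  if (nrow(rows) == 0L) stop("set not present in grid: ", set_name)
  frac <- if (contaminant == "a") rows$omega else 1 - rows$omega
  hit <- rows$score >= score_cutoff | rows$rank <= rank_cutoff
  if (!any(hit)) return(NA_real_)
  min(frac[hit])
}

#' Synthetic pair of tissue profiles with disjoint signatures
#'
#' Builds two non-negative linear-scale expression profiles sharing a
#' log-normal baseline, with two disjoint signature gene sets elevated
#' `fold_a`-fold in tissue A and `fold_b`-fold in tissue B respectively —
#' a controlled stand-in for a pair of real tissue profiles in mixing
#' studies. Unequal folds reproduce the asymmetric-detection situation where
#' the more highly expressed signature is detected at lower contamination.
#'
#' @param m number of genes (default 2000).
#' @param sig_size genes per signature (default 40).
#' @param fold_a,fold_b fold-elevation of each tissue's signature genes over
#'   baseline (default 10 each).
#' @param noise_sd standard deviation of multiplicative log-normal noise
#'   applied independently to each profile (default 0.1).
#' @param seed integer seed.
#' @return list with `profile_a`, `profile_b` (named numeric vectors) and
#'   `sets` (a [gene_sets()] collection with sets `tissue_A`, `tissue_B`).
#' @export
simulate_tissue_pair <- function(m = 2000L, sig_size = 40L, fold_a = 10,
                                 fold_b = 10, noise_sd = 0.1, seed = 0L) {
  if (m < 2L * sig_size + 10L) stop("gene universe too small for two disjoint signatures")
  set.seed(seed)
  gene_ids <- sprintf("g%06d", seq_len(m))
  baseline <- stats::rlnorm(m, meanlog = 2, sdlog = 1)
  names(baseline) <- gene_ids
  picks <- sample(gene_ids, 2L * sig_size)
  sig_a <- picks[seq_len(sig_size)]
  sig_b <- picks[sig_size + seq_len(sig_size)]
  a <- baseline * stats::rlnorm(m, 0, noise_sd)
  b <- baseline * stats::rlnorm(m, 0, noise_sd)
  a[sig_a] <- a[sig_a] * fold_a
  b[sig_b] <- b[sig_b] * fold_b
  list(profile_a = a, profile_b = b,
       sets = gene_sets(list(tissue_A = sig_a, tissue_B = sig_b),
                        descriptions = "synthetic tissue signature"))
}
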