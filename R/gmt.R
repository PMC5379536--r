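#' Construct a gene-set collection
#'
#' A gene-set collection is a named list of character vectors of gene
#' identifiers, one per set (tissue signature), carrying an optional
#' description per set. Members are trimmed of surrounding whitespace and
#' de-duplicated; matching against expression matrices is by exact string
#' equality.
#'
#' @param sets named list of character vectors; names are set names, unique
#'   within the collection.
#' @param descriptions optional character vector of per-set descriptions,
#'   recycled if length 1.
#' @return an object of class `gene_sets`.
#' @export
gene_sets <- function(sets, descriptions = "") {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be a fully named list of character vectors")
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets <- lapply(sets, function(g) unique(trimws(as.character(g))))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  sizes <- lengths(x)
  cat("gene_sets collection: ", length(x), " set(s), member counts ",
      if (length(x)) paste0(min(sizes), "-", max(sizes)) else "none", "\n", sep = "")
  for (nm in utils::head(names(x), 6L)) {
    cat("  ", nm, " (", length(x[[nm]]), " genes)\n", sep = "")
  }
  if (length(x) > 6L) cat("  ... and ", length(x) - 6L, " more\n", sep = "")
  invisible(x)
}

#' @export
`[.gene_sets` <- function(x, i) {
  y <- unclass(x)[i]
  gene_sets(y, descriptions = attr(x, "descriptions")[names(y)])
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member gene identifiers,
#' tab-separated. Blank lines and lines starting with `#` are ignored.
#' Whitespace around identifiers is trimmed.
#'
#' @param path file path.
#' @return a [gene_sets()] collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("malformed GMT (", path, "), line ", lineno[i],
           ": need name, description and at least one gene")
    }
    nms[i] <- trimws(f[1L])
    desc[i] <- f[2L]
    members <- trimws(f[-(1:2)])
    sets[[i]] <- members[nzchar(members)]
  }
  names(sets) <- nms
  gene_sets(sets, descriptions = desc)
}

#' Write a gene-set collection as GMT
#'
#' Round-trips losslessly through [read_gmt()].
#'
#' @param sets a [gene_sets()] collection.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_sets"))
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
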