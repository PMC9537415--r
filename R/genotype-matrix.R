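#' Genotype matrix container
#'
#' In-memory container for a multi-sample set of biallelic SNP genotypes:
#' per-sample alt-allele dosages (0/1/2, `NA` for missing), site coordinates,
#' sample group labels and optional per-genotype read depth.
#'
#' @param genotypes integer matrix, samples x sites, values in \{0, 1, 2, NA\}.
#' @param samples data.frame with columns `sample_id` and `group`; row order
#'   matches the rows of `genotypes`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`;
#'   row order matches the columns of `genotypes`. Positions must be strictly
#'   increasing within each chromosome.
#' @param depth optional integer matrix of read depths, same shape as
#'   `genotypes`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, samples, sites, depth = NULL) {
  genotypes <- as.matrix(genotypes)
  stopifnot(
    is.data.frame(samples), all(c("sample_id", "group") %in% names(samples)),
    is.data.frame(sites), all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
    nrow(genotypes) == nrow(samples),
    ncol(genotypes) == nrow(sites)
  )
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  storage.mode(genotypes) <- "integer"
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(all(dim(depth) == dim(genotypes)))
  }
  rownames(genotypes) <- samples$sample_id
  obj <- structure(
    list(
      genotypes = genotypes,
      samples = as.data.frame(samples, stringsAsFactors = FALSE),
      sites = as.data.frame(sites, stringsAsFactors = FALSE),
      depth = depth
    ),
    class = "genotype_matrix"
  )
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$genotypes), "samples x",
      ncol(x$genotypes), "sites\n")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  grp <- table(x$samples$group)
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missingness: %.2f%%; depth: %s\n", 100 * miss,
              if (is.null(x$depth)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Subset a genotype matrix by site and/or sample index
#'
#' @param x a `genotype_matrix`.
#' @param sites integer or logical index over sites (columns).
#' @param samples integer or logical index over samples (rows).
#' @return A `genotype_matrix` restricted to the selected entries.
#' @export
subset_matrix <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(sites)) seq_len(ncol(x$genotypes)) else sites
  sa <- if (is.null(samples)) seq_len(nrow(x$genotypes)) else samples
  genotype_matrix(
    x$genotypes[sa, si, drop = FALSE],
    x$samples[sa, , drop = FALSE],
    x$sites[si, , drop = FALSE],
    depth = if (is.null(x$depth)) NULL else x$depth[sa, si, drop = FALSE]
  )
}

#' Rows of a genotype matrix belonging to a group
#'
#' @param x a `genotype_matrix`.
#' @param group one or more group labels.
#' @return Integer row indices.
#' @export
group_rows <- function(x, group) {
  idx <- which(x$samples$group %in% group)
  if (!length(idx)) stop("no samples in group(s): ", paste(group, collapse = ", "))
  idx
}

#' Per-site alternative-allele frequencies within a set of samples
#'
#' Frequencies are computed from genotyped (non-missing) individuals only.
#'
#' @param x a `genotype_matrix`.
#' @param rows integer row indices (defaults to all samples).
#' @return Numeric vector, one frequency per site; `NaN` where no individual
#'   is genotyped.
#' @export
site_frequencies <- function(x, rows = seq_len(nrow(x$genotypes))) {
  g <- x$genotypes[rows, , drop = FALSE]
  n <- colSums(!is.na(g))
  colSums(g, na.rm = TRUE) / (2 * n)
}
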