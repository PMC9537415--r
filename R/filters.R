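#' Thin sites by a minimum physical distance
#'
#' Greedy left-to-right scan per chromosome: the first site is kept, then each
#' subsequent site is kept only if it lies at least `min_bp` downstream of the
#' last kept site. Deterministic; `min_bp = 0` is the identity. The thinning
#' dialect is recorded in the `thinning` attribute of the result.
#'
#' @param x a `genotype_matrix`.
#' @param min_bp minimum separation in base pairs (>= 0).
#' @return A `genotype_matrix` restricted to the kept sites.
#' @export
thin_by_distance <- function(x, min_bp) {
  stopifnot(inherits(x, "genotype_matrix"), min_bp >= 0)
  keep <- logical(ncol(x$genotypes))
  for (ch in unique(x$sites$chrom)) {
    idx <- which(x$sites$chrom == ch)
    last <- -Inf
    for (i in idx) {
      if (x$sites$pos[i] - last >= min_bp) {
        keep[i] <- TRUE
        last <- x$sites$pos[i]
      }
    }
  }
  out <- subset_matrix(x, sites = keep)
  attr(out, "thinning") <- sprintf("greedy-from-left, min_bp=%d",
                                   as.integer(min_bp))
  out
}

#' Filter sites by missing-genotype fraction
#'
#' Removes sites whose fraction of missing genotypes — computed over the
#' samples of `groups`, or over all samples when `groups` is `NULL` — exceeds
#' `max_missing_frac`. Surviving genotype values are never altered, only site
#' membership. `max_missing_frac = 0` keeps fully genotyped sites only;
#' `max_missing_frac = 1` is the identity.
#'
#' @param x a `genotype_matrix`.
#' @param max_missing_frac maximum tolerated missing fraction, in [0, 1].
#' @param groups optional group labels restricting the samples over which
#'   missingness is assessed.
#' @param drop_monomorphic also remove sites monomorphic (across all samples)
#'   after the missingness filter; default `FALSE`.
#' @return A filtered `genotype_matrix`; the number of removed sites is
#'   reported with `message()`.
#' @export
filter_sites <- function(x, max_missing_frac, groups = NULL,
                         drop_monomorphic = FALSE) {
  stopifnot(inherits(x, "genotype_matrix"),
            max_missing_frac >= 0, max_missing_frac <= 1)
  rows <- if (is.null(groups)) seq_len(nrow(x$genotypes)) else {
    unknown <- setdiff(groups, unique(x$samples$group))
    if (length(unknown)) stop("unknown group(s): ",
                              paste(unknown, collapse = ", "))
    group_rows(x, groups)
  }
  miss <- colMeans(is.na(x$genotypes[rows, , drop = FALSE]))
  keep <- miss <= max_missing_frac
  if (drop_monomorphic) {
    g <- x$genotypes[, keep, drop = FALSE]
    rng <- apply(g, 2, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) 0 else max(v) - min(v)
    })
    keep[keep] <- rng > 0
  }
  message("filter_sites: removed ", sum(!keep), " of ", length(keep),
          " site(s)")
  subset_matrix(x, sites = keep)
}
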