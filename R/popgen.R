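#' Per-site Weir & Cockerham variance components
#'
#' Computes, for two populations, the per-site among-population (`a`),
#' among-individuals-within-population (`b`) and within-individual (`c`)
#' variance components of the Weir & Cockerham (1984) Fst estimator from
#' genotype counts, allowing unequal and site-varying sample sizes. Sites
#' monomorphic across both groups, or with fewer than two genotyped
#' individuals in either group, are returned with `usable = FALSE`.
#'
#' @param x a `genotype_matrix`.
#' @param groupA,groupB group labels.
#' @return data.frame with `chrom`, `pos`, `a`, `b`, `c`, `usable`.
#' @export
wc_fst_components <- function(x, groupA, groupB) {
  stopifnot(inherits(x, "genotype_matrix"))
  comp <- lapply(c(groupA, groupB), function(grp) {
    g <- x$genotypes[group_rows(x, grp), , drop = FALSE]
    n <- colSums(!is.na(g))
    list(n = n,
         p = colSums(g, na.rm = TRUE) / (2 * n),
         h = colSums(g == 1L, na.rm = TRUE) / n)
  })
  n1 <- comp[[1]]$n; n2 <- comp[[2]]$n
  p1 <- comp[[1]]$p; p2 <- comp[[2]]$p
  h1 <- comp[[1]]$h; h2 <- comp[[2]]$h
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  usable <- n1 >= 2 & n2 >= 2 & !is.na(pbar) & pbar > 0 & pbar < 1
  data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
             a = a, b = b, c = cc, usable = usable)
}

#' Windowed Weir & Cockerham Fst
#'
#' Sums the per-site Weir & Cockerham variance components over
#' non-overlapping physical windows `[start, start + window_bp)` and reports
#' the weighted window estimate `sum(a) / sum(a + b + c)` together with the
#' mean of the per-site ratios. Negative window values are preserved, not
#' clipped. Windows with no usable site are emitted with `n_sites = 0` and
#' `NA` Fst.
#'
#' @param x a `genotype_matrix`.
#' @param groupA,groupB group labels (each needs >= 2 genotyped individuals
#'   at contributing sites).
#' @param window_bp window size in base pairs (default 10 kb).
#' @return List with `windows` (data.frame: `chrom`, `start`, `end`,
#'   `n_sites`, `weighted_fst`, `mean_fst`), `median_weighted_fst` (genome-wide
#'   median over non-empty windows) and `genome_weighted_fst` (single ratio
#'   over all usable sites).
#' @export
windowed_fst <- function(x, groupA, groupB, window_bp = 10000) {
  comp <- wc_fst_components(x, groupA, groupB)
  used <- comp[comp$usable, , drop = FALSE]
  win_of <- function(pos) (pos - 1L) %/% window_bp
  windows <- do.call(rbind, lapply(unique(comp$chrom), function(ch) {
    pos_all <- comp$pos[comp$chrom == ch]
    w_range <- 0:win_of(max(pos_all))
    u <- used[used$chrom == ch, , drop = FALSE]
    w_u <- win_of(u$pos)
    do.call(rbind, lapply(w_range, function(w) {
      s <- u[w_u == w, , drop = FALSE]
      tot <- sum(s$a + s$b + s$c)
      ratio <- s$a / (s$a + s$b + s$c)
      data.frame(
        chrom = ch, start = w * window_bp + 1L,
        end = (w + 1L) * window_bp,
        n_sites = nrow(s),
        weighted_fst = if (nrow(s) && tot != 0) sum(s$a) / tot else NA_real_,
        mean_fst = if (nrow(s)) mean(ratio[is.finite(ratio)]) else NA_real_
      )
    }))
  }))
  rownames(windows) <- NULL
  list(
    windows = windows,
    median_weighted_fst = stats::median(windows$weighted_fst, na.rm = TRUE),
    genome_weighted_fst = sum(used$a) / sum(used$a + used$b + used$c)
  )
}

#' Principal-component scores of the genotype dosage matrix
#'
#' Mean-imputes missing dosages per site, centers each site (no variance
#' scaling by default, matching standard genotype-PCA practice) and
#' eigendecomposes the sample covariance. Component signs are made
#' deterministic by forcing each component's largest-magnitude site loading
#' to be positive.
#'
#' @param x a `genotype_matrix` with >= 2 samples and >= 2 polymorphic sites.
#' @param n_components number of components to return.
#' @param scale also scale each site to unit variance (default `FALSE`).
#' @return List with `scores` (data.frame: `sample_id`, `group`, `PC1`...),
#'   `explained_variance` (fractions) and `rotation` (site loadings).
#' @export
pca_scores <- function(x, n_components = 6, scale = FALSE) {
  stopifnot(inherits(x, "genotype_matrix"), nrow(x$genotypes) >= 2)
  g <- x$genotypes
  mu <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]
  v <- apply(g, 2, stats::var)
  poly <- which(v > 0)
  if (length(poly) < 2) stop("need at least two polymorphic sites")
  g <- g[, poly, drop = FALSE]
  pc <- stats::prcomp(g, center = TRUE, scale. = scale)
  k <- min(n_components, ncol(pc$x))
  flip <- vapply(seq_len(k), function(j) {
    load <- pc$rotation[, j]
    sign(load[which.max(abs(load))]) < 0
  }, logical(1))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rotation <- pc$rotation[, seq_len(k), drop = FALSE]
  scores[, flip] <- -scores[, flip, drop = FALSE]
  rotation[, flip] <- -rotation[, flip, drop = FALSE]
  list(
    scores = data.frame(sample_id = x$samples$sample_id,
                        group = x$samples$group, scores,
                        row.names = NULL),
    explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
    rotation = rotation
  )
}
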