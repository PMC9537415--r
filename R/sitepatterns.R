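#' Site-pattern contributions for the hybridization invariants test
#'
#' For a quartet (outgroup, P1, hybrid, P2), computes per-site
#' frequency-weighted contributions to the three informative site patterns.
#' Derived-allele frequencies `d` are obtained by polarizing every group on
#' the outgroup major allele (`d` = alt frequency when the outgroup alt
#' frequency is <= 0.5, else `1 -` alt frequency); sites with outgroup alt
#' frequency exactly 0.5 are skipped as unpolarizable. Contributions are
#' `x1 = d_P1 d_H (1 - d_P2)(1 - d_O)` (hybrid shares derived with P1),
#' `x2 = (1 - d_P1) d_H d_P2 (1 - d_O)` (hybrid shares derived with P2) and
#' `x3 = d_P1 (1 - d_H) d_P2 (1 - d_O)` (parents share derived, hybrid
#' excluded). Sites monomorphic across the ingroup, or with no genotyped
#' individual in any group, are skipped and counted.
#'
#' @param x a `genotype_matrix`.
#' @param outgroup,p1,hybrid,p2 group labels of the quartet.
#' @return An object of class `pattern_counts`: totals `x1`, `x2`, `x3`, a
#'   per-site contribution table, the quartet labels and skip counts.
#' @export
pattern_frequencies <- function(x, outgroup, p1, hybrid, p2) {
  stopifnot(inherits(x, "genotype_matrix"))
  grp <- c(outgroup = outgroup, p1 = p1, hybrid = hybrid, p2 = p2)
  cnt <- lapply(grp, function(g) group_alt_count(x, g))
  n_ok <- Reduce(`&`, lapply(cnt, function(ct) ct$n > 0))
  f <- lapply(cnt, function(ct) ct$alt / (2 * ct$n))

  flip <- !is.na(f$outgroup) & f$outgroup > 0.5
  ambiguous <- !is.na(f$outgroup) & f$outgroup == 0.5
  d <- lapply(f, function(p) ifelse(flip, 1 - p, p))
  ingroup_mono <-
    (d$p1 == 0 & d$hybrid == 0 & d$p2 == 0) |
    (d$p1 == 1 & d$hybrid == 1 & d$p2 == 1)
  use <- n_ok & !ambiguous & !ingroup_mono
  c1 <- d$p1 * d$hybrid * (1 - d$p2) * (1 - d$outgroup)
  c2 <- (1 - d$p1) * d$hybrid * d$p2 * (1 - d$outgroup)
  c3 <- d$p1 * (1 - d$hybrid) * d$p2 * (1 - d$outgroup)
  per_site <- data.frame(
    chrom = x$sites$chrom[use], pos = x$sites$pos[use],
    x1 = c1[use], x2 = c2[use], x3 = c3[use]
  )
  structure(list(
    quartet = grp,
    x1 = sum(per_site$x1), x2 = sum(per_site$x2), x3 = sum(per_site$x3),
    per_site = per_site,
    n_sites = nrow(per_site),
    n_skipped_missing = sum(!n_ok),
    n_skipped_ambiguous = sum(ambiguous & n_ok),
    n_skipped_monomorphic = sum(ingroup_mono & n_ok & !ambiguous)
  ), class = "pattern_counts")
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat(sprintf("pattern_counts (%s; P1=%s, hybrid=%s, P2=%s): %d sites\n",
              x$quartet[["outgroup"]], x$quartet[["p1"]],
              x$quartet[["hybrid"]], x$quartet[["p2"]], x$n_sites))
  cat(sprintf("  x1=%.3f  x2=%.3f  x3=%.3f\n", x$x1, x$x2, x$x3))
  invisible(x)
}

#' Invariants-based hybridization test with gamma estimation
#'
#' Estimates the fraction `gamma` of the putative hybrid's ancestry derived
#' from P1 as `(x1 - x3) / ((x1 - x3) + (x2 - x3))` and tests for
#' hybridization with a delete-one block jackknife over contiguous site
#' blocks. The test statistic is `f_min = min(x1 - x3, x2 - x3)`: a genuine
#' hybrid must share an excess of derived alleles with BOTH parents, so the
#' smaller excess must be significantly positive. `Z = f_min / SE_jack` and
#' the one-tailed p-value is `1 - pnorm(Z)`.
#'
#' @param pat a `pattern_counts` object.
#' @param n_blocks number of contiguous equal-count site blocks for the
#'   jackknife (default 100).
#' @return An object of class `hybridization_test` with fields `quartet`,
#'   `x1`, `x2`, `x3`, `gamma`, `z`, `p`, `n_sites`, `n_blocks` and
#'   `no_signal` (`TRUE`, with `gamma` clamped to [0,1], when either derived
#'   excess is non-positive).
#' @export
gamma_test <- function(pat, n_blocks = 100) {
  stopifnot(inherits(pat, "pattern_counts"))
  if (pat$n_sites < n_blocks) {
    stop("need at least n_blocks (", n_blocks, ") informative sites, have ",
         pat$n_sites)
  }
  e1 <- pat$x1 - pat$x3
  e2 <- pat$x2 - pat$x3
  denom <- e1 + e2
  no_signal <- denom <= 0 || e1 <= 0 || e2 <= 0
  gamma <- if (denom > 0) min(max(e1 / denom, 0), 1) else NA_real_

  block <- as.integer(cut(seq_len(pat$n_sites), n_blocks, labels = FALSE))
  bx <- vapply(c("x1", "x2", "x3"), function(k) {
    as.numeric(tapply(pat$per_site[[k]], block, sum))
  }, numeric(n_blocks))
  f_min <- min(e1, e2)
  theta <- vapply(seq_len(n_blocks), function(i) {
    x1 <- pat$x1 - bx[i, "x1"]
    x2 <- pat$x2 - bx[i, "x2"]
    x3 <- pat$x3 - bx[i, "x3"]
    min(x1 - x3, x2 - x3)
  }, numeric(1))
  se <- sqrt((n_blocks - 1) / n_blocks * sum((theta - mean(theta))^2))
  z <- if (se > 0) f_min / se else ifelse(f_min > 0, Inf, 0)
  structure(list(
    quartet = pat$quartet,
    x1 = pat$x1, x2 = pat$x2, x3 = pat$x3,
    gamma = gamma, z = z, p = stats::pnorm(z, lower.tail = FALSE),
    n_sites = pat$n_sites, n_blocks = n_blocks, no_signal = no_signal
  ), class = "hybridization_test")
}

#' @export
print.hybridization_test <- function(x, ...) {
  cat(sprintf(
    "hybridization test: gamma = %.3f (share from P1=%s), Z = %.2f, p = %.4g\n",
    x$gamma, x$quartet[["p1"]], x$z, x$p))
  if (x$no_signal) cat("  note: no hybridization signal (an excess is <= 0)\n")
  cat(sprintf("  x1=%.3f x2=%.3f x3=%.3f over %d sites, %d jackknife blocks\n",
              x$x1, x$x2, x$x3, x$n_sites, x$n_blocks))
  invisible(x)
}

#' SNP quartet concordance factors
#'
#' Samples `n_quartets` individual quartets (one individual per species,
#' uniformly with replacement) and, for each, draws one allele per individual
#' per biallelic site (`mode = "sample"`, the default) or uses both alleles
#' of homozygous individuals only (`mode = "both"`). A site is informative
#' for a quartet when exactly two sampled alleles are of each type; each
#' informative site then supports exactly one of the three resolutions of
#' the quartet. Per-quartet concordance factors are the supported fractions;
#' the returned CFs average over quartets.
#'
#' @param x a `genotype_matrix`.
#' @param species character vector of four group labels.
#' @param n_quartets number of individual quartets to sample (default 100).
#' @param seed optional RNG seed.
#' @param mode allele handling, `"sample"` or `"both"` (see above).
#' @return An object of class `quartet_cf`: `species`, `cf` (named vector of
#'   the three splits, summing to 1), `cf_per_quartet` matrix, `n_quartets`,
#'   and `mean_informative_sites`.
#' @export
snp_concordance_factors <- function(x, species, n_quartets = 100, seed = NULL,
                                    mode = c("sample", "both")) {
  stopifnot(inherits(x, "genotype_matrix"), length(species) == 4)
  mode <- match.arg(mode)
  rows <- lapply(species, function(s) group_rows(x, s))
  splits <- c(
    paste0(species[1], species[2], "|", species[3], species[4]),
    paste0(species[1], species[3], "|", species[2], species[4]),
    paste0(species[1], species[4], "|", species[2], species[3])
  )
  run <- function() {
    L <- ncol(x$genotypes)
    cf_q <- matrix(NA_real_, n_quartets, 3, dimnames = list(NULL, splits))
    n_inf <- integer(n_quartets)
    for (q in seq_len(n_quartets)) {
      ind <- vapply(rows, function(r) r[sample.int(length(r), 1)], integer(1))
      g <- x$genotypes[ind, , drop = FALSE]
      al <- if (mode == "sample") {
        a <- matrix(NA_integer_, 4, L)
        ok <- !is.na(g)
        a[ok] <- stats::rbinom(sum(ok), 1L, g[ok] / 2)
        a
      } else {
        a <- g / 2
        a[g == 1L] <- NA          # heterozygotes uninformative in "both" mode
        a
      }
      complete <- colSums(is.na(al)) == 0L
      tot <- colSums(al, na.rm = TRUE)
      inf <- complete & tot == 2L
      n_inf[q] <- sum(inf)
      if (!any(inf)) next
      a <- al[, inf, drop = FALSE]
      s12 <- a[1, ] == a[2, ]
      s13 <- a[1, ] == a[3, ]
      counts <- c(sum(s12), sum(s13), sum(!s12 & !s13))
      cf_q[q, ] <- counts / sum(counts)
    }
    cf <- colMeans(cf_q, na.rm = TRUE)
    structure(list(
      species = species, cf = cf, cf_per_quartet = cf_q,
      n_quartets = n_quartets, mean_informative_sites = mean(n_inf),
      mode = mode
    ), class = "quartet_cf")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.quartet_cf <- function(x, ...) {
  cat("quartet concordance factors (", x$n_quartets, " quartets, mode=",
      x$mode, "):\n", sep = "")
  for (k in names(x$cf)) cat(sprintf("  %s: %.4f\n", k, x$cf[[k]]))
  cat(sprintf("  mean informative sites per quartet: %.1f\n",
              x$mean_informative_sites))
  invisible(x)
}
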