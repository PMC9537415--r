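group_alt_freq <- function(x, group) {
  site_frequencies(x, group_rows(x, group))
}

group_alt_count <- function(x, group) {
  g <- x$genotypes[group_rows(x, group), , drop = FALSE]
  list(alt = colSums(g, na.rm = TRUE),
       n = colSums(!is.na(g)))
}

#' Private high-frequency alleles of a focal group
#'
#' Finds biallelic sites carrying an allele that segregates at frequency
#' `>= min_freq` (but below fixation, so the focal group is polymorphic) in
#' the focal group while having zero copies among the genotyped individuals
#' of every other named group. Frequencies are computed from genotyped
#' (non-missing) individuals only; sites where any involved group has no
#' genotyped individual are skipped and counted.
#'
#' @param x a `genotype_matrix`.
#' @param focal focal group label.
#' @param others character vector of comparison group labels (disjoint from
#'   `focal`).
#' @param min_freq minimum private-allele frequency in the focal group
#'   (default 0.5).
#' @param criterion `"freq"` applies `min_freq` to the allele frequency;
#'   `"carrier"` applies it to the fraction of focal individuals carrying at
#'   least one copy.
#' @return data.frame with `chrom`, `pos`, `allele` (`"ref"` or `"alt"`),
#'   `focal_freq` and `carrier_frac`; attribute `n_skipped` counts sites
#'   skipped for lack of genotyped individuals.
#' @export
private_alleles <- function(x, focal, others, min_freq = 0.5,
                            criterion = c("freq", "carrier")) {
  criterion <- match.arg(criterion)
  if (focal %in% others) stop("focal and others must be disjoint")
  fc <- group_alt_count(x, focal)
  oc <- lapply(others, function(g) group_alt_count(x, g))
  gf <- x$genotypes[group_rows(x, focal), , drop = FALSE]

  usable <- fc$n > 0
  for (o in oc) usable <- usable & o$n > 0
  n_skipped <- sum(!usable)

  res <- list()
  for (allele in c("ref", "alt")) {
    cnt <- if (allele == "alt") fc$alt else 2 * fc$n - fc$alt
    f <- cnt / (2 * fc$n)
    carrier <- if (allele == "alt") {
      colMeans(gf >= 1, na.rm = TRUE)
    } else {
      colMeans(gf <= 1, na.rm = TRUE)
    }
    absent_elsewhere <- usable
    for (o in oc) {
      ocnt <- if (allele == "alt") o$alt else 2 * o$n - o$alt
      absent_elsewhere <- absent_elsewhere & ocnt == 0
    }
    crit <- if (criterion == "freq") f >= min_freq else carrier >= min_freq
    hit <- which(usable & crit & f < 1 & absent_elsewhere)
    if (length(hit)) {
      res[[allele]] <- data.frame(
        chrom = x$sites$chrom[hit], pos = x$sites$pos[hit],
        allele = allele, focal_freq = f[hit], carrier_frac = carrier[hit]
      )
    }
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(chrom = character(), pos = integer(), allele = character(),
               focal_freq = numeric(), carrier_frac = numeric())
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "criterion") <- criterion
  out
}

#' Fixed differences between two groups
#'
#' Sites where the two groups are fixed for alternative alleles: one allele
#' at frequency exactly 1 in `groupA` and exactly 0 in `groupB` (orientation
#' recorded). No physical-distance thinning is applied.
#'
#' @param x a `genotype_matrix`.
#' @param groupA,groupB group labels.
#' @return data.frame with `chrom`, `pos`, `orientation` (which VCF allele,
#'   `"ref"` or `"alt"`, is the group-A allele).
#' @export
fixed_differences <- function(x, groupA, groupB) {
  ca <- group_alt_count(x, groupA)
  cb <- group_alt_count(x, groupB)
  usable <- ca$n > 0 & cb$n > 0
  fa <- ca$alt / (2 * ca$n)
  fb <- cb$alt / (2 * cb$n)
  alt_fixed <- usable & fa == 1 & fb == 0
  ref_fixed <- usable & fa == 0 & fb == 1
  hit <- which(alt_fixed | ref_fixed)
  out <- data.frame(
    chrom = x$sites$chrom[hit], pos = x$sites$pos[hit],
    orientation = ifelse(alt_fixed[hit], "alt", "ref")
  )
  out[order(out$chrom, out$pos), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Build a diagnostic marker panel from a parental frequency contrast
#'
#' Selects sites where one allele has frequency `>= hi` in `groupA` and
#' `<= lo` in `groupB`, orients each site so the "parental-A allele" is the
#' allele at high frequency in `groupA`, and thins the candidates with
#' [thin_by_distance()]. With `hi = 1, lo = 0` the panel equals
#' [fixed_differences()] after thinning.
#'
#' @param x a `genotype_matrix`.
#' @param groupA,groupB parental group labels.
#' @param hi minimum frequency of the diagnostic allele in `groupA`
#'   (default 0.95).
#' @param lo maximum frequency of the same allele in `groupB` (default 0.05).
#' @param thin_bp minimum physical separation of panel sites (default 50 kb;
#'   0 disables thinning).
#' @return An object of class `diagnostic_panel`: data.frame with `chrom`,
#'   `pos`, `orientation`, `freqA`, `freqB` (frequencies of the parental-A
#'   allele in each parental group); thresholds stored as attributes.
#' @export
diagnostic_panel <- function(x, groupA, groupB, hi = 0.95, lo = 0.05,
                             thin_bp = 50000) {
  stopifnot(hi > lo)
  ca <- group_alt_count(x, groupA)
  cb <- group_alt_count(x, groupB)
  usable <- ca$n > 0 & cb$n > 0
  fa <- ca$alt / (2 * ca$n)
  fb <- cb$alt / (2 * cb$n)
  eps <- 1e-9   # count ratios like 19/20 sit just below the printed threshold
  alt_diag <- usable & fa >= hi - eps & fb <= lo + eps
  ref_diag <- usable & (1 - fa) >= hi - eps & (1 - fb) <= lo + eps
  keep <- alt_diag | ref_diag
  if (!any(keep)) {
    warning("no sites satisfy the diagnostic frequency contrast")
    panel <- data.frame(chrom = character(), pos = integer(),
                        orientation = character(),
                        freqA = numeric(), freqB = numeric())
  } else {
    thinned <- thin_by_distance(subset_matrix(x, sites = keep), thin_bp)
    idx <- match(paste(thinned$sites$chrom, thinned$sites$pos),
                 paste(x$sites$chrom, x$sites$pos))
    ori <- ifelse(alt_diag[idx], "alt", "ref")
    panel <- data.frame(
      chrom = x$sites$chrom[idx], pos = x$sites$pos[idx],
      orientation = ori,
      freqA = ifelse(ori == "alt", fa[idx], 1 - fa[idx]),
      freqB = ifelse(ori == "alt", fb[idx], 1 - fb[idx])
    )
    rownames(panel) <- NULL
  }
  structure(panel, class = c("diagnostic_panel", "data.frame"),
            hi = hi, lo = lo, groupA = groupA, groupB = groupB)
}

#' Recode genotypes against a diagnostic panel
#'
#' Re-expresses each genotype at the panel sites as the number of copies of
#' the non-parental-A allele: 0 = homozygous for the parental-A allele,
#' 1 = heterozygous, 2 = homozygous for the alternative parental variant.
#' Missing genotypes propagate.
#'
#' @param x a `genotype_matrix` containing every panel site.
#' @param panel a `diagnostic_panel`.
#' @return A `coded_matrix`: list with `codes` (samples x panel sites),
#'   `samples` and the `panel`.
#' @export
recode_genotypes <- function(x, panel) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(panel, "diagnostic_panel"))
  idx <- match(paste(panel$chrom, panel$pos),
               paste(x$sites$chrom, x$sites$pos))
  if (anyNA(idx)) {
    stop(sum(is.na(idx)), " panel site(s) absent from the genotype matrix")
  }
  g <- x$genotypes[, idx, drop = FALSE]
  flip <- panel$orientation == "alt"
  codes <- g
  codes[, flip] <- 2L - g[, flip, drop = FALSE]
  structure(list(codes = codes, samples = x$samples, panel = panel),
            class = "coded_matrix")
}

#' @export
print.coded_matrix <- function(x, ...) {
  cat("coded_matrix:", nrow(x$codes), "samples x", ncol(x$codes),
      "diagnostic sites\n")
  invisible(x)
}
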