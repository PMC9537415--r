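## Explicit pedigree individuals (F1, F2, first-generation backcrosses) with
## per-haplotype true-ancestry bookkeeping, used as ground truth for the
## ancestry and classification estimators.

founder_haplotypes <- function(p, ancestry) {
  L <- length(p)
  alleles <- matrix(stats::rbinom(2L * L, 1L, rep(p, each = 2L)), nrow = 2L)
  list(alleles = alleles,
       ancestry = matrix(ancestry, 2L, L))
}

## One meiosis: crossovers fall as a Poisson process on the genetic map
## (uniform recomb_rate cM/Mb, 1 cM = 1% recombination), independently per
## chromosome; the transmitted haplotype alternates between the parent's two
## haplotypes at each breakpoint, starting from a random one.
make_gamete <- function(parent, sites, recomb_rate) {
  L <- ncol(parent$alleles)
  allele <- integer(L)
  ancestry <- character(L)
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    span <- max(pos)
    morgans <- span / 1e6 * recomb_rate / 100
    n_xo <- stats::rpois(1L, morgans)
    breaks <- sort(stats::runif(n_xo, 0, span))
    start <- sample.int(2L, 1L)
    hap <- 1L + (start - 1L + findInterval(pos, breaks)) %% 2L
    take <- cbind(hap, idx)
    allele[idx] <- parent$alleles[take]
    ancestry[idx] <- parent$ancestry[take]
  }
  list(allele = allele, ancestry = ancestry)
}

cross <- function(mother, father, sites, recomb_rate) {
  g1 <- make_gamete(mother, sites, recomb_rate)
  g2 <- make_gamete(father, sites, recomb_rate)
  list(alleles = rbind(g1$allele, g2$allele),
       ancestry = rbind(g1$ancestry, g2$ancestry))
}

#' Generate pedigree individuals with known ancestry
#'
#' Builds explicit crosses from parental founders sampled under
#' Hardy-Weinberg equilibrium at the parental population frequencies:
#' F1 = A-founder x B-founder, F2 = F1 x F1 (independent F1s), BC1A = F1 x
#' A-founder, BC1B = F1 x B-founder. Every haplotype carries a per-locus
#' true-ancestry label (`"A"` or `"B"`) that is propagated through the
#' simulated crossovers, so each individual's realised ancestry proportion
#' and interclass heterozygosity are known exactly.
#'
#' @param freqs a `pop_frequencies` object.
#' @param config a [sim_config()]; `pedigree_counts` says how many of each
#'   class (`F1`, `F2`, `BC1A`, `BC1B`) to produce, `recomb_rate` sets the
#'   genetic map.
#' @param seed optional seed; default derives from `config$seed`.
#' @return An object of class `pedigree_set`: a list of individuals, each
#'   with `id`, `class`, a 2 x loci allele matrix and a matching ancestry
#'   label matrix.
#' @export
make_pedigree <- function(freqs, config, seed = config$seed + 101L) {
  stopifnot(inherits(freqs, "pop_frequencies"))
  counts <- config$pedigree_counts
  counts <- counts[counts > 0]
  if (!length(counts)) stop("pedigree_counts is empty")
  unknown <- setdiff(names(counts), c("F1", "F2", "BC1A", "BC1B"))
  if (length(unknown)) stop("unknown pedigree class: ",
                            paste(unknown, collapse = ", "))
  pA <- freqs$freq[, "parentalA"]
  pB <- freqs$freq[, "parentalB"]
  sites <- freqs$sites
  rr <- config$recomb_rate

  build <- function() {
    new_f1 <- function() {
      cross(founder_haplotypes(pA, "A"), founder_haplotypes(pB, "B"),
            sites, rr)
    }
    inds <- list()
    for (cls in names(counts)) {
      for (i in seq_len(counts[[cls]])) {
        ind <- switch(cls,
          F1 = new_f1(),
          F2 = cross(new_f1(), new_f1(), sites, rr),
          BC1A = cross(new_f1(), founder_haplotypes(pA, "A"), sites, rr),
          BC1B = cross(new_f1(), founder_haplotypes(pB, "B"), sites, rr)
        )
        ind$id <- sprintf("%s_%02d", cls, i)
        ind$class <- cls
        inds[[ind$id]] <- ind
      }
    }
    structure(inds, class = "pedigree_set")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' @export
print.pedigree_set <- function(x, ...) {
  cls <- table(vapply(x, `[[`, "", "class"))
  cat("pedigree_set:", length(x), "individuals (",
      paste(names(cls), cls, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Realised ancestry truth for pedigree individuals
#'
#' @param peds a `pedigree_set`.
#' @return data.frame with `id`, `class`, `true_S` (fraction of alleles of
#'   parental-A ancestry) and `true_H` (fraction of loci with one allele of
#'   each ancestry).
#' @export
pedigree_truth <- function(peds) {
  stopifnot(inherits(peds, "pedigree_set"))
  do.call(rbind, lapply(peds, function(ind) {
    data.frame(
      id = ind$id,
      class = ind$class,
      true_S = mean(ind$ancestry == "A"),
      true_H = mean(ind$ancestry[1, ] != ind$ancestry[2, ])
    )
  })) -> out
  rownames(out) <- NULL
  out
}

#' Convert pedigree individuals to a genotype matrix
#'
#' @param peds a `pedigree_set`.
#' @param freqs the `pop_frequencies` the pedigree was built from (site
#'   coordinates).
#' @return A `genotype_matrix` whose group labels are the pedigree classes.
#' @export
pedigree_genotypes <- function(peds, freqs) {
  stopifnot(inherits(peds, "pedigree_set"))
  g <- do.call(rbind, lapply(peds, function(ind) colSums(ind$alleles)))
  genotype_matrix(
    g,
    samples = data.frame(sample_id = vapply(peds, `[[`, "", "id"),
                         group = vapply(peds, `[[`, "", "class")),
    sites = data.frame(freqs$sites, ref = "A", alt = "T")
  )
}

#' Simulate a complete labelled dataset
#'
#' Runs [simulate_frequencies()], samples every population with a positive
#' entry in `sample_sizes`, generates the requested pedigree individuals, and
#' combines everything into one `genotype_matrix` plus a truth table. With
#' `out_prefix` set, writes `<prefix>.vcf` (via [write_vcf()]),
#' `<prefix>.groups.tsv` (sample_id, group, true_class) and
#' `<prefix>.truth.tsv` (per-individual true S, true H, class).
#'
#' @param config a [sim_config()].
#' @param out_prefix optional path prefix for output files.
#' @return List with `matrix` (genotype_matrix), `truth` (data.frame),
#'   `freqs` (pop_frequencies).
#' @export
simulate_dataset <- function(config, out_prefix = NULL) {
  freqs <- simulate_frequencies(config)
  ss <- config$sample_sizes[config$sample_sizes > 0]
  mats <- lapply(names(ss), function(grp) {
    sample_population(freqs, grp, ss[[grp]],
                      seed = config$seed + 7L + match(grp, names(ss)))
  })
  truth <- do.call(rbind, lapply(names(ss), function(grp) {
    expected <- switch(grp,
                       parentalA = c(1, 0), parentalB = c(0, 0),
                       hybrid = c(config$phi, NA_real_),
                       outgroup = c(NA_real_, NA_real_))
    data.frame(id = sprintf("%s_%02d", grp, seq_len(ss[[grp]])),
               class = grp, true_S = expected[1], true_H = expected[2])
  }))
  if (any(config$pedigree_counts > 0)) {
    peds <- make_pedigree(freqs, config)
    mats <- c(mats, list(pedigree_genotypes(peds, freqs)))
    truth <- rbind(truth, pedigree_truth(peds))
  }
  geno <- do.call(rbind, lapply(mats, `[[`, "genotypes"))
  samples <- do.call(rbind, lapply(mats, `[[`, "samples"))
  rownames(samples) <- NULL
  mat <- genotype_matrix(geno, samples, mats[[1]]$sites)
  rownames(truth) <- NULL
  if (!is.null(out_prefix)) {
    write_vcf(mat, paste0(out_prefix, ".vcf"))
    utils::write.table(
      data.frame(sample_id = samples$sample_id, group = samples$group,
                 true_class = truth$class),
      paste0(out_prefix, ".groups.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, paste0(out_prefix, ".truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(matrix = mat, truth = truth, freqs = freqs)
}
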