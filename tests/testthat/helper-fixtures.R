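## Shared fixtures and independent brute-force oracles.

## Frequencies with every locus on its own chromosome, so pedigree meioses
## assort loci independently (Mendelian expectations hold exactly).
unlinked_freqs <- function(L, pA, pB, pH = 0.5, pO = 0.5) {
  pop_frequencies(
    cbind(parentalA = rep_len(pA, L), parentalB = rep_len(pB, L),
          hybrid = rep_len(pH, L), outgroup = rep_len(pO, L)),
    data.frame(chrom = sprintf("chr%03d", seq_len(L)), pos = 1000L)
  )
}

## Parental populations fixed for alternative alleles at L unlinked loci,
## plus the requested pedigree classes; returns matrix, panel, coded codes.
fixed_panel_dataset <- function(L = 148, nA = 10, nB = 10,
                                pedigree = c(F1 = 3, F2 = 3, BC1A = 3, BC1B = 3),
                                seed = 42) {
  f <- unlinked_freqs(L, pA = 1, pB = 0)
  cfg <- sim_config(n_loci = L, tau_split = 10, tau_hybrid = 1,
                    tau_outgroup = 40, pedigree_counts = pedigree,
                    recomb_rate = 1, seed = seed)
  pa <- sample_population(f, "parentalA", nA, seed = seed + 1)
  pb <- sample_population(f, "parentalB", nB, seed = seed + 2)
  peds <- make_pedigree(f, cfg, seed = seed + 3)
  pg <- pedigree_genotypes(peds, f)
  mat <- genotype_matrix(
    rbind(pa$genotypes, pb$genotypes, pg$genotypes),
    rbind(pa$samples, pb$samples, pg$samples),
    pa$sites
  )
  panel <- diagnostic_panel(mat, "parentalA", "parentalB", hi = 1, lo = 0,
                            thin_bp = 0)
  list(matrix = mat, panel = panel, coded = recode_genotypes(mat, panel),
       peds = peds, freqs = f)
}

## Random small genotype matrix with group labels and optional missingness.
random_matrix <- function(n_samples, n_sites, groups, miss = 0, seed = 7) {
  withr::with_seed(seed, {
    g <- matrix(sample(0:2, n_samples * n_sites, replace = TRUE), n_samples)
    if (miss > 0) g[stats::runif(length(g)) < miss] <- NA
    genotype_matrix(
      g,
      data.frame(sample_id = sprintf("s%02d", seq_len(n_samples)),
                 group = rep_len(groups, n_samples)),
      data.frame(chrom = "chr1", pos = sort(sample.int(1e6, n_sites)),
                 ref = "A", alt = "T")
    )
  })
}

## --- independent oracles -------------------------------------------------

## Greedy distance thinning, written as the plainest possible scan.
oracle_thin_keep <- function(sites, min_bp) {
  keep <- rep(FALSE, nrow(sites))
  for (ch in unique(sites$chrom)) {
    last_kept <- NA
    for (i in which(sites$chrom == ch)) {
      if (is.na(last_kept) || sites$pos[i] - last_kept >= min_bp) {
        keep[i] <- TRUE
        last_kept <- sites$pos[i]
      }
    }
  }
  keep
}

## Exhaustive private-allele scan (allele frequency criterion).
oracle_private <- function(mat, focal, others, min_freq = 0.5) {
  hits <- NULL
  for (j in seq_len(ncol(mat$genotypes))) {
    for (allele in c("ref", "alt")) {
      gf <- mat$genotypes[mat$samples$group == focal, j]
      gf <- gf[!is.na(gf)]
      if (!length(gf)) next
      cnt <- if (allele == "alt") sum(gf) else sum(2 - gf)
      f <- cnt / (2 * length(gf))
      absent <- TRUE
      for (o in others) {
        go <- mat$genotypes[mat$samples$group == o, j]
        go <- go[!is.na(go)]
        if (!length(go)) { absent <- FALSE; break }
        ocnt <- if (allele == "alt") sum(go) else sum(2 - go)
        if (ocnt != 0) { absent <- FALSE; break }
      }
      if (absent && f >= min_freq && f < 1) {
        hits <- rbind(hits, data.frame(chrom = mat$sites$chrom[j],
                                       pos = mat$sites$pos[j],
                                       allele = allele))
      }
    }
  }
  hits
}

## Exhaustive fixed-difference scan.
oracle_fixed <- function(mat, groupA, groupB) {
  hits <- NULL
  for (j in seq_len(ncol(mat$genotypes))) {
    ga <- mat$genotypes[mat$samples$group == groupA, j]
    gb <- mat$genotypes[mat$samples$group == groupB, j]
    ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
    if (!length(ga) || !length(gb)) next
    fa <- sum(ga) / (2 * length(ga))
    fb <- sum(gb) / (2 * length(gb))
    if ((fa == 1 && fb == 0) || (fa == 0 && fb == 1)) {
      hits <- rbind(hits, data.frame(chrom = mat$sites$chrom[j],
                                     pos = mat$sites$pos[j]))
    }
  }
  hits
}

## Scalar per-site Weir & Cockerham (1984) components, transcribed
## independently from the two-population special case of the estimator.
oracle_wc_site <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  n1 <- length(gA); n2 <- length(gB)
  p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  r <- 2
  nbar <- mean(c(n1, n2))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}
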