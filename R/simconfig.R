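#' Simulation configuration for the hybrid-lineage demography
#'
#' Describes a forward-time Wright-Fisher scenario: an ancestral population
#' splits into two parental species `tau_split` generations before present; a
#' hybrid lineage is founded `tau_hybrid` generations before present with a
#' proportion `phi` of its ancestry drawn from parental species A; an outgroup
#' diverges earlier, at `tau_outgroup` generations. Only standing variation is
#' simulated (biallelic SNPs segregating at the root); new mutation during the
#' simulated epoch is restricted to the optional `private_mutations` spike-in.
#'
#' Defaults mirror the crater-lake cichlid system the package was built
#' around: parental divergence ~2578 generations ago, hybrid founding ~242
#' generations ago with phi ~0.546, and effective sizes of order 10^3-10^4.
#' The `scale` argument divides all times and effective sizes by a common
#' factor, which preserves the per-branch drift (t/2Ne) while making desk-scale
#' simulation fast; it is applied once, at construction.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in base pairs.
#' @param n_loci total number of segregating sites across chromosomes.
#' @param mu mutation rate per site per generation (metadata; standing
#'   variation only is simulated).
#' @param recomb_rate crossover rate in cM per Mb (pedigree meioses).
#' @param ne_ancestral,ne_parentalA,ne_parentalB,ne_hybrid diploid effective
#'   sizes; the outgroup branch drifts with `ne_ancestral`.
#' @param tau_split generations since the parental species diverged.
#' @param tau_hybrid generations since the hybrid lineage was founded
#'   (`0 <= tau_hybrid < tau_split`; 0 is the degenerate instant-founding case).
#' @param tau_outgroup generations since the outgroup diverged; default
#'   `4 * tau_split`.
#' @param phi proportion of hybrid ancestry contributed by parental A.
#' @param migration_rate per-generation fraction of the hybrid population
#'   replaced by migrants from EACH parental species (continuous
#'   backcrossing); default 0.
#' @param sample_sizes named integer vector of diploid sample counts per
#'   group; recognised names are `parentalA`, `parentalB`, `hybrid`,
#'   `outgroup`.
#' @param pedigree_counts named integer vector of explicit pedigree
#'   individuals to generate (`F1`, `F2`, `BC1A`, `BC1B`).
#' @param private_mutations named integer vector: number of extra loci seeded
#'   as a single new copy (frequency `1/(2*Ne)`) at the founding of the named
#'   branch, then drifting; useful for private-allele testing. Default none.
#' @param ancestral_freq function(n) drawing n ancestral root frequencies;
#'   default Beta(0.8, 0.8) truncated to [0.05, 0.95] (segregating, U-shaped
#'   like a neutral site-frequency spectrum).
#' @param scale common scaling divisor applied to all `tau_*` and `ne_*`
#'   values (default 1 = no scaling).
#' @param seed RNG seed; a fixed seed makes all downstream output, including
#'   written VCF bytes, reproducible.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4,
                       chrom_length = 1e7,
                       n_loci = 5000,
                       mu = 3.5e-9,
                       recomb_rate = 1,
                       ne_ancestral = 44301,
                       ne_parentalA = 23280,
                       ne_parentalB = 17329,
                       ne_hybrid = 6369,
                       tau_split = 2578,
                       tau_hybrid = 242,
                       tau_outgroup = 4 * tau_split,
                       phi = 0.546,
                       migration_rate = 0,
                       sample_sizes = c(parentalA = 13, parentalB = 10,
                                        hybrid = 11, outgroup = 25),
                       pedigree_counts = c(F1 = 0, F2 = 0, BC1A = 0, BC1B = 0),
                       private_mutations = integer(0),
                       ancestral_freq = NULL,
                       scale = 1,
                       seed = 1L) {
  stopifnot(scale >= 1)
  force(tau_outgroup)   # default depends on tau_split; bind before rescaling
  tau_split <- max(1L, as.integer(round(tau_split / scale)))
  tau_hybrid <- as.integer(round(tau_hybrid / scale))
  tau_outgroup <- as.integer(round(tau_outgroup / scale))
  nes <- vapply(
    c(ne_ancestral, ne_parentalA, ne_parentalB, ne_hybrid),
    function(x) max(1L, as.integer(round(x / scale))), integer(1)
  )
  if (is.null(ancestral_freq)) {
    ancestral_freq <- function(n) {
      lo <- stats::pbeta(0.05, 0.8, 0.8)
      hi <- stats::pbeta(0.95, 0.8, 0.8)
      stats::qbeta(stats::runif(n, lo, hi), 0.8, 0.8)
    }
  }
  cfg <- structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.numeric(chrom_length),
    n_loci = as.integer(n_loci),
    mu = mu,
    recomb_rate = recomb_rate,
    ne_ancestral = nes[1], ne_parentalA = nes[2],
    ne_parentalB = nes[3], ne_hybrid = nes[4],
    tau_split = tau_split, tau_hybrid = tau_hybrid,
    tau_outgroup = tau_outgroup,
    phi = phi,
    migration_rate = migration_rate,
    sample_sizes = sample_sizes,
    pedigree_counts = pedigree_counts,
    private_mutations = private_mutations,
    ancestral_freq = ancestral_freq,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$phi < 0 || cfg$phi > 1) stop("phi must lie in [0, 1]")
  if (cfg$tau_hybrid < 0 || cfg$tau_hybrid >= cfg$tau_split) {
    stop("tau ordering violated: need 0 <= tau_hybrid < tau_split")
  }
  if (cfg$tau_outgroup <= cfg$tau_split) {
    stop("tau ordering violated: need tau_outgroup > tau_split")
  }
  if (cfg$migration_rate < 0 || cfg$migration_rate > 0.5) {
    stop("migration_rate must lie in [0, 0.5]")
  }
  if (cfg$n_chromosomes * cfg$chrom_length < cfg$n_loci) {
    stop("n_loci exceeds total genome length")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_loci, "loci on", x$n_chromosomes, "chromosomes\n")
  cat(sprintf("  tau_outgroup=%d  tau_split=%d  tau_hybrid=%d  phi=%.3f\n",
              x$tau_outgroup, x$tau_split, x$tau_hybrid, x$phi))
  cat(sprintf("  Ne: ancestral=%d  A=%d  B=%d  hybrid=%d\n",
              x$ne_ancestral, x$ne_parentalA, x$ne_parentalB, x$ne_hybrid))
  invisible(x)
}
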