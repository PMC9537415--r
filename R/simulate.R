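#' Population allele-frequency trajectories container
#'
#' @param freq numeric matrix, loci x populations, with columns `parentalA`,
#'   `parentalB`, `hybrid`, `outgroup`; entries in [0, 1].
#' @param sites data.frame with `chrom` and 1-based `pos`, strictly increasing
#'   within each chromosome.
#' @return An object of class `pop_frequencies`.
#' @export
pop_frequencies <- function(freq, sites) {
  freq <- as.matrix(freq)
  stopifnot(
    all(c("parentalA", "parentalB", "hybrid", "outgroup") %in% colnames(freq)),
    nrow(freq) == nrow(sites),
    all(freq >= 0 & freq <= 1)
  )
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  structure(list(freq = freq, sites = as.data.frame(sites)),
            class = "pop_frequencies")
}

#' @export
print.pop_frequencies <- function(x, ...) {
  cat("pop_frequencies:", nrow(x$freq), "loci,",
      paste(colnames(x$freq), collapse = "/"), "\n")
  invisible(x)
}

## One or more generations of Wright-Fisher binomial drift:
## p' = Binomial(2Ne, p) / 2Ne, applied independently per locus.
wf_drift <- function(p, ne, generations) {
  n2 <- 2L * as.integer(ne)
  for (g in seq_len(generations)) {
    p <- stats::rbinom(length(p), n2, p) / n2
  }
  p
}

## Draw strictly increasing site coordinates for n loci spread over the
## simulated chromosomes.
draw_sites <- function(n_loci, n_chromosomes, chrom_length) {
  chrom_of <- sort(sample.int(n_chromosomes, n_loci, replace = TRUE))
  sites <- do.call(rbind, lapply(seq_len(n_chromosomes), function(ch) {
    k <- sum(chrom_of == ch)
    if (!k) return(NULL)
    data.frame(chrom = sprintf("chr%d", ch),
               pos = sort(sample.int(chrom_length, k)))
  }))
  rownames(sites) <- NULL
  sites
}

#' Simulate terminal population allele frequencies under the hybrid demography
#'
#' Forward-time Wright-Fisher simulation of per-locus allele frequencies.
#' Ancestral frequencies are drawn at the outgroup divergence time; each
#' branch then experiences per-generation binomial drift
#' (`p' = Binomial(2Ne, p)/2Ne`). At `tau_split` the ingroup lineage splits
#' into the two parental species; at `tau_hybrid` the hybrid lineage is
#' founded with initial frequency `phi * pA + (1 - phi) * pB` and then drifts
#' with `ne_hybrid`, optionally receiving a per-generation migrant fraction
#' from each parental species. Loci fixed for the same allele in all four
#' terminal populations (globally monomorphic) are dropped and their count
#' reported; loci fixed for opposite alleles between populations are retained,
#' since they are the diagnostic fixed differences downstream stages consume.
#'
#' @param config a [sim_config()].
#' @return A `pop_frequencies` object. Attributes: `founding_freq` (hybrid
#'   frequency at founding, before any hybrid drift, for retained loci),
#'   `founding_parental` (the parental frequencies at the founding
#'   generation the mixture was formed from) and `n_dropped_fixed` (globally
#'   monomorphic loci removed).
#' @export
simulate_frequencies <- function(config) {
  validate_sim_config(config)
  cfg <- config
  runner <- function() {
    n_inj <- sum(cfg$private_mutations)
    n_tot <- cfg$n_loci + n_inj
    sites <- draw_sites(n_tot, cfg$n_chromosomes, cfg$chrom_length)

    ## Core standing-variation loci.
    p_root <- cfg$ancestral_freq(cfg$n_loci)
    p_og <- wf_drift(p_root, cfg$ne_ancestral, cfg$tau_outgroup)
    p_anc <- wf_drift(p_root, cfg$ne_ancestral,
                      cfg$tau_outgroup - cfg$tau_split)
    t_pre <- cfg$tau_split - cfg$tau_hybrid
    p_a <- wf_drift(p_anc, cfg$ne_parentalA, t_pre)
    p_b <- wf_drift(p_anc, cfg$ne_parentalB, t_pre)
    p_a0 <- p_a
    p_b0 <- p_b
    p_h0 <- cfg$phi * p_a + (1 - cfg$phi) * p_b
    p_h <- p_h0
    m <- cfg$migration_rate
    nh2 <- 2L * cfg$ne_hybrid
    na2 <- 2L * cfg$ne_parentalA
    nb2 <- 2L * cfg$ne_parentalB
    for (g in seq_len(cfg$tau_hybrid)) {
      p_mix <- if (m > 0) (1 - 2 * m) * p_h + m * p_a + m * p_b else p_h
      p_h <- stats::rbinom(length(p_mix), nh2, p_mix) / nh2
      p_a <- stats::rbinom(length(p_a), na2, p_a) / na2
      p_b <- stats::rbinom(length(p_b), nb2, p_b) / nb2
    }
    freq <- cbind(parentalA = p_a, parentalB = p_b,
                  hybrid = p_h, outgroup = p_og)
    founding <- p_h0

    ## Optional spike-in: loci arising as a single new copy at the founding
    ## of one branch, absent everywhere else.
    if (n_inj > 0) {
      inj <- matrix(0, n_inj, 4,
                    dimnames = list(NULL, colnames(freq)))
      inj_found <- numeric(n_inj)
      row <- 1L
      for (br in names(cfg$private_mutations)) {
        k <- cfg$private_mutations[[br]]
        if (!k) next
        ne <- switch(br,
                     parentalA = cfg$ne_parentalA,
                     parentalB = cfg$ne_parentalB,
                     hybrid = cfg$ne_hybrid,
                     outgroup = cfg$ne_ancestral,
                     stop("unknown branch for private_mutations: ", br))
        gens <- switch(br,
                       parentalA = , parentalB = cfg$tau_split,
                       hybrid = cfg$tau_hybrid,
                       outgroup = cfg$tau_outgroup)
        p <- wf_drift(rep(1 / (2 * ne), k), ne, gens)
        inj[row:(row + k - 1L), br] <- p
        inj_found[row:(row + k - 1L)] <- if (br == "hybrid") 1 / (2 * ne) else 0
        row <- row + k
      }
      pick <- sort(sample.int(n_tot, n_inj))
      full <- matrix(NA_real_, n_tot, 4,
                     dimnames = list(NULL, colnames(freq)))
      full[pick, ] <- inj
      full[-pick, ] <- freq
      found_full <- numeric(n_tot)
      found_full[pick] <- inj_found
      found_full[-pick] <- founding
      freq <- full
      founding <- found_full
    }

    mono <- rowSums(freq == 0) == 4L | rowSums(freq == 1) == 4L
    out <- pop_frequencies(freq[!mono, , drop = FALSE],
                           sites[!mono, , drop = FALSE])
    attr(out, "founding_freq") <- founding[!mono]
    pf <- cbind(parentalA = p_a0, parentalB = p_b0)
    if (n_inj > 0) {
      pf_full <- matrix(0, n_tot, 2, dimnames = dimnames(pf))
      pf_full[-pick, ] <- pf
      pf <- pf_full
    }
    attr(out, "founding_parental") <- pf[!mono, , drop = FALSE]
    attr(out, "n_dropped_fixed") <- sum(mono)
    out
  }
  withr::with_seed(cfg$seed, runner())
}

#' Sample a diploid population from terminal allele frequencies
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium: each individual's
#' dosage at a locus is Binomial(2, p) with the locus frequency of the chosen
#' population.
#'
#' @param freqs a `pop_frequencies` object.
#' @param group one of the populations in `freqs` (`parentalA`, `parentalB`,
#'   `hybrid`, `outgroup`).
#' @param n number of diploid individuals (> 0).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param id_prefix prefix for generated sample ids.
#' @return A `genotype_matrix` with all samples labelled `group`.
#' @export
sample_population <- function(freqs, group, n, seed = NULL, id_prefix = group) {
  stopifnot(inherits(freqs, "pop_frequencies"))
  if (!group %in% colnames(freqs$freq)) stop("unknown group: ", group)
  if (n <= 0) stop("n must be positive")
  draw <- function() {
    p <- freqs$freq[, group]
    L <- length(p)
    g <- matrix(stats::rbinom(n * L, 2L, rep(p, each = n)), nrow = n)
    genotype_matrix(
      g,
      samples = data.frame(sample_id = sprintf("%s_%02d", id_prefix, seq_len(n)),
                           group = group),
      sites = data.frame(freqs$sites, ref = "A", alt = "T")
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
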