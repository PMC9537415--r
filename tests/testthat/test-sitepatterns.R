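quartet_matrix <- function(genos) {
  # genos: list of per-group dosage vectors (one individual each), in the
  # order outgroup, p1, hyb, p2
  g <- do.call(rbind, genos)
  genotype_matrix(
    g,
    data.frame(sample_id = c("o", "x", "h", "y"),
               group = c("outgroup", "p1", "hyb", "p2")),
    data.frame(chrom = "chr1", pos = seq_len(ncol(g)) * 100L,
               ref = "A", alt = "T")
  )
}

test_that("single-site patterns land in the right accumulator", {
  # derived fixed in P1 and hybrid only -> x1; in P1 and P2 only -> x3;
  # in hybrid and P2 only -> x2
  m <- quartet_matrix(list(c(0L, 0L, 0L), c(2L, 2L, 0L),
                           c(2L, 0L, 2L), c(0L, 2L, 2L)))
  pat <- pattern_frequencies(m, "outgroup", "p1", "hyb", "p2")
  expect_equal(pat$x1, 1)
  expect_equal(pat$x3, 1)
  expect_equal(pat$x2, 1)
  expect_equal(pat$n_sites, 3L)
  # polarization flips when the outgroup major allele is alt
  m2 <- quartet_matrix(list(c(2L), c(0L), c(0L), c(2L)))
  pat2 <- pattern_frequencies(m2, "outgroup", "p1", "hyb", "p2")
  expect_equal(pat2$x1, 1)   # P1 and hybrid share the derived (ref) allele
  # ingroup-monomorphic and half-frequency-outgroup sites are skipped
  m3 <- quartet_matrix(list(c(0L, 1L), c(2L, 2L), c(2L, 2L), c(2L, 0L)))
  pat3 <- pattern_frequencies(m3, "outgroup", "p1", "hyb", "p2")
  expect_equal(pat3$n_sites, 0L)
  expect_equal(pat3$n_skipped_monomorphic, 1L)
  expect_equal(pat3$n_skipped_ambiguous, 1L)
})

test_that("gamma has closed forms for symmetric pattern excesses", {
  per_site <- data.frame(chrom = "chr1", pos = seq_len(300) * 100L,
                         x1 = rep(c(1, 0, 0), 100),
                         x2 = rep(c(0, 1, 0), 100),
                         x3 = rep(c(0, 0, 0.5), 100))
  pat <- structure(list(quartet = c(outgroup = "o", p1 = "a", hybrid = "h",
                                    p2 = "b"),
                        x1 = sum(per_site$x1), x2 = sum(per_site$x2),
                        x3 = sum(per_site$x3), per_site = per_site,
                        n_sites = nrow(per_site)),
                   class = "pattern_counts")
  res <- gamma_test(pat, n_blocks = 50)
  expect_equal(res$gamma, 0.5)
  expect_false(res$no_signal)
  expect_gt(res$z, 0)
  expect_error(gamma_test(pat, n_blocks = 1000), "informative sites")
})

test_that("relabeling the parents maps gamma to 1 - gamma and swaps x1/x2", {
  cfg <- sim_config(n_loci = 8000, n_chromosomes = 4, scale = 30, phi = 0.7,
                    seed = 41,
                    sample_sizes = c(parentalA = 8, parentalB = 8,
                                     hybrid = 8, outgroup = 8))
  dat <- simulate_dataset(cfg)
  pat <- pattern_frequencies(dat$matrix, "outgroup", "parentalA", "hybrid",
                             "parentalB")
  pat_sw <- pattern_frequencies(dat$matrix, "outgroup", "parentalB", "hybrid",
                                "parentalA")
  expect_equal(pat_sw$x1, pat$x2, tolerance = 1e-12)
  expect_equal(pat_sw$x2, pat$x1, tolerance = 1e-12)
  expect_equal(pat_sw$x3, pat$x3, tolerance = 1e-12)
  res <- gamma_test(pat); res_sw <- gamma_test(pat_sw)
  expect_equal(res_sw$gamma, 1 - res$gamma, tolerance = 1e-9)
})

test_that("a sister lineage of P1 leaves the two parental excesses balanced", {
  # phi = 1: the "hybrid" is simply a late-diverging sister of parental A,
  # so E[x2] = E[x3] (incomplete lineage sorting is symmetric)
  diffs <- vapply(1:3, function(i) {
    cfg <- sim_config(n_loci = 6000, n_chromosomes = 4, scale = 30, phi = 1,
                      ne_parentalA = 20000, ne_parentalB = 20000,
                      seed = 50 + i,
                      sample_sizes = c(parentalA = 8, parentalB = 8,
                                       hybrid = 8, outgroup = 8))
    dat <- simulate_dataset(cfg)
    pat <- pattern_frequencies(dat$matrix, "outgroup", "parentalA", "hybrid",
                               "parentalB")
    (pat$x2 - pat$x3) / pat$n_sites
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.005)
})

test_that("concordance factors are exact on a fixed two-by-two quartet", {
  g <- rbind(rep(0L, 50), rep(0L, 50), rep(2L, 50), rep(2L, 50))
  m <- genotype_matrix(
    g,
    data.frame(sample_id = c("a1", "a2", "b1", "b2"),
               group = c("sp1", "sp2", "sp3", "sp4")),
    data.frame(chrom = "chr1", pos = seq_len(50) * 10L, ref = "A", alt = "T")
  )
  cf <- snp_concordance_factors(m, c("sp1", "sp2", "sp3", "sp4"),
                                n_quartets = 10, seed = 1)
  expect_equal(unname(cf$cf), c(1, 0, 0))
  expect_equal(unname(rowSums(cf$cf_per_quartet)), rep(1, 10))
  expect_equal(cf$mean_informative_sites, 50)
})

test_that("exchangeable populations give equal concordance factors", {
  # all four populations share identical frequencies (a star phylogeny)
  L <- 4000
  p <- withr::with_seed(61, runif(L, 0.1, 0.9))
  f <- pop_frequencies(
    cbind(parentalA = p, parentalB = p, hybrid = p, outgroup = p),
    data.frame(chrom = "chr1", pos = sort(sample.int(1e7, L)))
  )
  mats <- lapply(c("parentalA", "parentalB", "hybrid", "outgroup"),
                 function(g) sample_population(f, g, 6, seed = match(g,
                   c("parentalA", "parentalB", "hybrid", "outgroup"))))
  m <- genotype_matrix(do.call(rbind, lapply(mats, `[[`, "genotypes")),
                       do.call(rbind, lapply(mats, `[[`, "samples")),
                       mats[[1]]$sites)
  cf <- snp_concordance_factors(m, c("parentalA", "parentalB", "hybrid",
                                     "outgroup"), n_quartets = 60, seed = 2)
  expect_true(all(abs(cf$cf - 1 / 3) < 0.05))
  ok <- !is.na(cf$cf_per_quartet[, 1])
  expect_equal(unname(rowSums(cf$cf_per_quartet[ok, ])), rep(1, sum(ok)))
})
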