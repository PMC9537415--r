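test_that("hybrid index has the allele-count closed form on fixed panels", {
  fx <- fixed_panel_dataset(L = 60, nA = 5, nB = 5,
                            pedigree = c(F1 = 2, F2 = 2), seed = 11)
  hi <- hybrid_index(fx$coded)
  f1 <- hi[hi$group == "F1", ]
  expect_equal(f1$h, rep(0.5, 2), tolerance = 1e-12)
  pa <- hi[hi$group == "parentalA", ]
  expect_equal(pa$h, rep(0, 5), tolerance = 1e-12)
  expect_true(all(hi$lower <= hi$h & hi$h <= hi$upper))
  # closed-form identity: h = (sum of codes) / (2 * n_loci)
  expect_equal(hi$h,
               unname(rowSums(fx$coded$codes)) / (2 * ncol(fx$coded$codes)),
               tolerance = 1e-12)
})

test_that("mean hybrid index of BC1A individuals approaches 0.25", {
  fx <- fixed_panel_dataset(L = 148, nA = 5, nB = 5,
                            pedigree = c(BC1A = 50), seed = 12)
  hi <- hybrid_index(fx$coded)
  expect_equal(mean(hi$h[hi$group == "BC1A"]), 0.25, tolerance = 0.03)
})

test_that("F1s reach the triangle apex and parentals its corners exactly", {
  fx <- fixed_panel_dataset(L = 200, nA = 8, nB = 8,
                            pedigree = c(F1 = 5), seed = 13)
  est <- estimate_SH(fx$coded)
  f1 <- est[est$group == "F1", ]
  expect_equal(f1$S, rep(0.5, 5), tolerance = 1e-4)
  expect_equal(f1$H, rep(1, 5), tolerance = 1e-4)
  par <- est[est$group %in% c("parentalA", "parentalB"), ]
  expect_equal(par$H, rep(0, 16), tolerance = 1e-4)
  expect_true(all(abs(par$S) < 1e-4 | abs(par$S - 1) < 1e-4))
  # every estimate respects the triangle constraint
  expect_true(all(est$H <= 2 * pmin(est$S, 1 - est$S) + 1e-9))
})

test_that("an F2 cohort centres on (S, H) = (0.5, 0.5)", {
  fx <- fixed_panel_dataset(L = 148, nA = 5, nB = 5,
                            pedigree = c(F2 = 50), seed = 14)
  est <- estimate_SH(fx$coded)
  f2 <- est[est$group == "F2", ]
  expect_equal(mean(f2$S), 0.5, tolerance = 0.05)
  expect_equal(mean(f2$H), 0.5, tolerance = 0.05)
})

test_that("the free maximum dominates every fixed hypothesis point", {
  fx <- fixed_panel_dataset(L = 100, nA = 5, nB = 5,
                            pedigree = c(F2 = 5, BC1A = 5), seed = 15)
  cls <- classify_individuals(fx$coded)
  expect_true(all(cls$logL >= cls$logL_class - 1e-9))
})

test_that("estimated h and S coincide on fully fixed panels", {
  fx <- fixed_panel_dataset(L = 148, nA = 5, nB = 5,
                            pedigree = c(F2 = 10, BC1A = 10, BC1B = 10),
                            seed = 16)
  hi <- hybrid_index(fx$coded)
  est <- estimate_SH(fx$coded)
  # h counts parental-B alleles, S parental-A ancestry: S = 1 - h
  expect_equal(est$S, 1 - hi$h, tolerance = 1e-4)
})

test_that("simulated generations are assigned their true classes", {
  fx <- fixed_panel_dataset(L = 148, nA = 10, nB = 10,
                            pedigree = c(F1 = 10, F2 = 10,
                                         BC1A = 10, BC1B = 10), seed = 17)
  cls <- classify_individuals(fx$coded)
  expect_identical(cls$class[cls$group == "parentalA"], rep("parentalA", 10))
  expect_identical(cls$class[cls$group == "parentalB"], rep("parentalB", 10))
  expect_identical(cls$class[cls$group == "F1"], rep("F1", 10))
  agree <- cls$class == cls$group
  expect_gte(mean(agree), 0.9)
})

test_that("later-generation hybrids fall outside all six hypothesis points", {
  # genotypes drawn at (S, H) = (0.5, 0.2): far from every fixed class
  L <- 148
  anc <- withr::with_seed(18, sample(c("AA", "AB", "BB"), L, replace = TRUE,
                                     prob = c(0.4, 0.2, 0.4)))
  codes <- ifelse(anc == "AA", 0L, ifelse(anc == "AB", 1L, 2L))
  f <- unlinked_freqs(L, 1, 0)
  m <- genotype_matrix(
    matrix(codes, nrow = 1),
    data.frame(sample_id = "hyb1", group = "hybrid"),
    data.frame(f$sites, ref = "A", alt = "T")
  )
  pan <- structure(
    data.frame(chrom = f$sites$chrom, pos = f$sites$pos,
               orientation = "alt", freqA = 1, freqB = 0),
    class = c("diagnostic_panel", "data.frame"), hi = 1, lo = 0)
  cls <- classify_individuals(recode_genotypes(m, pan))
  expect_identical(cls$class, "later_generation_hybrid")
  # the MLE recovers the realised heterozygous-ancestry fraction
  expect_equal(cls$H, mean(anc == "AB"), tolerance = 1e-3)
})

test_that("swapping the parental designation reflects S, h and BC labels", {
  fx <- fixed_panel_dataset(L = 148, nA = 8, nB = 8,
                            pedigree = c(F1 = 3, BC1A = 10, BC1B = 10),
                            seed = 19)
  pan_sw <- diagnostic_panel(fx$matrix, "parentalB", "parentalA",
                             hi = 1, lo = 0, thin_bp = 0)
  cod_sw <- recode_genotypes(fx$matrix, pan_sw)
  est <- estimate_SH(fx$coded); est_sw <- estimate_SH(cod_sw)
  expect_equal(est_sw$S, 1 - est$S, tolerance = 1e-4)
  expect_equal(est_sw$H, est$H, tolerance = 1e-4)
  hi <- hybrid_index(fx$coded); hi_sw <- hybrid_index(cod_sw)
  expect_equal(hi_sw$h, 1 - hi$h, tolerance = 1e-4)
  cls <- classify_individuals(fx$coded, estimates = est)
  cls_sw <- classify_individuals(cod_sw, estimates = est_sw)
  swap <- c(parentalA = "parentalB", parentalB = "parentalA",
            F1 = "F1", F2 = "F2", BC1A = "BC1B", BC1B = "BC1A",
            later_generation_hybrid = "later_generation_hybrid")
  expect_identical(unname(swap[cls$class]), cls_sw$class)
})

test_that("inbreeding coefficient follows the 1 - Ho/He convention", {
  # fully homozygous individual -> F = 1; all-het individual -> F < 0
  g <- rbind(rep(0L, 6), rep(2L, 6), rep(1L, 6), c(0L, 1L, 1L, 2L, 0L, 1L))
  m <- genotype_matrix(
    g,
    data.frame(sample_id = sprintf("s%d", 1:4), group = "pop"),
    data.frame(chrom = "chr1", pos = 1:6 * 100L, ref = "A", alt = "T")
  )
  fc <- inbreeding_coefficient(m)
  expect_equal(fc$F[1], 1)
  expect_equal(fc$F[2], 1)
  expect_lt(fc$F[3], 0)

  # HWE population: mean F within 3 SE of zero
  f <- unlinked_freqs(300, 1, 0, pH = 0.4)
  mh <- sample_population(f, "hybrid", 200, seed = 23)
  fh <- inbreeding_coefficient(mh)
  se <- sd(fh$F) / sqrt(nrow(fh))
  expect_lt(abs(mean(fh$F)), 3 * se)

  # zero expected heterozygosity is flagged
  mono <- genotype_matrix(
    matrix(0L, 2, 2),
    data.frame(sample_id = c("a", "b"), group = "pop"),
    data.frame(chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "T")
  )
  expect_warning(fm <- inbreeding_coefficient(mono), "zero expected")
  expect_true(all(is.na(fm$F)))
})
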