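## Per-locus genotype probabilities under the three ancestry classes.
## a, b: frequency of the parental-A allele in parental species A and B;
## codes count copies of the NON-parental-A allele.
locus_class_probs <- function(a, b) {
  qa <- 1 - a   # non-A-allele probability when the allele comes from species A
  qb <- 1 - b
  list(
    AA = cbind(`0` = (1 - qa)^2, `1` = 2 * qa * (1 - qa), `2` = qa^2),
    AB = cbind(`0` = (1 - qa) * (1 - qb),
               `1` = qa * (1 - qb) + qb * (1 - qa),
               `2` = qa * qb),
    BB = cbind(`0` = (1 - qb)^2, `1` = 2 * qb * (1 - qb), `2` = qb^2)
  )
}

## Per-locus likelihood components for one individual: L x 3 matrix of
## P(code | AA), P(code | AB), P(code | BB) over its non-missing loci.
individual_class_lik <- function(codes, panel) {
  obs <- which(!is.na(codes))
  cp <- locus_class_probs(panel$freqA[obs], panel$freqB[obs])
  g <- codes[obs] + 1L
  n <- length(obs)
  cbind(
    AA = cp$AA[cbind(seq_len(n), g)],
    AB = cp$AB[cbind(seq_len(n), g)],
    BB = cp$BB[cbind(seq_len(n), g)]
  )
}

## log-likelihood of (S, H) points given the L x 3 component matrix.
## P(AA-ancestry) = S - H/2, P(AB) = H, P(BB) = 1 - S - H/2.
sh_loglik <- function(lik3, S, H) {
  w <- rbind(AA = pmax(S - H / 2, 0),
             AB = H,
             BB = pmax(1 - S - H / 2, 0))
  colSums(log(lik3 %*% w))
}

triangle_grid <- function(step) {
  g <- expand.grid(S = seq(0, 1, by = step), H = seq(0, 1, by = step))
  g[g$H <= 2 * pmin(g$S, 1 - g$S) + 1e-12, ]
}

maximize_sh <- function(lik3, coarse_step = 0.02, levels = 3) {
  g <- triangle_grid(coarse_step)
  ll <- sh_loglik(lik3, g$S, g$H)
  best <- which.max(ll)
  S <- g$S[best]; H <- g$H[best]; top <- ll[best]
  step <- coarse_step
  for (lev in seq_len(levels)) {
    fine <- step / 10
    gg <- expand.grid(S = seq(max(0, S - step), min(1, S + step), by = fine),
                      H = seq(max(0, H - step), min(1, H + step), by = fine))
    gg <- gg[gg$H <= 2 * pmin(gg$S, 1 - gg$S) + 1e-12, ]
    ll <- sh_loglik(lik3, gg$S, gg$H)
    best <- which.max(ll)
    if (ll[best] >= top) {
      S <- gg$S[best]; H <- gg$H[best]; top <- ll[best]
    }
    step <- fine
  }
  list(S = S, H = H, logL = top)
}

#' Maximum-likelihood hybrid index
#'
#' Estimates, per individual, the proportion `h` of its alleles derived from
#' parental species B by maximizing the binomial likelihood
#' `L(h) = prod_l P(code_l | q_l(h))` with
#' `q_l(h) = (1 - h)(1 - freqA_l) + h(1 - freqB_l)` the probability of the
#' non-parental-A allele. With a fully fixed panel the maximum has the closed
#' form `(sum of codes) / (2 n_loci)` and is returned exactly. A 2-log-unit
#' profile-likelihood support interval accompanies each estimate.
#'
#' @param coded a `coded_matrix` from [recode_genotypes()].
#' @return data.frame with `id`, `group`, `h`, `lower`, `upper`, `logL`,
#'   `n_loci`; individuals with no genotyped panel locus get `NA` and a
#'   warning.
#' @export
hybrid_index <- function(coded) {
  stopifnot(inherits(coded, "coded_matrix"))
  panel <- coded$panel
  fully_fixed <- all(panel$freqA == 1 & panel$freqB == 0)
  out <- lapply(seq_len(nrow(coded$codes)), function(i) {
    codes <- coded$codes[i, ]
    obs <- which(!is.na(codes))
    if (!length(obs)) {
      return(data.frame(id = coded$samples$sample_id[i],
                        group = coded$samples$group[i],
                        h = NA_real_, lower = NA_real_, upper = NA_real_,
                        logL = NA_real_, n_loci = 0L))
    }
    a <- panel$freqA[obs]; b <- panel$freqB[obs]; g <- codes[obs]
    ll <- function(h) {
      q <- pmin(pmax((1 - h) * (1 - a) + h * (1 - b), 1e-12), 1 - 1e-12)
      sum(stats::dbinom(g, 2, q, log = TRUE))
    }
    if (fully_fixed) {
      h_hat <- sum(g) / (2 * length(g))
      top <- sum(stats::dbinom(g, 2, pmin(pmax(h_hat, 1e-12), 1 - 1e-12),
                               log = TRUE))
    } else {
      opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-6)
      h_hat <- opt$maximum; top <- opt$objective
      for (edge in c(0, 1)) {           # optimize() cannot land on the bounds
        if (ll(edge) > top) { h_hat <- edge; top <- ll(edge) }
      }
    }
    drop2 <- function(h) ll(h) - (top - 2)
    lower <- if (h_hat > 0 && drop2(0) < 0) {
      stats::uniroot(drop2, c(0, h_hat), tol = 1e-6)$root
    } else 0
    upper <- if (h_hat < 1 && drop2(1) < 0) {
      stats::uniroot(drop2, c(h_hat, 1), tol = 1e-6)$root
    } else 1
    data.frame(id = coded$samples$sample_id[i],
               group = coded$samples$group[i],
               h = h_hat, lower = lower, upper = upper,
               logL = top, n_loci = length(obs))
  })
  out <- do.call(rbind, out)
  if (any(out$n_loci == 0)) {
    warning(sum(out$n_loci == 0),
            " individual(s) with no genotyped panel locus; h set to NA")
  }
  rownames(out) <- NULL
  out
}

#' Joint maximum-likelihood ancestry and interclass heterozygosity
#'
#' Estimates, per individual, the ancestry proportion `S` (genome fraction
#' from parental species A) and interclass heterozygosity `H` (fraction of
#' loci with one allele from each species) on the triangle
#' `{0 <= S <= 1, 0 <= H <= 2 min(S, 1 - S)}`. Per locus the three ancestry
#' classes have probabilities `S - H/2`, `H`, `1 - S - H/2`, and each allele
#' is drawn from the corresponding parental allele frequency; the likelihood
#' is maximized by a coarse grid (step 0.02) followed by successive local
#' grid refinement (final resolution 2e-5).
#'
#' @param coded a `coded_matrix` from [recode_genotypes()].
#' @return data.frame with `id`, `group`, `S`, `H`, `logL`, `n_loci` and
#'   `boundary` (`TRUE` when the triangle constraint is binding at the
#'   maximum).
#' @export
estimate_SH <- function(coded) {
  stopifnot(inherits(coded, "coded_matrix"))
  if (!all(c("freqA", "freqB") %in% names(coded$panel))) {
    stop("panel lacks parental allele frequencies")
  }
  out <- lapply(seq_len(nrow(coded$codes)), function(i) {
    codes <- coded$codes[i, ]
    n_obs <- sum(!is.na(codes))
    if (!n_obs) {
      return(data.frame(id = coded$samples$sample_id[i],
                        group = coded$samples$group[i],
                        S = NA_real_, H = NA_real_, logL = NA_real_,
                        n_loci = 0L, boundary = NA))
    }
    lik3 <- individual_class_lik(codes, coded$panel)
    fit <- maximize_sh(lik3)
    data.frame(id = coded$samples$sample_id[i],
               group = coded$samples$group[i],
               S = fit$S, H = fit$H, logL = fit$logL, n_loci = n_obs,
               boundary = fit$H >= 2 * min(fit$S, 1 - fit$S) - 1e-6 ||
                 fit$H <= 1e-6)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## Fixed (S, H) hypothesis points for the generation classes.
class_points <- function() {
  data.frame(
    class = c("parentalA", "parentalB", "F1", "F2", "BC1A", "BC1B"),
    S = c(1, 0, 0.5, 0.5, 0.75, 0.25),
    H = c(0, 0, 1, 0.5, 0.5, 0.5)
  )
}

#' Assign generation classes from the (S, H) likelihood
#'
#' Evaluates each individual's log-likelihood at the six fixed generation
#' hypotheses — parentalA (1,0), parentalB (0,0), F1 (0.5,1), F2 (0.5,0.5),
#' BC1A (0.75,0.5), BC1B (0.25,0.5) — and at the free maximum-likelihood
#' (S,H). The best fixed class is assigned unless the free maximum exceeds it
#' by more than `class_margin` log-units — an information-criterion penalty of
#' 2 log-units for each of the two free parameters — in which case the
#' individual is labelled `later_generation_hybrid`. Ties prefer the simpler
#' fixed hypothesis.
#'
#' @param coded a `coded_matrix`.
#' @param class_margin log-likelihood margin before the free model wins
#'   (default 4 = 2 log-units per free parameter).
#' @param estimates optional precomputed result of [estimate_SH()] for the
#'   same `coded` object.
#' @return The [estimate_SH()] data.frame with added columns `class` and
#'   `logL_class` (log-likelihood of the assigned fixed class).
#' @export
classify_individuals <- function(coded, class_margin = 4, estimates = NULL) {
  stopifnot(inherits(coded, "coded_matrix"))
  if (is.null(estimates)) estimates <- estimate_SH(coded)
  cp <- class_points()
  res <- estimates
  res$class <- NA_character_
  res$logL_class <- NA_real_
  for (i in seq_len(nrow(res))) {
    if (res$n_loci[i] == 0) next
    lik3 <- individual_class_lik(coded$codes[i, ], coded$panel)
    ll_fixed <- sh_loglik(lik3, cp$S, cp$H)
    best <- which.max(ll_fixed)
    if (res$logL[i] - ll_fixed[best] > class_margin) {
      res$class[i] <- "later_generation_hybrid"
    } else {
      res$class[i] <- cp$class[best]
    }
    res$logL_class[i] <- ll_fixed[best]
  }
  res
}

#' Per-individual inbreeding coefficient
#'
#' `F = 1 - observed heterozygosity / expected heterozygosity`, where the
#' expectation sums `2 p_l (1 - p_l)` over the individual's genotyped sites
#' with allele frequencies taken from a designated reference sample (the
#' method-of-moments convention of standard VCF tooling).
#'
#' @param x a `genotype_matrix`.
#' @param ref_group optional group label(s) whose samples define the
#'   reference allele frequencies; default all samples.
#' @return data.frame with `id`, `group`, `n_sites`, `obs_het`, `exp_het`
#'   and `F`; `F` is `NA` (with a warning) when the expected heterozygosity
#'   is zero.
#' @export
inbreeding_coefficient <- function(x, ref_group = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  rows <- if (is.null(ref_group)) seq_len(nrow(x$genotypes))
          else group_rows(x, ref_group)
  p <- site_frequencies(x, rows)
  exp_site <- 2 * p * (1 - p)
  out <- lapply(seq_len(nrow(x$genotypes)), function(i) {
    g <- x$genotypes[i, ]
    obs <- !is.na(g) & !is.na(exp_site)
    e <- sum(exp_site[obs])
    o <- sum(g[obs] == 1)
    data.frame(id = x$samples$sample_id[i], group = x$samples$group[i],
               n_sites = sum(obs), obs_het = o, exp_het = e,
               F = if (e > 0) 1 - o / e else NA_real_)
  })
  out <- do.call(rbind, out)
  if (anyNA(out$F)) {
    warning(sum(is.na(out$F)),
            " individual(s) with zero expected heterozygosity; F set to NA")
  }
  rownames(out) <- NULL
  out
}
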