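## The combined haplotype test (CHT): a per-SNP joint likelihood-ratio test
## of allele-specific read imbalance at heterozygotes (beta-binomial) and
## genotype-dependent total region read depth (negative binomial).
##
## Likelihood, with alpha + beta = 2 so that alpha/beta is the single
## effect parameter and m the genotype-neutral mean depth:
##   L(alpha, beta, m) =
##     sum_hets log BetaBin(ref_as | n_as, pi = alpha/(alpha+beta), rho)
##   + sum_all  log NB(total | mu_j, phi),
##     mu_j = size_factor_j * m * (g_ref,j * alpha + g_alt,j * beta) / 2
## The null fixes alpha = beta = 1; the LRT statistic is referred to a
## 1-df chi-square. Effect size = alpha/beta.

#' Beta-binomial log density
#'
#' Parameterised by mean probability \code{prob} and overdispersion
#' \code{rho} in [0, 1); \code{rho = 0} degenerates to the binomial.
#'
#' @param x successes. @param size trials. @param prob mean probability.
#' @param rho overdispersion. @param log return log density?
#' @return (log) density, vectorised over \code{x}/\code{size}.
#' @export
dbetabinom <- function(x, size, prob, rho, log = TRUE) {
  if (rho < 1e-8) {
    ll <- dbinom(x, size, prob, log = TRUE)
  } else {
    a <- prob * (1 - rho) / rho
    b <- (1 - prob) * (1 - rho) / rho
    ll <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  }
  if (log) ll else exp(ll)
}

#' Split a RegionCounts table into per-SNP regions with dosages attached
#'
#' @param counts long RegionCounts data.frame.
#' @param gt a \code{GenotypeTable} covering the SNPs.
#' @return named list of per-SNP data.frames with a \code{dosage} column.
#' @export
split_regions <- function(counts, gt) {
  d <- dosages(gt)
  split_idx <- split(seq_len(nrow(counts)), counts$snp_id)
  lapply(split_idx, function(ix) {
    r <- counts[ix, , drop = FALSE]
    snp <- r$snp_id[1]
    if (!snp %in% rownames(d)) stop("SNP absent from genotypes: ", snp)
    r$dosage <- d[snp, r$sample_id]
    r
  })
}

#' CHT testability filter
#'
#' A SNP region is testable when the total number of allele-specific reads
#' over all samples reaches \code{min_as_reads} (15 in the discovery
#' configuration; 10 in replication mode) and at least one sample is
#' heterozygous.
#'
#' @param region per-SNP counts data.frame with a \code{dosage} column.
#' @param min_as_reads minimum summed allele-specific reads.
#' @return logical.
#' @export
testable <- function(region, min_as_reads = 15) {
  het <- !is.na(region$dosage) & region$dosage == 1L
  sum(region$ref_as + region$alt_as) >= min_as_reads && any(het)
}

#' Learn CHT dispersion parameters across regions
#'
#' Maximum likelihood with region-level nuisance parameters profiled out:
#' the beta-binomial overdispersion \code{rho} is fit on heterozygote
#' allele-specific counts pooled across regions with a free per-region mean
#' allele fraction, and the negative-binomial dispersion \code{phi} (the NB
#' size; larger = closer to Poisson) on total counts with a free per-region
#' mean and fixed size factors. Both are then held fixed during per-SNP
#' tests.
#'
#' @param regions list of per-SNP regions (see \code{\link{split_regions}}).
#' @return list with \code{rho} and \code{phi}.
#' @export
estimate_dispersions <- function(regions) {
  as_data <- lapply(regions, function(r) {
    het <- !is.na(r$dosage) & r$dosage == 1L
    n <- r$ref_as[het] + r$alt_as[het]
    list(x = r$ref_as[het][n > 0], n = n[n > 0])
  })
  as_data <- Filter(function(d) length(d$n) > 0, as_data)
  if (!length(as_data) || all(vapply(as_data, function(d) max(d$n), 0) <= 1))
    stop("cannot estimate rho: no region has a heterozygote with >= 2 ",
         "allele-specific reads")
  ## Cox-Reid adjusted profile likelihoods: profiling the per-region
  ## nuisance (allele fraction / mean depth) out of a plain profile
  ## likelihood underestimates the dispersion at these sample sizes; the
  ## -0.5 log(information) adjustment removes that bias.
  cr_term <- function(ll, hat, h = 1e-4) {
    info <- -(ll(hat + h) - 2 * ll(hat) + ll(hat - h)) / h^2
    0.5 * log(max(info, 1e-12))
  }
  prof_bb <- function(rho) {
    sum(vapply(as_data, function(d) {
      ll <- function(p) sum(dbetabinom(d$x, d$n, p, rho))
      o <- optimize(function(p) -ll(p), c(1e-4, 1 - 1e-4), tol = 1e-5)
      -o$objective - cr_term(ll, min(max(o$minimum, 2e-4), 1 - 2e-4))
    }, numeric(1)))
  }
  rho <- optimize(function(r) -prof_bb(r), c(1e-6, 0.95), tol = 1e-4)$minimum
  tot_data <- lapply(regions, function(r) {
    keep <- !is.na(r$total_region)
    list(y = r$total_region[keep], sf = r$size_factor[keep])
  })
  prof_nb <- function(log_phi) {
    phi <- exp(log_phi)
    sum(vapply(tot_data, function(d) {
      m0 <- log(max(mean(d$y / d$sf), 0.5))
      ll <- function(lm) sum(dnbinom(d$y, size = phi, mu = d$sf * exp(lm),
                                     log = TRUE))
      o <- optimize(function(lm) -ll(lm), c(m0 - 4, m0 + 4), tol = 1e-4)
      -o$objective - cr_term(ll, o$minimum)
    }, numeric(1)))
  }
  phi <- exp(optimize(function(lp) -prof_nb(lp), c(log(0.05), log(1e6)),
                      tol = 1e-3)$minimum)
  list(rho = rho, phi = phi)
}

.cht_loglik <- function(e, log_m, region, rho, phi, het, n_as) {
  r_es <- 2^e
  alpha <- 2 * r_es / (1 + r_es)
  beta <- 2 - alpha
  ll <- 0
  if (length(n_as))
    ll <- ll + sum(dbetabinom(region$ref_as[het][n_as > 0],
                              n_as[n_as > 0], alpha / 2, rho))
  keep <- !is.na(region$dosage)
  g_alt <- region$dosage[keep]
  mu <- region$size_factor[keep] * exp(log_m) *
    ((2 - g_alt) * alpha + g_alt * beta) / 2
  ll + sum(dnbinom(region$total_region[keep], size = phi, mu = mu,
                   log = TRUE))
}

#' Fit the combined haplotype test for one SNP
#'
#' Maximises the joint beta-binomial/negative-binomial likelihood over the
#' effect parameter \eqn{\log_2(\alpha/\beta)} and the genotype-neutral
#' mean depth, with \eqn{\alpha + \beta = 2}. The null fixes
#' \eqn{\alpha = \beta = 1}. The LRT statistic is compared to a 1-df
#' chi-square. Effect size is \eqn{\hat\alpha/\hat\beta}; the effect is box
#' constrained to \code{[1/es_bound, es_bound]} and hitting the bound is
#' flagged.
#'
#' @param region per-SNP counts data.frame with \code{dosage}.
#' @param dispersions list with \code{rho}, \code{phi} from
#'   \code{\link{estimate_dispersions}}.
#' @param es_bound box bound on \eqn{\alpha/\beta} (default 64).
#' @return one-row data.frame: \code{snp_id}, \code{alpha_hat},
#'   \code{beta_hat}, \code{effect_size}, \code{log2_es}, \code{lrt_stat},
#'   \code{p_nominal}, \code{converged}, \code{at_bound}.
#' @export
fit_cht <- function(region, dispersions, es_bound = 64) {
  rho <- dispersions$rho; phi <- dispersions$phi
  het <- !is.na(region$dosage) & region$dosage == 1L
  n_as <- region$ref_as[het] + region$alt_as[het]
  emax <- log2(es_bound)
  m0 <- log(max(mean(region$total_region / region$size_factor, na.rm = TRUE),
                0.5))
  null <- optimize(function(lm) -.cht_loglik(0, lm, region, rho, phi, het,
                                             n_as),
                   c(m0 - 6, m0 + 6), tol = 1e-6)
  ll_null <- -null$objective
  e0 <- log2((sum(region$ref_as[het]) + 0.5) /
               (sum(region$alt_as[het]) + 0.5))
  e0 <- min(max(e0, -emax + 1e-3), emax - 1e-3)
  fit <- optim(c(e0, null$minimum),
               function(p) -.cht_loglik(p[1], p[2], region, rho, phi, het,
                                        n_as),
               method = "L-BFGS-B",
               lower = c(-emax, m0 - 8), upper = c(emax, m0 + 8))
  converged <- fit$convergence == 0
  if (!converged) {
    ## nested golden-section profile: slower but derivative-free and robust
    prof <- function(e) optimize(function(lm)
      -.cht_loglik(e, lm, region, rho, phi, het, n_as),
      c(m0 - 8, m0 + 8), tol = 1e-6)
    outer <- optimize(function(e) prof(e)$objective, c(-emax, emax),
                      tol = 1e-6)
    if (outer$objective <= fit$value) {
      fit$par <- c(outer$minimum, prof(outer$minimum)$minimum)
      fit$value <- outer$objective
    }
    converged <- TRUE
  }
  e_hat <- fit$par[1]
  lrt <- max(0, 2 * (-fit$value - ll_null))
  r_es <- 2^e_hat
  data.frame(snp_id = region$snp_id[1],
             alpha_hat = 2 * r_es / (1 + r_es),
             beta_hat = 2 / (1 + r_es),
             effect_size = r_es, log2_es = e_hat,
             lrt_stat = lrt,
             p_nominal = if (converged) pchisq(lrt, 1, lower.tail = FALSE)
                         else NA_real_,
             converged = converged,
             at_bound = abs(e_hat) >= emax - 1e-6,
             stringsAsFactors = FALSE)
}

#' Genome-wide CHT scan with FWER tiers
#'
#' Applies the testability filter, learns dispersions from the testable
#' regions (unless supplied), fits the CHT per SNP, Holm-adjusts the
#' nominal p-values across all tested SNPs, and assigns tiers:
#' \code{significant} at FWER <= \code{fwer_significant} (0.1),
#' \code{suggestive} at FWER <= \code{fwer_suggestive} (0.2), else
#' \code{ns}.
#'
#' @param counts RegionCounts data.frame.
#' @param gt a \code{GenotypeTable}.
#' @param min_as_reads testability threshold (15; use 10 for replication).
#' @param fwer_significant,fwer_suggestive FWER tier thresholds.
#' @param dispersions optional pre-estimated dispersions.
#' @param es_bound box bound on the effect size.
#' @return list with \code{results} (per-SNP table incl. \code{fwer_p} and
#'   \code{tier}), \code{dispersions}, and \code{n_tested}.
#' @export
cht_scan <- function(counts, gt, min_as_reads = 15, fwer_significant = 0.1,
                     fwer_suggestive = 0.2, dispersions = NULL,
                     es_bound = 64) {
  regions <- split_regions(counts, gt)
  ok <- vapply(regions, testable, logical(1), min_as_reads = min_as_reads)
  regions <- regions[ok]
  if (!length(regions)) stop("no testable regions")
  if (is.null(dispersions)) dispersions <- estimate_dispersions(regions)
  res <- do.call(rbind, lapply(regions, fit_cht, dispersions = dispersions,
                               es_bound = es_bound))
  rownames(res) <- NULL
  adj <- holm_adjust(res$p_nominal, alpha = fwer_significant)
  res$fwer_p <- adj$adjusted
  res$tier <- ifelse(is.na(res$fwer_p), "ns",
                     ifelse(res$fwer_p <= fwer_significant, "significant",
                            ifelse(res$fwer_p <= fwer_suggestive,
                                   "suggestive", "ns")))
  list(results = res, dispersions = dispersions, n_tested = nrow(res))
}

.permute_region <- function(region, perm, flip) {
  ## move each sample's (ref, alt, total) triple as a unit so totals stay
  ## exchangeable, keep the genotype labels in place, and randomise the
  ## ref/alt assignment (phase) at heterozygote labels
  r <- region
  r$ref_as <- region$ref_as[perm]
  r$alt_as <- region$alt_as[perm]
  r$total_region <- region$total_region[perm]
  do_flip <- flip & !is.na(r$dosage)
  tmp <- r$ref_as[do_flip]
  r$ref_as[do_flip] <- r$alt_as[do_flip]
  r$alt_as[do_flip] <- tmp
  ## a het label with no AS reads (triple came from a hom) contributes
  ## nothing to the beta-binomial term; a hom label that received AS reads
  ## is zeroed (total untouched) to keep the RegionCounts invariant
  hom <- !is.na(r$dosage) & r$dosage != 1L
  r$ref_as[hom] <- 0L; r$alt_as[hom] <- 0L
  r
}

#' Permutation calibration of the CHT
#'
#' Re-runs the CHT after breaking the genotype/read-count association:
#' per SNP, count rows are shuffled across samples relative to the genotype
#' labels and the reference/alternate allele assignment at heterozygotes is
#' flipped with probability 1/2 (phase randomisation). The resulting
#' permuted p-value distribution should be uniform when the test is well
#' calibrated; comparing observed versus permuted quantiles gives the
#' quantile-quantile diagnostic.
#'
#' @param counts RegionCounts data.frame.
#' @param gt a \code{GenotypeTable}.
#' @param dispersions dispersions from the observed-data scan.
#' @param n_perm permutations per SNP.
#' @param seed RNG seed.
#' @param min_as_reads testability threshold.
#' @return list with \code{observed_p}, \code{permuted_p}, and a
#'   \code{qq} data.frame of matched quantiles.
#' @export
cht_calibrate <- function(counts, gt, dispersions, n_perm = 1, seed = 1,
                          min_as_reads = 15) {
  set.seed(seed)
  regions <- split_regions(counts, gt)
  ok <- vapply(regions, testable, logical(1), min_as_reads = min_as_reads)
  regions <- regions[ok]
  observed <- vapply(regions, function(r)
    fit_cht(r, dispersions)$p_nominal, numeric(1))
  permuted <- unlist(lapply(seq_len(n_perm), function(b) {
    vapply(regions, function(r) {
      n <- nrow(r)
      pr <- .permute_region(r, sample.int(n), runif(n) < 0.5)
      if (!testable(pr, min_as_reads)) return(NA_real_)
      fit_cht(pr, dispersions)$p_nominal
    }, numeric(1))
  }))
  permuted <- permuted[!is.na(permuted)]
  probs <- seq(0.01, 0.99, by = 0.01)
  qq <- data.frame(quantile = probs,
                   observed = quantile(observed, probs, na.rm = TRUE),
                   permuted = quantile(permuted, probs, na.rm = TRUE))
  list(observed_p = observed, permuted_p = permuted, qq = qq)
}
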