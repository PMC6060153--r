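make_region <- function(ref, alt, total, dosage, sf = 1) {
  data.frame(snp_id = "snp", sample_id = paste0("s", seq_along(ref)),
             ref_as = ref, alt_as = alt, total_region = total,
             size_factor = sf, dosage = dosage, stringsAsFactors = FALSE)
}

test_that("testability filter applies the allele-specific read threshold", {
  r <- make_region(c(7, 0), c(7, 0), c(30, 30), c(1, 0))
  expect_false(testable(r, 15))   # 14 AS reads
  r <- make_region(c(8, 0), c(7, 0), c(30, 30), c(1, 0))
  expect_true(testable(r, 15))    # 15 AS reads, one het
  # plenty of AS reads but no het recorded: inconsistent input, not testable
  r <- make_region(c(50, 50), c(50, 50), c(200, 200), c(0, 2))
  expect_false(testable(r, 15))
})

test_that("fit_cht recovers the null and the binomial MLE", {
  disp <- list(rho = 1e-9, phi = 1e5)
  # balanced hets, flat totals: the null is the MLE
  r <- make_region(ref = c(10, 10, 0, 0), alt = c(10, 10, 0, 0),
                   total = c(50, 50, 50, 50), dosage = c(1, 1, 0, 2))
  fit <- fit_cht(r, disp)
  expect_lt(fit$lrt_stat, 1e-4)
  expect_equal(fit$effect_size, 1, tolerance = 1e-3)
  # one informative het (30 ref / 10 alt), all samples het so the depth
  # component carries no genotype signal: pi-hat = 0.75, ES = 3
  r <- make_region(ref = c(30, 0, 0), alt = c(10, 0, 0),
                   total = c(40, 40, 40), dosage = c(1, 1, 1))
  fit <- fit_cht(r, disp)
  expect_equal(fit$alpha_hat / fit$beta_hat, 3, tolerance = 1e-3)
  # grid-search oracle over pi for the same binomial likelihood
  pis <- seq(0.01, 0.99, by = 1e-4)
  pi_hat <- pis[which.max(dbinom(30, 40, pis, log = TRUE))]
  expect_equal(fit$alpha_hat / 2, pi_hat, tolerance = 1e-3)
})

test_that("extreme all-reference counts land at the box bound, flagged", {
  disp <- list(rho = 1e-9, phi = 1e5)
  r <- make_region(ref = c(40, 0), alt = c(0, 0), total = c(60, 60),
                   dosage = c(1, 1))
  fit <- fit_cht(r, disp)
  expect_true(fit$at_bound)
  expect_equal(fit$effect_size, 64, tolerance = 1e-6)
})

test_that("dispersion learning recovers simulated rho and phi", {
  sim <- simulate_genotypes(list(block_spec(500, type = "independent",
                                            maf = 0.4)),
                            n_samples = 25, seed = 61)
  eff <- data.frame(snp_id = sim$genotypes$variants$id, log2_effect = 0)
  # rho = 0.10 recovered within [0.07, 0.13]
  cnt <- simulate_as_counts(sim$genotypes, eff, rho = 0.10, phi = 8,
                            mean_as_depth = 30, seed = 62)
  disp <- estimate_dispersions(split_regions(cnt, sim$genotypes))
  expect_gte(disp$rho, 0.07)
  expect_lte(disp$rho, 0.13)
  expect_gt(disp$phi, 4); expect_lt(disp$phi, 16)
  # rho = 0 lands in the binomial limit
  cnt0 <- simulate_as_counts(sim$genotypes, eff[1:150, ], rho = 0, phi = 8,
                             mean_as_depth = 30, seed = 63)
  disp0 <- estimate_dispersions(split_regions(cnt0, sim$genotypes))
  expect_lt(disp0$rho, 0.02)
  # Poisson totals push phi to the large-dispersion (Poisson) boundary
  set.seed(64)
  pois_regions <- lapply(1:200, function(i)
    make_region(ref = rep(5, 25), alt = rep(5, 25),
                total = 10 + rpois(25, 190), dosage = rep(1, 25)))
  dispp <- estimate_dispersions(pois_regions)
  expect_gt(dispp$phi, 1e3)
})

test_that("LRT is invariant to sample relabelling and size-factor scale", {
  disp <- list(rho = 0.05, phi = 10)
  r <- make_region(ref = c(20, 4, 0, 0, 0), alt = c(6, 9, 0, 0, 0),
                   total = c(60, 40, 80, 30, 55), dosage = c(1, 1, 0, 2, 0))
  f1 <- fit_cht(r, disp)
  perm <- c(3, 1, 5, 2, 4)
  f2 <- fit_cht(r[perm, ], disp)
  expect_equal(f1$lrt_stat, f2$lrt_stat, tolerance = 1e-6)
  r3 <- r; r3$size_factor <- r3$size_factor * 7.3
  f3 <- fit_cht(r3, disp)
  expect_equal(f1$p_nominal, f3$p_nominal, tolerance = 1e-6)
})

test_that("power rises with effect size and allele-specific depth", {
  grid_es <- c(0, 0.5, 1); grid_depth <- c(10, 30, 90)
  sim <- simulate_genotypes(list(block_spec(1, type = "independent",
                                            maf = 0.4)),
                            n_samples = 25, seed = 71)
  disp <- list(rho = 0.05, phi = 10)
  power <- matrix(NA_real_, 3, 3)
  for (i in seq_along(grid_es)) for (j in seq_along(grid_depth)) {
    p <- vapply(1:40, function(r) {
      cnt <- simulate_as_counts(sim$genotypes,
                                data.frame(snp_id = "b1_v1",
                                           log2_effect = grid_es[i]),
                                rho = 0.05, phi = 10,
                                mean_as_depth = grid_depth[j],
                                seed = 7000 + 100 * i + 10 * j + r)
      fit_cht(split_regions(cnt, sim$genotypes)[[1]], disp)$p_nominal
    }, numeric(1))
    power[i, j] <- mean(p < 0.05)
  }
  # monotone nondecreasing in |log2 ES| (columns) and depth (rows, es > 0),
  # with slack for Monte Carlo noise at 40 replicates
  expect_true(all(diff(power[, 3]) > -0.08))
  expect_true(all(diff(power[3, ]) > -0.08))
  expect_gt(power[3, 3], 0.9)
  expect_lt(power[1, 1], 0.2)
})

test_that("scan ranks a strong signal first and tiers partition", {
  sim <- simulate_genotypes(list(block_spec(120, type = "independent",
                                            maf = 0.4)),
                            n_samples = 25, seed = 81)
  eff <- data.frame(snp_id = sim$genotypes$variants$id,
                    log2_effect = c(2.5, rep(0, 119)))
  cnt <- simulate_as_counts(sim$genotypes, eff, mean_as_depth = 50,
                            seed = 82)
  sc <- cht_scan(cnt, sim$genotypes)
  best <- sc$results$snp_id[which.min(sc$results$p_nominal)]
  expect_equal(best, "b1_v1")
  expect_true(all(sc$results$tier %in% c("significant", "suggestive", "ns")))
  expect_equal(sum(table(sc$results$tier)), nrow(sc$results))
  expect_equal(sc$results$tier[sc$results$snp_id == "b1_v1"], "significant")
})

test_that("permutation calibration is uniform under the null and seeded", {
  sim <- simulate_genotypes(list(block_spec(150, type = "independent",
                                            maf = 0.4)),
                            n_samples = 25, seed = 91)
  eff <- data.frame(snp_id = sim$genotypes$variants$id, log2_effect = 0)
  cnt <- simulate_as_counts(sim$genotypes, eff, seed = 92)
  disp <- list(rho = 0.05, phi = 10)
  cal <- cht_calibrate(cnt, sim$genotypes, disp, n_perm = 2, seed = 93)
  expect_gt(ks.test(cal$permuted_p, "punif")$p.value, 0.01)
  cal2 <- cht_calibrate(cnt, sim$genotypes, disp, n_perm = 2, seed = 93)
  expect_identical(cal$permuted_p, cal2$permuted_p)
  # with simulated effects, observed signal far exceeds permuted
  eff$log2_effect <- 1.5
  cnt_s <- simulate_as_counts(sim$genotypes, eff, mean_as_depth = 50,
                              seed = 94)
  cal_s <- cht_calibrate(cnt_s, sim$genotypes, disp, n_perm = 1, seed = 95)
  expect_lt(median(cal_s$observed_p), 0.01)
  expect_gt(median(cal_s$permuted_p), 0.05)
})
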