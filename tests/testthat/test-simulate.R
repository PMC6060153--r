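test_that("haplotype-pool blocks realise the pool's LD structure", {
  # two-haplotype pool: no recombinant exists, D' -> 1
  sim <- simulate_genotypes(list(block_spec(2, pool = c("11", "00"),
                                            freqs = c(0.5, 0.5))),
                            n_samples = 200, seed = 1)
  ld <- ld_stats("b1_v1", "b1_v2", sim$genotypes)
  expect_equal(ld$d_prime, 1)
  # equilibrium pool: closed-form r2 = 0; sampling tolerance 0.02 at n=10000
  sim <- simulate_genotypes(list(block_spec(2,
                                            pool = c("11", "10", "01", "00"),
                                            freqs = rep(0.25, 4))),
                            n_samples = 10000, seed = 2)
  expect_lt(ld_stats("b1_v1", "b1_v2", sim$genotypes)$r2, 0.02)
})

test_that("generators are deterministic given the seed", {
  spec <- list(block_spec(4, type = "independent", maf = 0.3))
  a <- simulate_genotypes(spec, n_samples = 20, seed = 7)
  b <- simulate_genotypes(spec, n_samples = 20, seed = 7)
  expect_identical(a$genotypes$hap1, b$genotypes$hap1)
  eff <- data.frame(snp_id = "b1_v1", log2_effect = 1)
  expect_identical(simulate_as_counts(a$genotypes, eff, seed = 3),
                   simulate_as_counts(b$genotypes, eff, seed = 3))
  trip <- data.frame(gene_id = "g", eqtl_id = "b1_v2", beta_e = 0.5,
                     hqtl_id = NA, beta_h = NA, gamma = NA)
  expect_identical(simulate_expression(a$genotypes, trip, seed = 4)$cpm,
                   simulate_expression(b$genotypes, trip, seed = 4)$cpm)
})

test_that("allele-specific counts carry the requested imbalance", {
  sim <- simulate_genotypes(list(block_spec(2, type = "independent",
                                            maf = 0.5)),
                            n_samples = 2000, seed = 5)
  cnt <- simulate_as_counts(sim$genotypes,
                            data.frame(snp_id = c("b1_v1", "b1_v2"),
                                       log2_effect = c(0, 1)),
                            rho = 0.02, mean_as_depth = 30, seed = 6)
  frac <- function(snp) {
    r <- cnt[cnt$snp_id == snp, ]
    het <- r$ref_as + r$alt_as > 0
    sum(r$ref_as[het]) / sum(r$ref_as[het] + r$alt_as[het])
  }
  expect_equal(frac("b1_v1"), 0.5, tolerance = 0.02)
  # log2(alpha/beta) = 1 gives pi = alpha/(alpha+beta) = 2/3
  expect_equal(frac("b1_v2"), 2 / 3, tolerance = 0.02)
  # homozygous samples carry no allele-specific reads but a positive total
  hom <- cnt$snp_id == "b1_v1" &
    dosages(sim$genotypes)["b1_v1", cnt$sample_id[cnt$snp_id == "b1_v1"]] != 1
  expect_true(all(cnt$ref_as[hom] == 0 & cnt$alt_as[hom] == 0))
  expect_true(any(cnt$total_region[hom] > 0))
})

test_that("beta-binomial and NB draws match closed-form moments", {
  set.seed(9)
  n <- 10000; size <- 40; pi <- 2 / 3; rho <- 0.1
  p <- rbeta(n, pi * (1 - rho) / rho, (1 - pi) * (1 - rho) / rho)
  x <- rbinom(n, size, p)
  m_exp <- size * pi
  v_exp <- size * pi * (1 - pi) * (1 + (size - 1) * rho)
  expect_lt(abs(mean(x) - m_exp), 3 * sqrt(v_exp / n))
  se_var <- v_exp * sqrt(2 / (n - 1)) * 2  # generous SE for the variance
  expect_lt(abs(var(x) - v_exp), 3 * se_var)
  mu <- 200; phi <- 10
  y <- rnbinom(n, size = phi, mu = mu)
  v_nb <- mu + mu^2 / phi
  expect_lt(abs(mean(y) - mu), 3 * sqrt(v_nb / n))
})

test_that("expression generator recovers the simulated eQTL slope", {
  sim <- simulate_genotypes(list(block_spec(1, type = "independent",
                                            maf = 0.5)),
                            n_samples = 2000, seed = 10)
  trip <- data.frame(gene_id = "g", eqtl_id = "b1_v1", beta_e = 0.5,
                     hqtl_id = NA, beta_h = NA, gamma = NA)
  ex <- simulate_expression(sim$genotypes, trip, seed = 11)
  fit <- fit_nb_glm(gene_counts(ex, "g"),
                    data.frame(dosage = dosages(sim$genotypes, "b1_v1")[1, ]))
  expect_equal(unname(fit$coefficients["dosage"]), 0.5, tolerance = 0.05)
  # null slopes: genotype-stratified means agree within sampling error
  trip0 <- transform(trip, beta_e = 0)
  ex0 <- simulate_expression(sim$genotypes, trip0, seed = 12)
  y0 <- gene_counts(ex0, "g")
  g <- dosages(sim$genotypes, "b1_v1")[1, ]
  m <- tapply(y0, g, mean)
  expect_lt(diff(range(m)) / mean(y0), 0.1)
})

test_that("loop and catalog generators honour their contracts", {
  lay <- data.frame(chrom = "chr1", hqtl_pos = 50000, promoter_pos = 120000)
  loops <- simulate_loops(lay, anchor_halfwidth = 2500)
  expect_equal(nrow(loops), 1)
  expect_equal(c(loops$start_a, loops$end_a), c(47500, 52500))
  expect_equal(c(loops$start_b, loops$end_b), c(117500, 122500))

  blocks <- data.frame(block_id = paste0("blk", 1:400), chrom = "chr1",
                       start = 1:400 * 1000, end = 1:400 * 1000 + 500,
                       nsnps = 1,
                       snps = I(as.list(paste0("v", 1:400))))
  hq <- paste0("v", 1:200)
  # fold = 2: hQTL blocks selected at twice the background rate
  cat2 <- simulate_risk_catalog(blocks, hq, fold = 2, background = 0.2,
                                seed = 13)
  in_h <- sum(cat2$index_snp_id %in% hq)
  in_bg <- nrow(cat2) - in_h
  expect_gt(in_h, in_bg)  # 200*0.4 = 80 expected vs 40
  expect_error(simulate_risk_catalog(blocks, hq, fold = 0.5), "fold")
})
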