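test_that("NB GLM deviance explained: bounds and degenerate designs", {
  set.seed(111)
  y <- rnbinom(30, size = 10, mu = 100)
  # single constant-ish predictor contributes nothing: d2 ~ 0
  f0 <- fit_nb_glm(y, data.frame(x = rep(c(0, 1), 15)))
  expect_gte(f0$d2, 0)
  expect_lte(f0$d2, 1)
  # grouped response exactly reproduced by its group dummies: d2 -> 1
  yg <- rep(c(20L, 400L, 2000L), each = 8)
  fg <- fit_nb_glm(yg, data.frame(g1 = rep(c(1, 0, 0), each = 8),
                                  g2 = rep(c(0, 1, 0), each = 8)))
  expect_gt(fg$d2, 0.999)
  expect_lt(fg$residual_deviance, 1e-4)
  expect_error(fit_nb_glm(y, data.frame(a = rep(1, 30))), "rank-deficient")
})

test_that("NB deviances match an independently coded IRLS oracle", {
  # 12-observation fixture
  y <- c(12L, 30L, 25L, 60L, 41L, 15L, 80L, 33L, 21L, 55L, 47L, 18L)
  X <- cbind(d = c(0, 1, 1, 2, 2, 0, 2, 1, 0, 2, 1, 0))
  fit <- fit_nb_glm(y, data.frame(d = X[, "d"]))
  want <- oracle_nb_irls(y, X, theta = fit$theta)
  expect_equal(fit$null_deviance, want$null_deviance, tolerance = 1e-6)
  expect_equal(fit$residual_deviance, want$residual_deviance,
               tolerance = 1e-6)
})

test_that("d2 is monotone under nested design expansion at fixed theta", {
  set.seed(113)
  y <- rnbinom(60, size = 5, mu = exp(4 + 0.3 * rep(0:2, 20)))
  d <- rep(0:2, 20); z <- rbinom(60, 2, 0.5)
  f1 <- fit_nb_glm(y, data.frame(d = d), theta = 5)
  f2 <- fit_nb_glm(y, data.frame(d = d, z = z), theta = 5)
  f3 <- fit_nb_glm(y, data.frame(d = d, z = z, dz = d * z), theta = 5)
  expect_lte(f1$d2, f2$d2 + 1e-10)
  expect_lte(f2$d2, f3$d2 + 1e-10)
})

test_that("loop filters apply PET and span bounds inclusively", {
  loops <- data.frame(chrom = "chr1",
                      start_a = c(0, 0, 0, 0, 0),
                      end_a = rep(1000, 5),
                      start_b = c(5000, 5000, 3700, 2000500, 2499500),
                      end_b = c(6000, 6000, 4700, 2001500, 2500500),
                      pet_count = c(4, 3, 4, 4, 4), mark = "H3K27ac")
  kept <- filter_loops(loops)
  # spans (midpoint to midpoint): 5000, 5000, 3700, 2000500, 2499500
  expect_equal(nrow(kept), 1)          # pet 3, span < 5 kb, spans > 2 Mb drop
  expect_equal(kept$start_b, 5000)
  # boundary: span exactly 5 kb and exactly 2 Mb are kept
  bnd <- data.frame(chrom = "chr1", start_a = 0, end_a = 1000,
                    start_b = c(5000, 2000000), end_b = c(6000, 2001000),
                    pet_count = 4, mark = "H3K27ac")
  expect_equal(nrow(filter_loops(bnd)), 2)
})

interaction_fixture <- function(n = 358, gamma = 0.5, seed = 121,
                                maf = c(0.4, 0.4)) {
  sim <- simulate_genotypes(list(block_spec(1, type = "independent",
                                            maf = maf[1]),
                                 block_spec(1, type = "independent",
                                            maf = maf[2])),
                            n_samples = n, seed = seed)
  trip <- data.frame(gene_id = "g1", eqtl_id = "b1_v1", beta_e = 0.5,
                     hqtl_id = "b2_v1", beta_h = 0.3, gamma = gamma)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 60000L,
                      tes = 80000L, strand = "+", stringsAsFactors = FALSE)
  ex <- simulate_expression(sim$genotypes, trip, genes = genes,
                            seed = seed + 1)
  list(sim = sim, expr = ex)
}

test_that("eligibility filters: LD, blocks, anchors, network, genotype cells", {
  fx <- interaction_fixture(n = 300, gamma = 0, seed = 123)
  gt <- fx$sim$genotypes; blocks <- fx$sim$blocks
  v <- gt$variants
  genes <- fx$expr$genes
  eq <- data.frame(snp_id = "b1_v1", gene_id = "g1")
  hq <- data.frame(snp_id = "b2_v1")
  # loop anchored on the hQTL connecting to the gene's target range
  loops <- simulate_loops(data.frame(chrom = v$chrom[2],
                                     hqtl_pos = v$pos[2],
                                     promoter_pos = genes$tss[1]),
                          anchor_halfwidth = 600)
  loops$pet_count <- 6L
  p <- eligible_pairs(eq, hq, loops, blocks, gt, genes)
  expect_true(p$eligible)
  # hQTL outside every anchor
  far <- loops; far$start_a <- far$start_a + 5e6
  far$end_a <- far$end_a + 5e6
  p2 <- eligible_pairs(eq, hq, far, blocks, gt, genes)
  expect_equal(p2$reason, "anchor")
  # same haplotype block is rejected
  blk1 <- data.frame(block_id = "b", chrom = v$chrom[1], start = 0,
                     end = 1e7, nsnps = 2,
                     snps = I(list(c("b1_v1", "b2_v1"))))
  p3 <- eligible_pairs(eq, hq, loops, blk1, gt, genes)
  expect_equal(p3$reason, "same_block")
  # an empty genotype cell is rejected: hQTL with no homozygote-alternate
  v2 <- gt$variants; v2$maf <- NULL
  set.seed(124)
  h1 <- gt$hap1; h1["b2_v1", ] <- rbinom(300, 1, 0.5)
  h2 <- gt$hap2; h2["b2_v1", ] <- 0L
  gt2 <- genotype_table(h1, h2, v2, gt$samples)
  p4 <- eligible_pairs(eq, hq, loops, blocks, gt2, genes)
  expect_equal(p4$reason, "genotype_combinations")
  # perfect proxies are LD-rejected
  gt3 <- gt
  gt3$hap1["b2_v1", ] <- gt3$hap1["b1_v1", ]
  gt3$hap2["b2_v1", ] <- gt3$hap2["b1_v1", ]
  p5 <- eligible_pairs(eq, hq, loops, blocks, gt3, genes)
  expect_equal(p5$reason, "ld")
})

test_that("interaction scan recovers gamma and dies under permutation", {
  fx <- interaction_fixture(n = 358, gamma = 0.5, seed = 131)
  gt <- fx$sim$genotypes
  pairs <- data.frame(eqtl_id = "b1_v1", hqtl_id = "b2_v1", gene_id = "g1",
                      eligible = TRUE, reason = NA_character_)
  sc <- interaction_scan(pairs, gt, fx$expr)
  expect_true(sc$records$converged)
  expect_equal(sc$records$gamma, 0.5, tolerance = 0.25)
  expect_lt(sc$records$p_interaction, 1e-4)
  # permuting the expression sample labels kills the signal
  ex2 <- fx$expr
  set.seed(132)
  perm <- sample(ncol(ex2$cpm))
  ex2$cpm <- ex2$cpm[, perm, drop = FALSE]
  ex2$lib_sizes <- ex2$lib_sizes[perm]
  sc2 <- interaction_scan(pairs, gt, ex2)
  expect_gt(sc2$records$p_interaction, 0.001)
})

test_that("quadrant classification follows the sign rule and partitions", {
  qd <- function(be, ga) classify_quadrant(
    list(coefficients = c(eqtl = be, interaction = ga)))
  expect_equal(qd(0.4, -0.2), "enhancing-opposed")
  expect_equal(qd(0.4, 0.2), "enhancing-concordant")
  expect_equal(qd(-0.4, 0.2), "repressive-opposed")
  expect_equal(qd(-0.4, -0.2), "repressive-concordant")
  expect_equal(qd(0, 0.2), "boundary")
  set.seed(141)
  rec <- data.frame(beta_eqtl = rnorm(50), gamma = rnorm(50))
  expect_equal(sum(quadrant_summary(rec)), 50)
})

test_that("topology classifier agrees with the truth-table oracle", {
  counts <- integer(0)
  for (i in 1:1000) {
    cfg <- random_topology_config(i)
    genes <- data.frame(gene_id = "g", chrom = "chr1", tss = cfg$tss,
                        tes = cfg$tss + 20000L, strand = "+",
                        stringsAsFactors = FALSE)
    v <- data.frame(id = c("hq", "eq"), chrom = "chr1",
                    pos = c(cfg$h_pos, cfg$e_pos), ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
    gt <- genotype_table(matrix(0L, 2, 2), matrix(1L, 2, 2), v,
                         c("s1", "s2"))
    blocks <- data.frame(block_id = c("bh", "be"), chrom = "chr1",
                         start = c(cfg$h_block[1], cfg$e_block[1]),
                         end = c(cfg$h_block[2] + 1, cfg$e_block[2] + 1),
                         nsnps = 1, snps = I(list("hq", "eq")))
    rec <- list(hqtl_id = "hq", eqtl_id = "eq", gene_id = "g")
    got <- classify_topology(rec, cfg$loops, genes, gt, blocks)
    want <- oracle_topology(cfg$h_pos, cfg$e_pos,
                            c(cfg$tss - 10000, cfg$tss + 20000),
                            cfg$loops,
                            c(cfg$h_block[1], cfg$h_block[2] + 1),
                            c(cfg$e_block[1], cfg$e_block[2] + 1))
    expect_equal(got, want)
    counts <- c(counts, setNames(1L, got))
  }
  # the fixture family reaches every one of the six labels
  expect_setequal(unique(names(counts)),
                  c("Anchored", "Unanchored", "Looped", "Off-target",
                    "Joint", "Disjoint"))
})

test_that("hand-built topology examples", {
  loops <- data.frame(chrom = "chr1", start_a = 1000, end_a = 2000,
                      start_b = 50000, end_b = 51000, pet_count = 5,
                      mark = "H3K27ac")
  genes <- data.frame(gene_id = "g", chrom = "chr1", tss = 50500L,
                      tes = 70000L, strand = "+", stringsAsFactors = FALSE)
  mk_gt <- function(h_pos, e_pos)
    genotype_table(matrix(0L, 2, 2), matrix(1L, 2, 2),
                   data.frame(id = c("hq", "eq"), chrom = "chr1",
                              pos = c(h_pos, e_pos), ref = "A", alt = "G",
                              stringsAsFactors = FALSE), c("s1", "s2"))
  blocks <- data.frame(block_id = c("bh", "be"), chrom = "chr1",
                       start = c(900, 49000), end = c(2100, 52000),
                       nsnps = 1, snps = I(list("hq", "eq")))
  rec <- list(hqtl_id = "hq", eqtl_id = "eq", gene_id = "g")
  # both inside the same anchor
  expect_equal(classify_topology(rec, loops, genes, mk_gt(1500, 1600),
                                 blocks), "Anchored")
  # hQTL in no anchor
  expect_equal(classify_topology(rec, loops, genes, mk_gt(95000, 1600),
                                 blocks), "Unanchored")
})

test_that("eligible_blocks honours size and the LD window", {
  # qualifying design: D' = 1, r2 = 1/6 (pool 11:0.2, 01:0.4, 00:0.4)
  mk <- function(n_var, pool, freqs, n = 200, seed = 1) {
    simulate_genotypes(list(block_spec(n_var, pool = pool, freqs = freqs)),
                       n_samples = n, seed = seed)
  }
  pool6 <- c("110000", "010011", "000110")
  sim <- mk(6, pool6, c(0.2, 0.4, 0.4), seed = 151)
  eq <- data.frame(snp_id = "b1_v2", gene_id = "g1", d2 = 0.5)
  hq <- data.frame(snp_id = "b1_v1", p_nominal = 1e-8)
  eb <- eligible_blocks(sim$blocks, eq, hq, sim$genotypes)
  expect_equal(nrow(eb), 1)
  expect_equal(eb$lead_eqtl, "b1_v2")
  expect_equal(eb$lead_hqtl, "b1_v1")
  # a 5-variant block is excluded regardless of LD
  sim5 <- mk(5, c("11000", "01001", "00011"), c(0.2, 0.4, 0.4), seed = 152)
  eq5 <- data.frame(snp_id = "b1_v2", gene_id = "g1", d2 = 0.5)
  hq5 <- data.frame(snp_id = "b1_v1", p_nominal = 1e-8)
  expect_equal(nrow(eligible_blocks(sim5$blocks, eq5, hq5,
                                    sim5$genotypes)), 0)
  # r2 = 0.64 >= 0.6 (counts 18/2/2/18) is excluded even though D' = 0.8
  haps <- cbind(haps_from_counts(18, 2, 2, 18),
                matrix(rep(c(1, 0), 20 * 4), ncol = 4))
  gt <- gt_from_haplotypes(haps)
  blocks <- data.frame(block_id = "b", chrom = "chr1", start = 0,
                       end = 10000, nsnps = 6,
                       snps = I(list(paste0("v", 1:6))))
  expect_equal(nrow(eligible_blocks(
    blocks, data.frame(snp_id = "v1", gene_id = "g", d2 = 0.1),
    data.frame(snp_id = "v2", p_nominal = 1e-7), gt)), 0)
  # D' = 0.75 < 0.8 (counts 35/5/5/35) is excluded
  haps2 <- cbind(haps_from_counts(35, 5, 5, 35),
                 matrix(rep(c(1, 0), 40 * 4), ncol = 4))
  gt2 <- gt_from_haplotypes(haps2)
  expect_equal(nrow(eligible_blocks(
    blocks, data.frame(snp_id = "v1", gene_id = "g", d2 = 0.1),
    data.frame(snp_id = "v2", p_nominal = 1e-7), gt2)), 0)
})

test_that("d2_scan: tie counting, determinism and block exhaustion", {
  sim <- simulate_genotypes(list(block_spec(8, type = "independent",
                                            maf = 0.3)),
                            n_samples = 120, seed = 161)
  gt <- sim$genotypes
  # duplicate the hQTL dosage column into a null variant: guaranteed tie
  gt$hap1["b1_v3", ] <- gt$hap1["b1_v2", ]
  gt$hap2["b1_v3", ] <- gt$hap2["b1_v2", ]
  trip <- data.frame(gene_id = "g1", eqtl_id = "b1_v1", beta_e = 0.4,
                     hqtl_id = "b1_v2", beta_h = 0.4, gamma = 0)
  ex <- simulate_expression(gt, trip, seed = 162)
  res <- d2_scan(paste0("b1_v", 1:8), gt, ex, "g1", "b1_v1", "b1_v2",
                 n_perm = 100, seed = 163)
  expect_gte(res$perm_p, 2 / 101)
  expect_true(all(res$null_d2 >= 0 & res$null_d2 <= 1, na.rm = TRUE))
  res2 <- d2_scan(paste0("b1_v", 1:8), gt, ex, "g1", "b1_v1", "b1_v2",
                  n_perm = 100, seed = 163)
  expect_identical(res$perm_p, res2$perm_p)
  expect_error(d2_scan(c("b1_v1", "b1_v2"), gt, ex, "g1", "b1_v1",
                       "b1_v2"), "non-QTL")
})
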