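## Synthetic-data generators. Each emulates one input of the pipeline with
## the statistical structure the downstream stage assumes: LD-structured
## phased haplotypes in blocks, heterozygote-only allele-specific counts
## with tunable log2 imbalance and overdispersion, NB expression with
## additive eQTL/hQTL effects plus a multiplicative interaction, loops
## whose anchors cover variants and promoters, and risk catalogs with
## controllable enrichment. All generators are deterministic given a seed.

#' Specify a haplotype block for simulation
#'
#' Within a block, each sample's two haplotypes are drawn independently
#' from a finite haplotype pool, so LD is controlled exactly by the pool
#' composition (no recombination model); variants in different blocks are
#' independent. \code{type = "independent"} is the limiting case where
#' every haplotype allele is drawn i.i.d. per variant at frequency
#' \code{maf} (zero LD in expectation).
#'
#' @param n_variants number of variants in the block.
#' @param pool haplotype pool: matrix (haplotypes x variants) of 0/1
#'   alternate-allele indicators, or character vector like
#'   \code{c("11", "00")} (required for \code{type = "pool"}).
#' @param freqs haplotype pool frequencies (sum to 1).
#' @param type \code{"pool"} or \code{"independent"}.
#' @param maf per-variant allele frequency for \code{"independent"} blocks.
#' @return a block spec list.
#' @export
block_spec <- function(n_variants, pool = NULL, freqs = NULL,
                       type = c("pool", "independent"), maf = 0.3) {
  type <- match.arg(type)
  if (type == "pool") {
    if (is.character(pool))
      pool <- do.call(rbind, lapply(strsplit(pool, ""),
                                    function(s) as.integer(s)))
    if (is.null(pool) || nrow(pool) == 0) stop("empty haplotype pool")
    if (is.null(freqs)) freqs <- rep(1 / nrow(pool), nrow(pool))
    if (abs(sum(freqs) - 1) > 1e-8)
      stop("haplotype pool frequencies must sum to 1")
    if (ncol(pool) != n_variants)
      stop("pool width disagrees with n_variants")
  }
  list(n_variants = n_variants, pool = pool, freqs = freqs, type = type,
       maf = rep_len(maf, n_variants))
}

#' Simulate phased genotypes in haplotype blocks
#'
#' @param blocks_spec list of \code{\link{block_spec}}s.
#' @param n_samples number of diploid samples (25 for the hQTL-scale
#'   design, 358 for the eQTL-scale design).
#' @param seed RNG seed.
#' @param chrom chromosome label.
#' @param spacing bp between adjacent variants; blocks are separated by
#'   \code{10 * spacing}.
#' @param start first variant position (0-based).
#' @param tss_distance_sampler function(n) drawing absolute TSS distances
#'   for variant metadata (default: exponential, mean 50 kb).
#' @return list with \code{genotypes} (a \code{GenotypeTable}) and
#'   \code{blocks} (a blocks data.frame as from \code{\link{read_blocks}}).
#' @export
simulate_genotypes <- function(blocks_spec, n_samples = 25, seed = 1,
                               chrom = "chr1", spacing = 1000, start = 10000,
                               tss_distance_sampler = function(n)
                                 round(rexp(n, 1 / 5e4))) {
  set.seed(seed)
  h1 <- list(); h2 <- list(); vrows <- list(); brows <- list()
  pos <- start
  for (bi in seq_along(blocks_spec)) {
    sp <- blocks_spec[[bi]]
    draw_hap <- function() {
      if (sp$type == "independent") {
        matrix(rbinom(n_samples * sp$n_variants, 1, rep(sp$maf,
                                                        each = n_samples)),
               nrow = sp$n_variants, byrow = TRUE)
      } else {
        idx <- sample.int(nrow(sp$pool), n_samples, replace = TRUE,
                          prob = sp$freqs)
        t(sp$pool[idx, , drop = FALSE])
      }
    }
    h1[[bi]] <- draw_hap(); h2[[bi]] <- draw_hap()
    ids <- sprintf("b%d_v%d", bi, seq_len(sp$n_variants))
    positions <- pos + (seq_len(sp$n_variants) - 1L) * spacing
    vrows[[bi]] <- data.frame(id = ids, chrom = chrom, pos = positions,
                              ref = "A", alt = "G",
                              maf = NA_real_,
                              tss_distance =
                                as.integer(tss_distance_sampler(
                                  sp$n_variants)),
                              stringsAsFactors = FALSE)
    brows[[bi]] <- data.frame(block_id = sprintf("blk%d", bi),
                              chrom = chrom, start = positions[1],
                              end = positions[sp$n_variants] + 1L,
                              nsnps = sp$n_variants, snps = I(list(ids)),
                              stringsAsFactors = FALSE)
    pos <- positions[sp$n_variants] + 10L * spacing
  }
  variants <- do.call(rbind, vrows)
  gt <- genotype_table(do.call(rbind, h1), do.call(rbind, h2), variants,
                       sprintf("s%02d", seq_len(n_samples)))
  list(genotypes = gt, blocks = do.call(rbind, brows))
}

.rztpois <- function(n, lambda) {
  qpois(runif(n, dpois(0, lambda), 1), lambda)
}

#' Simulate allele-specific region counts under the CHT generative model
#'
#' For each listed SNP: heterozygous samples draw an allele-specific depth
#' from a zero-truncated Poisson, then reference-allele reads from a
#' beta-binomial with mean \eqn{\pi = \alpha/(\alpha+\beta)} where
#' \eqn{\log_2(\alpha/\beta)} is the requested effect and
#' \eqn{\alpha + \beta = 2}; homozygous samples have zero allele-specific
#' reads. Every sample's region total is a negative-binomial draw whose
#' mean is scaled by \eqn{(g_{ref}\alpha + g_{alt}\beta)/2}, carrying the
#' depth portion of the signal; the draw is floored at the sample's
#' allele-specific read count so the RegionCounts invariant holds (with
#' the default depths the floor is essentially never active).
#'
#' @param gt a \code{GenotypeTable}.
#' @param effects data.frame with \code{snp_id} and \code{log2_effect}.
#' @param rho beta-binomial overdispersion of the allele-specific draws.
#' @param phi NB dispersion (size) of the region totals.
#' @param mean_as_depth mean allele-specific depth per heterozygote.
#' @param mean_region_depth mean of the non-allele-specific region reads.
#' @param size_factors per-sample size factors (default 1).
#' @param seed RNG seed.
#' @return a validated RegionCounts data.frame.
#' @export
simulate_as_counts <- function(gt, effects, rho = 0.05, phi = 10,
                               mean_as_depth = 30, mean_region_depth = 200,
                               size_factors = NULL, seed = 1) {
  set.seed(seed)
  if (!all(effects$snp_id %in% gt$variants$id))
    stop("effect SNP absent from genotypes")
  n <- length(gt$samples)
  if (is.null(size_factors)) size_factors <- rep(1, n)
  out <- lapply(seq_len(nrow(effects)), function(i) {
    snp <- effects$snp_id[i]
    e <- effects$log2_effect[i]
    r_es <- 2^e
    alpha <- 2 * r_es / (1 + r_es); beta <- 2 - alpha
    pi_ref <- alpha / 2
    g <- dosages(gt, snp)[1, ]
    het <- !is.na(g) & g == 1L
    ref <- alt <- integer(n)
    k <- sum(het)
    if (k) {
      n_as <- .rztpois(k, mean_as_depth)
      p <- if (rho < 1e-12) rep(pi_ref, k) else
        rbeta(k, pi_ref * (1 - rho) / rho, (1 - pi_ref) * (1 - rho) / rho)
      ref[het] <- rbinom(k, n_as, p)
      alt[het] <- n_as - ref[het]
    }
    g_alt <- ifelse(is.na(g), 1L, g)
    mu <- size_factors * mean_region_depth *
      ((2 - g_alt) * alpha + g_alt * beta) / 2
    total <- pmax(rnbinom(n, size = phi, mu = mu), ref + alt)
    data.frame(snp_id = snp, sample_id = gt$samples, ref_as = ref,
               alt_as = alt, total_region = total,
               size_factor = size_factors, stringsAsFactors = FALSE)
  })
  validate_counts(do.call(rbind, out))
}

#' Simulate NB expression with eQTL/hQTL main effects and an interaction
#'
#' Gene counts are negative binomial with
#' \eqn{\log \mu = \mu_0 + \beta_e d_e + \beta_h d_h + \gamma d_e d_h}
#' (dosages coded 0/1/2), emitted as library-size-scaled CPM with
#' log-normal library sizes around 30 million reads. Optional sample-level
#' log-normal noise emulates residual technical variation.
#'
#' @param gt a \code{GenotypeTable}.
#' @param triplets data.frame with \code{gene_id}, \code{eqtl_id},
#'   \code{beta_e}, \code{hqtl_id}, \code{beta_h}, \code{gamma}
#'   (\code{hqtl_id} may be NA for an eQTL-only gene).
#' @param mu0 baseline log mean count.
#' @param phi NB dispersion (size).
#' @param n_background number of additional effect-free genes.
#' @param sample_noise_sd sd of per-sample log-scale noise (default 0).
#' @param lib_meanlog,lib_sdlog log-normal library size parameters.
#' @param genes optional gene annotation; autogenerated near the eQTL
#'   positions when NULL.
#' @param seed RNG seed.
#' @return an expression set.
#' @export
simulate_expression <- function(gt, triplets, mu0 = log(500), phi = 20,
                                n_background = 0, sample_noise_sd = 0,
                                lib_meanlog = log(3e7), lib_sdlog = 0.1,
                                genes = NULL, seed = 1) {
  set.seed(seed)
  n <- length(gt$samples)
  lib <- rlnorm(n, lib_meanlog, lib_sdlog)
  noise <- if (sample_noise_sd > 0) rnorm(n, 0, sample_noise_sd) else
    rep(0, n)
  all_genes <- c(triplets$gene_id,
                 if (n_background > 0) sprintf("bg_gene%d",
                                               seq_len(n_background)))
  counts <- matrix(0L, nrow = length(all_genes), ncol = n,
                   dimnames = list(all_genes, gt$samples))
  for (i in seq_len(nrow(triplets))) {
    d_e <- dosages(gt, triplets$eqtl_id[i])[1, ]
    lm <- mu0 + triplets$beta_e[i] * d_e
    if (!is.na(triplets$hqtl_id[i])) {
      d_h <- dosages(gt, triplets$hqtl_id[i])[1, ]
      lm <- lm + triplets$beta_h[i] * d_h + triplets$gamma[i] * d_e * d_h
    }
    counts[triplets$gene_id[i], ] <- rnbinom(n, size = phi,
                                             mu = exp(lm + noise))
  }
  if (n_background > 0) {
    for (gid in sprintf("bg_gene%d", seq_len(n_background)))
      counts[gid, ] <- rnbinom(n, size = phi, mu = exp(mu0 + noise))
  }
  if (is.null(genes)) {
    v <- gt$variants
    anchor_pos <- c(v$pos[match(triplets$eqtl_id, v$id)],
                    if (n_background > 0)
                      max(v$pos) + 5e4 * seq_len(n_background))
    genes <- data.frame(gene_id = all_genes,
                        chrom = v$chrom[1],
                        tss = as.integer(anchor_pos + 10000),
                        tes = as.integer(anchor_pos + 30000),
                        strand = "+", stringsAsFactors = FALSE)
  }
  cpm <- sweep(counts, 2, lib / 1e6, `/`)
  expression_set(cpm, genes, lib_sizes = lib)
}

#' Simulate chromatin loops connecting hQTL anchors to gene promoters
#'
#' One loop per layout row, with anchor A centred on the hQTL position and
#' anchor B on the promoter position (half-width \code{anchor_halfwidth});
#' anchors are emitted in genomic order.
#'
#' @param layout data.frame with \code{chrom}, \code{hqtl_pos},
#'   \code{promoter_pos}, and optionally \code{pet_count} (default 6) and
#'   \code{mark} (default \code{"H3K27ac"}).
#' @param anchor_halfwidth half-width of each anchor in bp.
#' @return a loop data.frame (as \code{\link{read_loops}}).
#' @export
simulate_loops <- function(layout, anchor_halfwidth = 2500) {
  if (is.null(layout$pet_count)) layout$pet_count <- 6L
  if (is.null(layout$mark)) layout$mark <- "H3K27ac"
  w <- anchor_halfwidth
  s1 <- pmax(0, layout$hqtl_pos - w); e1 <- layout$hqtl_pos + w
  s2 <- pmax(0, layout$promoter_pos - w); e2 <- layout$promoter_pos + w
  swap <- s1 > s2
  data.frame(chrom = layout$chrom,
             start_a = ifelse(swap, s2, s1), end_a = ifelse(swap, e2, e1),
             start_b = ifelse(swap, s1, s2), end_b = ifelse(swap, e1, e2),
             pet_count = as.integer(layout$pet_count), mark = layout$mark,
             stringsAsFactors = FALSE)
}

#' Simulate a risk catalog with controllable hQTL enrichment
#'
#' Selects haplotype blocks into the catalog: a block containing a
#' designated hQTL enters with probability \code{min(1, fold *
#' background)}, any other block with probability \code{background}; the
#' first variant of each selected block becomes its index SNP. With
#' \code{fold = 1} catalog membership is independent of hQTL status.
#'
#' @param blocks blocks data.frame.
#' @param hqtl_ids designated hQTL variant ids.
#' @param fold enrichment fold (>= 1).
#' @param background baseline block selection probability.
#' @param trait trait label.
#' @param seed RNG seed.
#' @return catalog data.frame (\code{index_snp_id}, \code{trait}).
#' @export
simulate_risk_catalog <- function(blocks, hqtl_ids, fold = 1,
                                  background = 0.05, trait = "synthetic",
                                  seed = 1) {
  if (fold < 1) stop("enrichment fold must be >= 1")
  set.seed(seed)
  has_h <- vapply(blocks$snps, function(s) any(hqtl_ids %in% s), logical(1))
  p <- ifelse(has_h, pmin(1, fold * background), background)
  sel <- runif(nrow(blocks)) < p
  data.frame(index_snp_id = vapply(blocks$snps[sel], `[`, "", 1),
             trait = trait, stringsAsFactors = FALSE)
}

#' Simulate per-individual reproducible peak sets
#'
#' Each individual carries a jittered copy of each true peak, dropped
#' independently with probability \code{dropout}; used to exercise the
#' consensus-map majority rule.
#'
#' @param true_peaks data.frame (\code{chrom}, \code{start}, \code{end}).
#' @param n_individuals number of individuals.
#' @param jitter max uniform boundary jitter in bp.
#' @param dropout per-individual peak dropout probability.
#' @param seed RNG seed.
#' @return list of per-individual peak data.frames.
#' @export
simulate_peaks <- function(true_peaks, n_individuals = 25, jitter = 20,
                           dropout = 0.2, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_individuals), function(i) {
    keep <- runif(nrow(true_peaks)) >= dropout
    p <- true_peaks[keep, , drop = FALSE]
    if (!nrow(p)) return(p)
    p$start <- pmax(0, p$start + sample(-jitter:jitter, nrow(p), TRUE))
    p$end <- p$end + sample(-jitter:jitter, nrow(p), TRUE)
    p <- p[p$start < p$end, , drop = FALSE]
    p[order(p$chrom, p$start), , drop = FALSE]
  })
}

#' Emit a complete synthetic fixture directory
#'
#' Writes every input format the pipeline reads: a phased VCF, one BED file
#' of peaks per individual, allele-specific region counts, an expression
#' table with gene annotation, H3K27ac loops (BEDPE), a risk catalog, a
#' haplotype blocks table, the YAML config and a JSON manifest.
#'
#' @param dir output directory (created).
#' @param n_samples number of diploid samples.
#' @param seed RNG seed.
#' @param hqtl_log2_es log2 effect size of the designated hQTL.
#' @param beta_e,beta_h,gamma expression model coefficients.
#' @return (invisibly) a list of the generated in-memory objects and paths.
#' @export
simulate_study <- function(dir, n_samples = 25, seed = 1,
                           hqtl_log2_es = 1, beta_e = 0.5, beta_h = 0.3,
                           gamma = 0.3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ## block 1 carries the designated hQTL (v3) and eQTL (v6) in strong but
  ## incomplete LD (D' = 1, r2 ~ 0.43), the regime of the local D2 analysis
  specs <- c(
    list(block_spec(8, pool = c("10110101", "01101010", "01000001",
                                "10010000"),
                    freqs = c(0.3, 0.2, 0.25, 0.25))),
    replicate(6, block_spec(6, type = "independent", maf = 0.3),
              simplify = FALSE))
  sim <- simulate_genotypes(specs, n_samples = n_samples, seed = seed)
  gt <- sim$genotypes; blocks <- sim$blocks
  hqtl <- "b1_v3"; eqtl <- "b1_v6"
  effects <- data.frame(
    snp_id = gt$variants$id,
    log2_effect = ifelse(gt$variants$id == hqtl, hqtl_log2_es, 0))
  counts <- simulate_as_counts(gt, effects, seed = seed + 1)
  triplets <- data.frame(gene_id = "gene1", eqtl_id = eqtl, beta_e = beta_e,
                         hqtl_id = hqtl, beta_h = beta_h, gamma = gamma,
                         stringsAsFactors = FALSE)
  expr <- simulate_expression(gt, triplets, n_background = 4,
                              seed = seed + 2)
  v <- gt$variants
  loops <- simulate_loops(data.frame(
    chrom = v$chrom[v$id == hqtl], hqtl_pos = v$pos[v$id == hqtl],
    promoter_pos = expr$genes$tss[1]))
  catalog <- simulate_risk_catalog(blocks, hqtl, fold = 2,
                                   background = 0.3, seed = seed + 3)
  peaks <- simulate_peaks(data.frame(chrom = v$chrom[1],
                                     start = pmax(0, v$pos - 500),
                                     end = v$pos + 500)[c(3, 20, 30), ],
                          n_individuals = n_samples, seed = seed + 4)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    counts = file.path(dir, "as_counts.tsv"),
    expression = file.path(dir, "expression.tsv"),
    genes = file.path(dir, "genes.tsv"),
    loops = file.path(dir, "loops_h3k27ac.bedpe"),
    catalog = file.path(dir, "catalog.tsv"),
    blocks = file.path(dir, "blocks.tsv"),
    config = file.path(dir, "config.yaml"),
    manifest = file.path(dir, "manifest.json"))
  write_vcf(gt, paths$vcf)
  write_counts(counts, paths$counts)
  write_expression(expr, paths$expression)
  write.table(expr$genes, paths$genes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_loops(loops, paths$loops)
  write_catalog(catalog, paths$catalog)
  write_blocks(blocks, paths$blocks)
  peak_paths <- vapply(seq_along(peaks), function(i) {
    p <- file.path(dir, sprintf("peaks_ind%02d.bed", i))
    write_bed(peaks[[i]], p)
    p
  }, "")
  ## matching bins scaled to the fixture's pool size
  write_config(default_config(seed = seed,
                              enrich = list(n_maf_bins = 3L,
                                            n_tss_bins = 3L)),
               paths$config)
  write_manifest("simulate", list(seed = seed, n_samples = n_samples),
                 c(unlist(paths[-length(paths)]), peak_paths),
                 paths$manifest)
  invisible(list(genotypes = gt, blocks = blocks, counts = counts,
                 expression = expr, loops = loops, catalog = catalog,
                 peaks = peaks, paths = paths))
}
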