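## Matched-permutation enrichment of hQTLs on risk haplotypes. Query
## variants are binned into 10 x 10 MAF x TSS-distance decile categories;
## null variant sets matched on the category histogram are drawn from the
## consensus-peak pool; enrichment is a one-sided Fisher's exact test and a
## permutation p-value over repeated matchings.

#' Bin pool variants into MAF x TSS-distance decile categories
#'
#' Decile edges are computed on the pool's empirical minor allele frequency
#' and absolute TSS-distance distributions; assignment uses right-closed
#' intervals, so duplicate edge values collapse bins (the occupied category
#' count may fall below 100).
#'
#' @param pool data.frame of variants with \code{id}, \code{maf},
#'   \code{tss_distance}.
#' @param n_maf_bins,n_tss_bins number of quantile bins per axis (10 each).
#' @return list with \code{category} (named by variant id),
#'   \code{maf_edges}, \code{tss_edges}.
#' @export
bin_categories <- function(pool, n_maf_bins = 10, n_tss_bins = 10) {
  if (nrow(pool) < max(n_maf_bins, n_tss_bins))
    stop("variant pool smaller than the number of bins")
  maf_edges <- unique(quantile(pool$maf, probs = seq(0, 1, length.out =
                                                       n_maf_bins + 1)))
  tss_edges <- unique(quantile(abs(pool$tss_distance),
                               probs = seq(0, 1, length.out = n_tss_bins + 1)))
  cut_or_one <- function(x, edges) {
    if (length(edges) < 2) return(rep(1L, length(x)))
    cut(x, edges, include.lowest = TRUE, right = TRUE, labels = FALSE)
  }
  maf_bin <- cut_or_one(pool$maf, maf_edges)
  tss_bin <- cut_or_one(abs(pool$tss_distance), tss_edges)
  category <- paste(maf_bin, tss_bin, sep = ":")
  names(category) <- pool$id
  list(category = category, maf_edges = maf_edges, tss_edges = tss_edges,
       by_category = split(pool$id, category))
}

#' Draw one category-matched variant set
#'
#' For each occupied query category, samples without replacement exactly as
#' many non-query pool variants as the query holds in that category, so the
#' matched set reproduces the query's MAF x TSS category histogram exactly.
#'
#' @param query_ids query (e.g. hQTL) variant ids.
#' @param binning output of \code{\link{bin_categories}} on the pool.
#' @param exclude_query drop the query variants from the matchable pool?
#' @return character vector of matched variant ids.
#' @export
matched_sample <- function(query_ids, binning, exclude_query = TRUE) {
  cat_of <- binning$category
  if (!all(query_ids %in% names(cat_of)))
    stop("query variants missing from the binned pool")
  by_cat <- binning$by_category
  if (is.null(by_cat)) by_cat <- split(names(cat_of), cat_of)
  need <- table(cat_of[query_ids])
  unlist(lapply(names(need), function(cc) {
    avail <- by_cat[[cc]]
    if (exclude_query) avail <- setdiff(avail, query_ids)
    k <- need[[cc]]
    if (is.null(avail) || length(avail) < k)
      stop(sprintf(
        "category %s: %d matchable pool variants for %d query variants",
        cc, length(avail), k))
    avail[sample.int(length(avail), k)]
  }), use.names = FALSE)
}

#' Expand a risk catalog to haplotype variant sets
#'
#' Risk haplotypes are the PLINK-style LD blocks containing each catalog
#' index SNP; membership is by variant-id set. Index SNPs falling in no
#' block contribute themselves as singleton haplotypes.
#'
#' @param catalog data.frame with \code{index_snp_id} (and \code{trait}).
#' @param blocks blocks data.frame.
#' @return character vector of catalog-haplotype variant ids.
#' @export
catalog_haplotype_variants <- function(catalog, blocks) {
  if (!nrow(catalog)) stop("empty risk catalog")
  in_block <- vapply(blocks$snps, function(s)
    any(catalog$index_snp_id %in% s), logical(1))
  unique(c(unlist(blocks$snps[in_block]),
           catalog$index_snp_id))
}

#' Fold enrichment of a variant set in catalog haplotypes
#'
#' Builds the 2x2 table (in-set vs rest-of-pool by in-catalog vs not) and
#' reports the one-sided (greater) Fisher's exact p together with the fold
#' enrichment, observed over expected under independence.
#'
#' @param variant_ids the variant set.
#' @param catalog_ids catalog-haplotype variant ids
#'   (\code{\link{catalog_haplotype_variants}}).
#' @param pool_ids the full matchable pool (must contain the set).
#' @return list with \code{observed}, \code{expected}, \code{fold},
#'   \code{fisher_p}, \code{table}.
#' @export
fold_enrichment <- function(variant_ids, catalog_ids, pool_ids) {
  if (!length(catalog_ids)) stop("empty risk catalog")
  a <- sum(variant_ids %in% catalog_ids)
  b <- length(variant_ids) - a
  rest <- setdiff(pool_ids, variant_ids)
  c_ <- sum(rest %in% catalog_ids)
  d <- length(rest) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2,
                dimnames = list(c("in_catalog", "out"), c("set", "rest")))
  expected <- length(variant_ids) * (a + c_) / length(pool_ids)
  fold <- if (expected > 0) a / expected else NA_real_
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(observed = a, expected = expected, fold = fold, fisher_p = p,
       table = tab)
}

#' Matched-permutation enrichment of hQTLs on risk haplotypes
#'
#' Computes the observed catalog overlap of the query set, then a null
#' distribution of overlaps from \code{n_perm} repetitions of the matched
#' variant sampling. The permutation p-value uses the add-one estimator
#' \eqn{(1 + \#\{null \ge obs\}) / (1 + n_{perm})} and never returns 0.
#' An optional exclusion interval (e.g. the HLA region) removes variants
#' from both query and pool before binning.
#'
#' @param query_ids query (hQTL) variant ids.
#' @param catalog catalog data.frame (\code{index_snp_id}, \code{trait}).
#' @param pool data.frame of pool variants (\code{id}, \code{maf},
#'   \code{tss_distance}, and \code{chrom}, \code{pos} if exclusion used).
#' @param blocks blocks data.frame defining risk haplotypes.
#' @param n_perm number of matching repetitions (default 1000).
#' @param seed RNG seed.
#' @param exclude_query drop query variants from the matchable pool?
#' @param exclusion optional list(chrom, start, end): variants inside are
#'   dropped from query and pool before binning.
#' @param n_maf_bins,n_tss_bins quantile bins per matching axis (10 each;
#'   smaller pools need coarser bins for matching to stay feasible).
#' @return list of class \code{EnrichmentResult}: \code{observed},
#'   \code{expected} (null mean), \code{fold}, \code{fisher_p},
#'   \code{perm_p}, \code{n_perm}, \code{null_counts}, \code{binning}.
#' @export
permutation_enrichment <- function(query_ids, catalog, pool, blocks,
                                   n_perm = 1000, seed = 1,
                                   exclude_query = TRUE, exclusion = NULL,
                                   n_maf_bins = 10, n_tss_bins = 10) {
  set.seed(seed)
  if (!is.null(exclusion)) {
    drop <- pool$chrom == exclusion$chrom & pool$pos >= exclusion$start &
      pool$pos < exclusion$end
    pool <- pool[!drop, , drop = FALSE]
    query_ids <- intersect(query_ids, pool$id)
  }
  binning <- bin_categories(pool, n_maf_bins = n_maf_bins,
                            n_tss_bins = n_tss_bins)
  catalog_ids <- catalog_haplotype_variants(catalog, blocks)
  obs <- fold_enrichment(query_ids, catalog_ids, pool$id)
  null_counts <- vapply(seq_len(n_perm), function(b) {
    m <- matched_sample(query_ids, binning, exclude_query = exclude_query)
    sum(m %in% catalog_ids)
  }, numeric(1))
  perm_p <- (1 + sum(null_counts >= obs$observed)) / (1 + n_perm)
  structure(list(observed = obs$observed, expected = mean(null_counts),
                 fold = obs$fold, fisher_p = obs$fisher_p,
                 perm_p = perm_p, n_perm = n_perm,
                 null_counts = null_counts, binning = binning),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "risk-haplotype enrichment: %d observed vs %.1f expected (fold %.2f)\n",
    x$observed, x$expected, x$fold))
  cat(sprintf("  Fisher one-sided p = %.3g; permutation p = %.3g (%d reps)\n",
              x$fisher_p, x$perm_p, x$n_perm))
  invisible(x)
}
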