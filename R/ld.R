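## Linkage disequilibrium statistics and multiple-testing procedures shared
## by all pipeline stages. LD is always computed from phased haplotypes;
## unphased records are rejected rather than resolved by EM.

#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Tallies the four haplotype classes over all phased chromosomes carrying
#' both variants and returns the classical biallelic LD measures:
#' \deqn{D = p_{AB} - p_A p_B,\quad D' = |D| / D_{max},\quad
#'       r^2 = D^2 / (p_A p_a p_B p_b)}
#' where \eqn{D_{max} = \min(p_A p_b, p_a p_B)} when \eqn{D > 0} and
#' \eqn{\min(p_A p_B, p_a p_b)} otherwise. Alleles are coded by the
#' alternate-allele indicator.
#'
#' @param id_a,id_b variant ids.
#' @param gt a \code{\link{genotype_table}} with phased haplotypes.
#' @return list with \code{d}, \code{d_prime}, \code{r2}.
#' @export
ld_stats <- function(id_a, id_b, gt) {
  ia <- match(id_a, gt$variants$id); ib <- match(id_b, gt$variants$id)
  if (is.na(ia) || is.na(ib)) stop("unknown variant id")
  if (!gt$phased[ia] || !gt$phased[ib])
    stop("LD requires phased haplotypes; variant is unphased")
  a <- c(gt$hap1[ia, ], gt$hap2[ia, ])
  b <- c(gt$hap1[ib, ], gt$hap2[ib, ])
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  ld_from_haplotypes(a, b)
}

#' LD measures from two aligned haplotype vectors
#'
#' @param a,b 0/1 allele vectors, one entry per chromosome, aligned.
#' @return list with \code{d}, \code{d_prime}, \code{r2}.
#' @export
ld_from_haplotypes <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("LD undefined for a monomorphic variant")
  pAB <- mean(a == 1 & b == 1)
  d <- pAB - pA * pB
  dmax <- if (d > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (dmax == 0) 0 else abs(d) / dmax
  r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(d = d, d_prime = min(d_prime, 1), r2 = min(r2, 1))
}

#' Greedy proxy pruning by LD
#'
#' Scans results in ascending p-value order and retains a SNP only if its
#' squared correlation with every already-retained SNP stays below
#' \code{r2_max}. This is the standard lead-SNP pruning used after an
#' association scan: the most significant variant of each correlated clump
#' survives.
#'
#' @param results data.frame with \code{snp_id} and \code{p} columns.
#' @param gt a \code{GenotypeTable} covering the result SNPs.
#' @param r2_max retention threshold (retain iff \eqn{r^2 <} r2_max).
#' @return the retained subset of \code{results}, in ascending p order.
#' @export
prune_proxies <- function(results, gt, r2_max = 0.8) {
  if (!nrow(results)) return(results)
  ord <- order(results$p)
  results <- results[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(results))) {
    ok <- TRUE
    for (j in kept) {
      r2 <- ld_stats(results$snp_id[i], results$snp_id[j], gt)$r2
      if (r2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  results[kept, , drop = FALSE]
}

#' Holm step-down FWER adjustment
#'
#' Step-down procedure: order p-values ascending and reject while
#' \eqn{p_{(k)} \le \alpha / (m - k + 1)}; adjusted p-values are the running
#' maximum of \eqn{(m - k + 1) p_{(k)}}, capped at 1.
#'
#' @param pvals numeric p-values in [0, 1].
#' @param alpha FWER level for the rejection flags.
#' @return list with \code{adjusted} (same order as input) and
#'   \code{reject} logical flags.
#' @export
holm_adjust <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) return(list(adjusted = numeric(0), reject = logical(0)))
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  adj <- p.adjust(pvals, method = "holm")
  list(adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure; q-values are the running minimum from the largest
#' p-value of \eqn{m \, p_{(k)} / k}.
#'
#' @param pvals numeric p-values.
#' @param q FDR level for the rejection flags.
#' @return list with \code{qvalues} (input order) and \code{reject}.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(list(qvalues = numeric(0), reject = logical(0)))
  qv <- p.adjust(pvals, method = "BH")
  list(qvalues = qv, reject = !is.na(qv) & qv <= q)
}

#' Map variant ids to haplotype block ids
#'
#' Variants absent from every block are treated as singleton blocks of
#' their own (labelled \code{singleton:<id>}).
#'
#' @param ids variant ids.
#' @param blocks blocks data.frame from \code{\link{read_blocks}}.
#' @return character vector of block ids, parallel to \code{ids}.
#' @export
block_of <- function(ids, blocks) {
  lut <- setNames(rep(blocks$block_id, lengths(blocks$snps)),
                  unlist(blocks$snps))
  out <- lut[ids]
  miss <- is.na(out)
  out[miss] <- paste0("singleton:", ids[miss])
  unname(out)
}
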