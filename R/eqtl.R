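## Cis-eQTL mapping: rank-based inverse-normal transformed expression
## regressed on alternate-allele dosage for every SNP-gene pair within a
## 1 Mb window, with MAF and coefficient-of-variation filters, BH FDR, and
## greedy proxy pruning of the significant hits.

#' Rank-based inverse-normal transform of an expression matrix
#'
#' Per gene: ranks (ties by average rank) mapped through the Blom offset
#' \eqn{\Phi^{-1}((r - 3/8) / (n + 1/4))}, standardising each gene to an
#' approximate standard normal as assumed by the linear eQTL model.
#'
#' @param expr an expression set (\code{\link{expression_set}}) or a
#'   genes x samples matrix.
#' @return matrix of transformed values (genes x samples).
#' @export
normalize_expression <- function(expr) {
  m <- if (inherits(expr, "chromqtl_expression")) expr$cpm else expr
  if (any(apply(m, 1, function(x) length(unique(x)) == 1)))
    stop("constant gene expression row; apply the CV filter first")
  t(apply(m, 1, function(x) {
    r <- rank(x, ties.method = "average")
    qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  }))
}

.cv <- function(x) sd(x) / mean(x)

#' Cis-eQTL scan
#'
#' For each gene, tests every variant whose position lies strictly within
#' \code{window} bp of the transcript interval (TSS/TES edge, not TSS only)
#' by ordinary least squares of inverse-normal expression on dosage.
#' Exclusion filters: variant MAF < \code{maf_min} (reason \code{"maf"}),
#' gene coefficient of variation on raw CPM < \code{cv_min} (reason
#' \code{"cv"}), distance (reason \code{"window"}). BH q-values are
#' computed across all tested pairs; pairs with q <= \code{fdr} are flagged
#' significant.
#'
#' @param gt a \code{GenotypeTable}.
#' @param expr an expression set with gene annotation (chrom/tss/tes).
#' @param window maximum SNP-transcript separation in bp (1 Mb, strict).
#' @param maf_min minimum minor allele frequency (0.05).
#' @param cv_min minimum gene coefficient of variation on raw CPM (0.15).
#' @param fdr significance level on BH q-values (0.05).
#' @return list with \code{results} (tested pairs: \code{snp_id},
#'   \code{gene_id}, \code{beta}, \code{t_stat}, \code{p_nominal},
#'   \code{q_value}, \code{significant}) and \code{excluded} (pair,
#'   reason).
#' @export
cis_scan <- function(gt, expr, window = 1e6, maf_min = 0.05, cv_min = 0.15,
                     fdr = 0.05) {
  genes <- expr$genes
  v <- gt$variants
  norm <- normalize_expression(expr$cpm[apply(expr$cpm, 1, .cv) >= cv_min, ,
                                        drop = FALSE])
  dos <- dosages(gt)
  n <- ncol(dos)
  results <- list(); excluded <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    lo <- min(g$tss, g$tes); hi <- max(g$tss, g$tes)
    dist <- ifelse(v$chrom != g$chrom, Inf,
                   pmax(0, pmax(lo - v$pos, v$pos - hi)))
    gene_cv_ok <- g$gene_id %in% rownames(norm)
    for (vi in which(dist < window)) {
      reason <- NULL
      if (!gene_cv_ok) reason <- "cv"
      else if (is.na(v$maf[vi]) || v$maf[vi] < maf_min) reason <- "maf"
      if (!is.null(reason)) {
        excluded[[length(excluded) + 1]] <-
          data.frame(snp_id = v$id[vi], gene_id = g$gene_id,
                     reason = reason, stringsAsFactors = FALSE)
        next
      }
      y <- norm[g$gene_id, ]
      x <- dos[v$id[vi], ]
      keep <- !is.na(x) & !is.na(y)
      fit <- .ols_t(x[keep], y[keep])
      results[[length(results) + 1]] <-
        data.frame(snp_id = v$id[vi], gene_id = g$gene_id,
                   beta = fit$beta, t_stat = fit$t, p_nominal = fit$p,
                   stringsAsFactors = FALSE)
    }
    far <- which(is.finite(dist) & dist >= window)
    if (length(far))
      excluded[[length(excluded) + 1]] <-
        data.frame(snp_id = v$id[far], gene_id = g$gene_id,
                   reason = "window", stringsAsFactors = FALSE)
  }
  res <- if (length(results)) do.call(rbind, results) else
    data.frame(snp_id = character(0), gene_id = character(0),
               beta = numeric(0), t_stat = numeric(0),
               p_nominal = numeric(0))
  if (nrow(res)) {
    adj <- bh_fdr(res$p_nominal, q = fdr)
    res$q_value <- adj$qvalues
    res$significant <- adj$reject
  }
  list(results = res,
       excluded = if (length(excluded)) do.call(rbind, excluded) else
         data.frame(snp_id = character(0), gene_id = character(0),
                    reason = character(0)))
}

.ols_t <- function(x, y) {
  n <- length(x)
  if (n < 3 || var(x) == 0)
    return(list(beta = NA_real_, t = NA_real_, p = NA_real_))
  vx <- var(x)
  beta <- cov(x, y) / vx
  r <- cor(x, y)
  r2 <- min(r^2, 1 - 1e-15)
  t <- r * sqrt((n - 2) / (1 - r2))
  list(beta = beta, t = t, p = 2 * pt(-abs(t), df = n - 2))
}

#' Per-gene lead eQTLs after proxy pruning
#'
#' Restricts to significant results and, gene by gene, greedily prunes
#' proxies in ascending p-value order at \eqn{r^2 \ge} \code{r2_max}
#' (delegating to \code{\link{prune_proxies}}), retaining the lead SNP of
#' each independent signal.
#'
#' @param results significant eQTL results (\code{snp_id}, \code{gene_id},
#'   \code{p_nominal}).
#' @param gt a \code{GenotypeTable}.
#' @param r2_max pruning threshold (0.8).
#' @return pruned results data.frame.
#' @export
lead_and_prune <- function(results, gt, r2_max = 0.8) {
  if (!nrow(results)) return(results)
  out <- lapply(split(results, results$gene_id), function(rr) {
    rr$p <- rr$p_nominal
    pruned <- prune_proxies(rr, gt, r2_max = r2_max)
    pruned$p <- NULL
    pruned
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
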