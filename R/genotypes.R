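#' Construct a GenotypeTable
#'
#' Container for phased diploid genotypes: two haplotype matrices
#' (variants x samples, alternate-allele indicators) plus per-variant
#' metadata. Internal coordinates are 0-based half-open; VCF positions are
#' converted on ingest.
#'
#' @param hap1,hap2 integer matrices (variants x samples) of 0/1 alternate
#'   allele indicators; \code{NA} marks missing genotypes.
#' @param variants data.frame with columns \code{id}, \code{chrom},
#'   \code{pos} (0-based bp), \code{ref}, \code{alt} and optionally
#'   \code{maf}, \code{tss_distance}. \code{maf} is recomputed from the
#'   haplotypes when absent.
#' @param samples character vector of sample identifiers.
#' @param phased logical vector per variant; FALSE flags records whose GT
#'   was not pipe-separated in the source VCF.
#' @return an object of class \code{GenotypeTable}.
#' @export
genotype_table <- function(hap1, hap2, variants, samples,
                           phased = rep(TRUE, nrow(variants))) {
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  stopifnot(identical(dim(hap1), dim(hap2)),
            nrow(hap1) == nrow(variants),
            ncol(hap1) == length(samples))
  if (anyDuplicated(variants$id))
    stop("variant ids must be unique within a GenotypeTable")
  if (any(variants$pos < 0)) stop("variant positions must be >= 0")
  rownames(hap1) <- rownames(hap2) <- variants$id
  colnames(hap1) <- colnames(hap2) <- samples
  if (is.null(variants$maf) || all(is.na(variants$maf))) {
    variants$maf <- .maf_from_haps(hap1, hap2)
  }
  if (any(variants$maf > 0.5 + 1e-9, na.rm = TRUE))
    stop("maf must lie in [0, 0.5]")
  if (is.null(variants$tss_distance)) variants$tss_distance <- NA_integer_
  structure(list(hap1 = hap1, hap2 = hap2, variants = variants,
                 samples = samples, phased = phased),
            class = "GenotypeTable")
}

.maf_from_haps <- function(hap1, hap2) {
  alt <- rowSums(hap1, na.rm = TRUE) + rowSums(hap2, na.rm = TRUE)
  n <- rowSums(!is.na(hap1)) + rowSums(!is.na(hap2))
  f <- ifelse(n > 0, alt / n, NA_real_)
  pmin(f, 1 - f)
}

#' @export
print.GenotypeTable <- function(x, ...) {
  cat(sprintf("GenotypeTable: %d variants x %d samples (%d unphased)\n",
              nrow(x$variants), length(x$samples), sum(!x$phased)))
  invisible(x)
}

#' Alternate-allele dosages
#'
#' @param gt a \code{GenotypeTable}.
#' @param ids optional variant ids to extract (rows).
#' @return integer matrix of 0/1/2 dosages, variants x samples.
#' @export
dosages <- function(gt, ids = NULL) {
  d <- gt$hap1 + gt$hap2
  if (!is.null(ids)) {
    miss <- setdiff(ids, rownames(d))
    if (length(miss)) stop("unknown variant id(s): ",
                           paste(miss, collapse = ", "))
    d <- d[ids, , drop = FALSE]
  }
  d
}

#' Heterozygosity indicator for one variant
#' @param gt a \code{GenotypeTable}.
#' @param id variant id.
#' @return logical vector over samples (NA where genotype missing).
#' @export
is_het <- function(gt, id) {
  d <- dosages(gt, id)[1, ]
  d == 1L
}

#' Phased haplotype pair for one variant
#' @param gt a \code{GenotypeTable}.
#' @param id variant id.
#' @return 2 x n_samples matrix of alternate-allele indicators.
#' @export
haplotypes_at <- function(gt, id) {
  if (!id %in% rownames(gt$hap1)) stop("unknown variant id: ", id)
  rbind(h1 = gt$hap1[id, ], h2 = gt$hap2[id, ])
}

#' Subset a GenotypeTable by variant ids
#' @param gt a \code{GenotypeTable}.
#' @param ids variant ids to keep.
#' @return a \code{GenotypeTable}.
#' @export
subset_variants <- function(gt, ids) {
  keep <- match(ids, gt$variants$id)
  if (anyNA(keep)) stop("unknown variant id(s)")
  genotype_table(gt$hap1[keep, , drop = FALSE], gt$hap2[keep, , drop = FALSE],
                 gt$variants[keep, , drop = FALSE], gt$samples,
                 gt$phased[keep])
}

#' Annotate variants with distance to the nearest 5' TSS
#'
#' Fills the \code{tss_distance} column of the variant table with the
#' absolute distance (bp) from each variant to the nearest transcription
#' start site in a gene annotation.
#'
#' @param gt a \code{GenotypeTable}.
#' @param genes data.frame with \code{gene_id}, \code{chrom}, \code{tss}
#'   (0-based bp), \code{tes}, \code{strand}.
#' @return the \code{GenotypeTable} with \code{tss_distance} filled.
#' @export
annotate_tss_distance <- function(gt, genes) {
  v <- gt$variants
  v$tss_distance <- vapply(seq_len(nrow(v)), function(i) {
    g <- genes[genes$chrom == v$chrom[i], , drop = FALSE]
    if (!nrow(g)) return(NA_integer_)
    as.integer(min(abs(g$tss - v$pos[i])))
  }, integer(1))
  gt$variants <- v
  gt
}

.autosome <- function(chrom) {
  core <- sub("^chr", "", chrom)
  ok <- grepl("^[0-9]+$", core)
  out <- rep(FALSE, length(chrom))
  out[ok] <- as.integer(core[ok]) >= 1 & as.integer(core[ok]) <= 22
  out
}
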