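## Readers and writers for every external format the pipeline touches.
## All intervals are stored 0-based half-open (BED native); VCF positions
## are converted on ingest (pos - 1) and egress (pos + 1).

#' Read phased genotypes from a VCF
#'
#' Parses a VCF (v4.x) with phased GT fields into a
#' \code{\link{genotype_table}}. Dosage is the count of alternate alleles;
#' the phased haplotype pair is retained per sample; MAF is computed from
#' the observed dosages. Records with any slash-separated (unphased) GT are
#' flagged via the \code{phased} field; missing GTs (\code{.}) become
#' record-level \code{NA}.
#'
#' @param vcf_path path to an uncompressed or gzipped VCF.
#' @return a \code{GenotypeTable}.
#' @export
read_genotypes <- function(vcf_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", vcf_path)
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop(sprintf("malformed VCF: non-integer POS at record %d of %s",
                 bad, vcf_path))
  }
  gt_str <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_str)) stop("VCF has no GT field: ", vcf_path)
  samples <- colnames(gt_str)
  parse_allele <- function(k) {
    a <- sub(if (k == 1) "^([^/|])[/|].*$" else "^[^/|][/|](.*)$", "\\1",
             gt_str)
    a[gt_str %in% c(".", "./.", ".|.") | is.na(gt_str)] <- NA
    suppressWarnings(matrix(as.integer(a), nrow = nrow(gt_str)))
  }
  h1 <- parse_allele(1); h2 <- parse_allele(2)
  phased <- apply(gt_str, 1, function(g) !any(grepl("/", g, fixed = TRUE)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", pos)[
    is.na(ids) | ids == "."]
  variants <- data.frame(id = ids, chrom = fix[, "CHROM"], pos = pos - 1L,
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  genotype_table(h1, h2, variants, samples, phased = phased)
}

#' Write a GenotypeTable as a phased VCF
#'
#' @param gt a \code{GenotypeTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(gt, path) {
  v <- gt$variants
  gts <- matrix(paste(gt$hap1, gt$hap2, sep = "|"),
                nrow = nrow(v))
  gts[is.na(gt$hap1) | is.na(gt$hap2)] <- ".|."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gt$samples), collapse = "\t")), con)
  body <- cbind(v$chrom, v$pos + 1L, v$id, v$ref, v$alt, ".", "PASS", ".",
                "GT", gts)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a BED3 peak file
#'
#' @param bed_path path to a BED3 file (one individual's peak set).
#' @return data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), validated sorted and disjoint per chromosome.
#' @export
read_peaks <- function(bed_path) {
  b <- read.table(bed_path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (ncol(b) < 3) stop("BED file needs >= 3 columns: ", bed_path)
  peaks <- data.frame(chrom = as.character(b[[1]]),
                      start = as.integer(b[[2]]), end = as.integer(b[[3]]),
                      stringsAsFactors = FALSE)
  if (any(peaks$start >= peaks$end))
    stop("invalid BED interval (start >= end) in ", bed_path)
  for (ch in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == ch, ]
    if (is.unsorted(p$start, strictly = FALSE))
      stop("unsorted BED intervals on ", ch, " in ", bed_path)
    if (nrow(p) > 1 && any(p$start[-1] < p$end[-nrow(p)]))
      stop("overlapping BED intervals on ", ch, " in ", bed_path)
  }
  peaks
}

#' Write intervals as BED
#'
#' @param intervals data.frame with \code{chrom}, \code{start}, \code{end}
#'   and optionally further columns (e.g. \code{support}) written as extra
#'   BED fields.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(intervals, path) {
  write.table(intervals, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read HiChIP loops from BEDPE
#'
#' Parses a 6+ column BEDPE with the PET count in the score (8th) column.
#' Anchor intervals stay 0-based half-open. Interchromosomal rows are
#' skipped with a warning; anchors are ordered so that anchor A precedes
#' anchor B.
#'
#' @param bedpe_path path to a BEDPE file.
#' @param mark loop mark label, \code{"H3K27ac"} or \code{"CTCF"}.
#' @return data.frame of loops: \code{chrom}, \code{start_a}, \code{end_a},
#'   \code{start_b}, \code{end_b}, \code{pet_count}, \code{mark}.
#' @export
read_loops <- function(bedpe_path, mark = "H3K27ac") {
  b <- read.table(bedpe_path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (ncol(b) < 6) stop("BEDPE needs >= 6 columns: ", bedpe_path)
  pet <- if (ncol(b) >= 8) b[[8]] else rep(1L, nrow(b))
  if (!is.numeric(pet) || any(pet != round(pet)))
    stop("non-integer PET count in ", bedpe_path)
  inter <- b[[1]] != b[[4]]
  if (any(inter))
    warning(sum(inter), " interchromosomal loop row(s) skipped in ",
            bedpe_path)
  b <- b[!inter, , drop = FALSE]; pet <- pet[!inter]
  swap <- b[[2]] > b[[5]]
  loops <- data.frame(chrom = b[[1]],
                      start_a = ifelse(swap, b[[5]], b[[2]]),
                      end_a = ifelse(swap, b[[6]], b[[3]]),
                      start_b = ifelse(swap, b[[2]], b[[5]]),
                      end_b = ifelse(swap, b[[3]], b[[6]]),
                      pet_count = as.integer(pet), mark = mark,
                      stringsAsFactors = FALSE)
  if (any(loops$pet_count < 0)) stop("negative PET count in ", bedpe_path)
  loops
}

#' Write loops as BEDPE
#' @param loops loop data.frame (see \code{\link{read_loops}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_loops <- function(loops, path) {
  out <- data.frame(loops$chrom, loops$start_a, loops$end_a, loops$chrom,
                    loops$start_b, loops$end_b, ".", loops$pet_count)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read per-SNP allele-specific region counts
#'
#' @param tsv_path TSV with columns \code{snp_id}, \code{sample_id},
#'   \code{ref_as}, \code{alt_as}, \code{total_region} and optionally
#'   \code{size_factor} (defaults to 1).
#' @return validated data.frame (class \code{RegionCounts}).
#' @export
read_counts <- function(tsv_path) {
  x <- read.table(tsv_path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("snp_id", "sample_id", "ref_as", "alt_as", "total_region")
  if (!all(need %in% names(x)))
    stop("counts TSV missing column(s): ",
         paste(setdiff(need, names(x)), collapse = ", "))
  if (is.null(x$size_factor)) x$size_factor <- 1
  validate_counts(x)
}

#' Validate a RegionCounts table
#' @param x counts data.frame.
#' @return \code{x} with class \code{RegionCounts} prepended.
#' @export
validate_counts <- function(x) {
  if (any(x$ref_as < 0 | x$alt_as < 0 | x$total_region < 0))
    stop("negative read counts in RegionCounts")
  if (any(x$size_factor <= 0)) stop("size factors must be positive")
  if (any(x$ref_as + x$alt_as > x$total_region))
    stop("ref_as + alt_as exceeds total_region")
  if (anyDuplicated(x[c("snp_id", "sample_id")]))
    stop("duplicate (snp_id, sample_id) rows in RegionCounts")
  class(x) <- unique(c("RegionCounts", class(x)))
  x
}

#' Write a RegionCounts table
#' @param counts counts data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(counts, path) {
  write.table(as.data.frame(counts)[c("snp_id", "sample_id", "ref_as",
                                      "alt_as", "total_region",
                                      "size_factor")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a risk-catalog index SNP table
#' @param tsv_path TSV with columns \code{index_snp_id}, \code{trait}.
#' @return data.frame.
#' @export
read_catalog <- function(tsv_path) {
  x <- read.table(tsv_path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (!all(c("index_snp_id", "trait") %in% names(x)))
    stop("catalog TSV needs index_snp_id and trait columns")
  x
}

#' Write a risk catalog
#' @param catalog data.frame with \code{index_snp_id}, \code{trait}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read haplotype blocks (PLINK \code{.blocks.det} style)
#'
#' @param tsv_path TSV with columns \code{chrom}, \code{start}, \code{end},
#'   \code{nsnps}, \code{snps} (pipe-separated variant ids).
#' @return data.frame with a \code{snps} list-column and \code{block_id}.
#' @export
read_blocks <- function(tsv_path) {
  x <- read.table(tsv_path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "nsnps", "snps")
  if (!all(need %in% names(x)))
    stop("blocks TSV missing column(s): ",
         paste(setdiff(need, names(x)), collapse = ", "))
  snps <- strsplit(x$snps, "|", fixed = TRUE)
  if (any(lengths(snps) != x$nsnps))
    stop("blocks file: nsnps disagrees with the snp list")
  if (anyDuplicated(unlist(snps)))
    stop("blocks file: a variant appears in more than one block")
  data.frame(block_id = if (is.null(x$block_id))
               paste0("blk", seq_len(nrow(x))) else x$block_id,
             chrom = x$chrom, start = x$start, end = x$end,
             nsnps = x$nsnps, snps = I(snps), stringsAsFactors = FALSE)
}

#' Write haplotype blocks
#' @param blocks blocks data.frame (\code{snps} list-column).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  out <- data.frame(block_id = blocks$block_id, chrom = blocks$chrom,
                    start = blocks$start, end = blocks$end,
                    nsnps = blocks$nsnps,
                    snps = vapply(blocks$snps, paste, "", collapse = "|"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build an expression set
#'
#' @param cpm numeric matrix, genes x samples, counts-per-million scale.
#' @param genes data.frame with \code{gene_id}, \code{chrom}, \code{tss},
#'   \code{tes}, \code{strand} (0-based coordinates).
#' @param lib_sizes numeric vector of library sizes per sample (reads);
#'   used to de-normalise CPM back to expected counts for NB models.
#' @return list of class \code{ExpressionSet} (package-local).
#' @export
expression_set <- function(cpm, genes,
                           lib_sizes = rep(3e7, ncol(cpm))) {
  stopifnot(nrow(cpm) == nrow(genes), length(lib_sizes) == ncol(cpm))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  rownames(cpm) <- genes$gene_id
  structure(list(cpm = cpm, genes = genes, lib_sizes = lib_sizes),
            class = "chromqtl_expression")
}

#' @export
print.chromqtl_expression <- function(x, ...) {
  cat(sprintf("expression set: %d genes x %d samples\n",
              nrow(x$cpm), ncol(x$cpm)))
  invisible(x)
}

#' Expected counts from CPM and library sizes
#' @param expr an expression set.
#' @return integer matrix of de-normalised counts (rounded).
#' @export
expression_counts <- function(expr) {
  round(sweep(expr$cpm, 2, expr$lib_sizes / 1e6, `*`))
}

#' Read an expression table
#'
#' TSV with a \code{gene_id} column then one column per sample (CPM).
#' Library sizes are carried in a \code{#library_sizes} comment header when
#' written by \code{\link{write_expression}}; absent, they default to 30M.
#'
#' @param tsv_path expression TSV path.
#' @param genes optional gene annotation data.frame; when NULL, a stub
#'   annotation with NA coordinates is created.
#' @return an expression set.
#' @export
read_expression <- function(tsv_path, genes = NULL) {
  first <- readLines(tsv_path, n = 1)
  lib_sizes <- NULL
  if (startsWith(first, "#library_sizes")) {
    lib_sizes <- as.numeric(strsplit(first, "\t")[[1]][-1])
  }
  x <- read.table(tsv_path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  if (names(x)[1] != "gene_id") stop("expression TSV must start with gene_id")
  cpm <- as.matrix(x[, -1, drop = FALSE])
  if (any(cpm < 0)) stop("negative expression values")
  if (is.null(genes))
    genes <- data.frame(gene_id = x$gene_id, chrom = NA_character_,
                        tss = NA_integer_, tes = NA_integer_, strand = "+",
                        stringsAsFactors = FALSE)
  if (is.null(lib_sizes)) lib_sizes <- rep(3e7, ncol(cpm))
  expression_set(cpm, genes[match(x$gene_id, genes$gene_id), , drop = FALSE],
                 lib_sizes)
}

#' Write an expression table
#' @param expr an expression set.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(expr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#library_sizes", format(expr$lib_sizes,
                                              scientific = FALSE)),
                   collapse = "\t"), con)
  out <- data.frame(gene_id = rownames(expr$cpm), expr$cpm,
                    check.names = FALSE)
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a gene annotation table
#' @param tsv_path TSV with \code{gene_id}, \code{chrom}, \code{tss},
#'   \code{tes}, \code{strand}.
#' @return data.frame.
#' @export
read_gene_annotation <- function(tsv_path) {
  x <- read.table(tsv_path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "tes", "strand")
  if (!all(need %in% names(x)))
    stop("gene annotation missing column(s): ",
         paste(setdiff(need, names(x)), collapse = ", "))
  x
}

## GenomicInterval helpers (0-based half-open) -------------------------------

.as_iranges <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

.point_in <- function(pos0, start0, end0) {
  any(pos0 >= start0 & pos0 < end0)
}

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
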