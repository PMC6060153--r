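## Population consensus peak map: per-base-pair majority rule over
## per-individual reproducible peak sets, then merging of nearby regions.

#' Build a consensus peak map
#'
#' Genomic bases covered by peaks in at least \code{min_support} individuals
#' form candidate consensus regions; disjoint candidate regions separated by
#' fewer than \code{merge_gap} bp are then merged (strict inequality: a gap
#' of exactly \code{merge_gap} stays unmerged). The per-interval support is
#' the number of individuals whose peak set overlaps the final interval.
#'
#' @param peak_sets list of per-individual peak data.frames (\code{chrom},
#'   \code{start}, \code{end}, 0-based half-open, disjoint per individual).
#' @param min_support minimum number of supporting individuals (default 13,
#'   a majority of 25).
#' @param merge_gap merge regions separated by fewer than this many bp
#'   (default 147, one nucleosome footprint).
#' @param mark label for the chromatin mark.
#' @return data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{support}), sorted and disjoint, with attribute \code{mark}.
#' @export
consensus_map <- function(peak_sets, min_support = 13, merge_gap = 147,
                          mark = "H3K27ac") {
  if (min_support > length(peak_sets))
    stop("min_support (", min_support, ") exceeds the number of individuals (",
         length(peak_sets), ")")
  chroms <- sort(unique(unlist(lapply(peak_sets, function(p) p$chrom))))
  out <- lapply(chroms, function(ch) {
    per_ind <- lapply(peak_sets, function(p) {
      p <- p[p$chrom == ch, , drop = FALSE]
      IRanges::reduce(.as_iranges(p$start, p$end))
    })
    width <- max(1L, vapply(per_ind, function(r)
      if (length(r)) max(IRanges::end(r)) else 0L, numeric(1)))
    cov <- Reduce(`+`, lapply(per_ind, IRanges::coverage, width = width))
    cand <- .slice_ranges(cov, min_support)
    if (!length(cand)) return(NULL)
    merged <- IRanges::reduce(cand, min.gapwidth = merge_gap)
    support <- vapply(seq_along(merged), function(i) {
      sum(vapply(per_ind, function(r)
        any(IRanges::overlapsAny(merged[i], r)), logical(1)))
    }, numeric(1))
    data.frame(chrom = ch, start = IRanges::start(merged) - 1L,
               end = IRanges::end(merged), support = as.integer(support),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), support = integer(0))
  attr(res, "mark") <- mark
  res
}

.slice_ranges <- function(cov, min_support) {
  sl <- IRanges::slice(cov, lower = min_support, rangesOnly = TRUE)
  sl
}

#' Candidate variants inside consensus peaks
#'
#' Returns the variants lying inside any consensus interval (half-open:
#' a variant at the interval end is excluded) that are heterozygous in at
#' least one sample. Only autosomal variants are considered.
#'
#' @param gt a \code{GenotypeTable}.
#' @param map a consensus map from \code{\link{consensus_map}}, or a list
#'   of maps (a variant qualifies if inside any of them).
#' @return the subset of \code{gt$variants} that qualifies.
#' @export
variants_in_peaks <- function(gt, map) {
  maps <- if (is.data.frame(map)) list(map) else map
  v <- gt$variants
  d <- dosages(gt)
  any_het <- rowSums(d == 1L, na.rm = TRUE) > 0
  inside <- vapply(seq_len(nrow(v)), function(i) {
    any(vapply(maps, function(m) {
      mm <- m[m$chrom == v$chrom[i], , drop = FALSE]
      nrow(mm) > 0 && .point_in(v$pos[i], mm$start, mm$end)
    }, logical(1)))
  }, logical(1))
  v[inside & any_het & .autosome(v$chrom), , drop = FALSE]
}
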