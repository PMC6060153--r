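## Negative-binomial joint-effect models: D-squared (deviance explained)
## haplotype analysis with a permutation null over non-QTL variant
## positions, and the distal eQTL x hQTL interaction scan with chromatin
## loop-topology and effect-sign quadrant classification.

#' Fit a negative-binomial GLM and report deviance explained
#'
#' Log-link NB regression of counts on a design data.frame, with the
#' dispersion estimated by profile maximum likelihood (\code{MASS::glm.nb});
#' pass \code{theta} to fix the dispersion instead. Reports the null
#' (intercept-only) and residual deviance at the fitted dispersion and the
#' pseudo-R-squared
#' \deqn{D^2 = (\mathrm{null\ deviance} - \mathrm{residual\ deviance}) /
#'       \mathrm{null\ deviance}.}
#'
#' @param y non-negative integer response counts.
#' @param design data.frame of predictors (no intercept column; one is
#'   added). Must be full rank.
#' @param theta optional fixed NB dispersion (size).
#' @return list of class \code{JointModelFit}: \code{coefficients},
#'   \code{se}, \code{null_deviance}, \code{residual_deviance}, \code{d2},
#'   \code{theta}, \code{converged}, and \code{z}/\code{p_interaction} when
#'   an \code{interaction} column is present in the design.
#' @export
fit_nb_glm <- function(y, design, theta = NULL) {
  stopifnot(all(y >= 0))
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  dat <- data.frame(.y = y, design, check.names = FALSE)
  form <- stats::as.formula(paste(".y ~",
                                  paste(sprintf("`%s`", names(design)),
                                        collapse = " + ")))
  fit <- if (is.null(theta)) {
    f <- tryCatch(suppressWarnings(MASS::glm.nb(form, data = dat)),
                  error = function(e) NULL)
    if (is.null(f)) {
      ## profile dispersion diverged (residual variation at or below the
      ## Poisson limit): pin the dispersion at a large fixed value
      f <- tryCatch(suppressWarnings(
        stats::glm(form, data = dat,
                   family = MASS::negative.binomial(1e6))),
        error = function(e) NULL)
      if (!is.null(f)) f$theta <- 1e6
    }
    f
  } else {
    tryCatch(suppressWarnings(
      stats::glm(form, data = dat,
                 family = MASS::negative.binomial(theta))),
      error = function(e) NULL)
  }
  if (is.null(fit))
    return(structure(list(coefficients = NULL, se = NULL,
                          null_deviance = NA_real_,
                          residual_deviance = NA_real_, d2 = NA_real_,
                          theta = theta, converged = FALSE),
                     class = "JointModelFit"))
  sm <- summary(fit)
  co <- sm$coefficients
  d2 <- (fit$null.deviance - fit$deviance) / fit$null.deviance
  d2 <- min(max(d2, 0), 1)
  out <- list(coefficients = co[, "Estimate"], se = co[, "Std. Error"],
              null_deviance = fit$null.deviance,
              residual_deviance = fit$deviance, d2 = d2,
              theta = if (is.null(theta)) fit$theta else theta,
              converged = isTRUE(fit$converged))
  if ("interaction" %in% rownames(co)) {
    out$z <- co["interaction", "Estimate"] / co["interaction", "Std. Error"]
    out$p_interaction <- 2 * pnorm(-abs(out$z))
  }
  structure(out, class = "JointModelFit")
}

#' @export
print.JointModelFit <- function(x, ...) {
  cat("NB joint-effect model fit\n")
  if (!is.null(x$coefficients)) print(round(x$coefficients, 4))
  cat(sprintf("  D2 = %.4f (null dev %.2f, residual dev %.2f), theta %.2f\n",
              x$d2, x$null_deviance, x$residual_deviance, x$theta))
  invisible(x)
}

#' De-normalised counts for one gene
#' @param expr expression set. @param gene_id gene.
#' @return integer vector of expected counts per sample.
#' @export
gene_counts <- function(expr, gene_id) {
  if (!gene_id %in% rownames(expr$cpm)) stop("unknown gene: ", gene_id)
  as.integer(round(expr$cpm[gene_id, ] * expr$lib_sizes / 1e6))
}

#' Single-variant deviance explained
#'
#' D-squared of the NB model of a gene's counts on one variant's dosage
#' alone; used to rank eQTLs within a haplotype block.
#'
#' @param gt genotypes. @param expr expression set.
#' @param snp_id variant. @param gene_id target gene.
#' @return D-squared (scalar).
#' @export
variant_d2 <- function(gt, expr, snp_id, gene_id) {
  y <- gene_counts(expr, gene_id)
  d <- dosages(gt, snp_id)[1, ]
  fit_nb_glm(y, data.frame(dosage = d))$d2
}

#' Select haplotype blocks eligible for the local D-squared analysis
#'
#' Keeps blocks of at least \code{min_block_size} variants containing an
#' eQTL-hQTL pair in strong LD (\eqn{D' \ge} \code{dprime_min}) but not
#' highly correlated (\eqn{r^2 <} \code{r2_max}). Within each kept block
#' the lead eQTL is the one with maximum single-variant deviance explained
#' (D-squared) for its target gene and the lead hQTL the one with the most
#' significant CHT p-value.
#'
#' @param blocks blocks data.frame.
#' @param eqtls data.frame with \code{snp_id}, \code{gene_id} and
#'   \code{d2} (from \code{\link{variant_d2}}).
#' @param hqtls data.frame with \code{snp_id}, \code{p_nominal}.
#' @param gt genotypes (phased) for LD.
#' @param min_block_size minimum variants per block (6).
#' @param dprime_min,r2_max LD window for the pair (0.8 / 0.6).
#' @return data.frame of eligible blocks with lead pair and its LD.
#' @export
eligible_blocks <- function(blocks, eqtls, hqtls, gt, min_block_size = 6,
                            dprime_min = 0.8, r2_max = 0.6) {
  rows <- lapply(seq_len(nrow(blocks)), function(bi) {
    snps <- blocks$snps[[bi]]
    if (length(snps) < min_block_size) return(NULL)
    e_in <- eqtls[eqtls$snp_id %in% snps, , drop = FALSE]
    h_in <- hqtls[hqtls$snp_id %in% snps, , drop = FALSE]
    if (!nrow(e_in) || !nrow(h_in)) return(NULL)
    ok_pair <- FALSE
    for (ei in e_in$snp_id) for (hi in setdiff(h_in$snp_id, ei)) {
      ld <- ld_stats(ei, hi, gt)
      if (ld$d_prime >= dprime_min && ld$r2 < r2_max) { ok_pair <- TRUE }
    }
    if (!ok_pair) return(NULL)
    lead_e <- e_in[which.max(e_in$d2), ]
    lead_h <- h_in[which.min(h_in$p_nominal), ]
    if (lead_e$snp_id == lead_h$snp_id) return(NULL)
    ld <- ld_stats(lead_e$snp_id, lead_h$snp_id, gt)
    data.frame(block_id = blocks$block_id[bi], lead_eqtl = lead_e$snp_id,
               gene_id = lead_e$gene_id, lead_hqtl = lead_h$snp_id,
               n_snps = length(snps), d_prime = ld$d_prime, r2 = ld$r2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(block_id = character(0), lead_eqtl = character(0),
                      gene_id = character(0), lead_hqtl = character(0),
                      n_snps = integer(0), d_prime = numeric(0),
                      r2 = numeric(0))
  out
}

#' Local D-squared scan with a permutation null over variant positions
#'
#' Fits the joint-effect model (eQTL and hQTL main effects plus a
#' multiplicative interaction) of the target gene's counts and records its
#' deviance explained; the null distribution substitutes each non-QTL
#' variant of the haplotype block for the hQTL. When the number of distinct
#' substitutions is below \code{n_perm} they are exhausted once and
#' resampled with replacement up to \code{n_perm}. The permutation p-value
#' uses the add-one estimator with a Clopper-Pearson 95% CI.
#'
#' @param block_snps variant ids of the block.
#' @param gt genotypes. @param expr expression set.
#' @param gene_id target gene. @param eqtl_id,hqtl_id the lead QTL pair.
#' @param n_perm permutation count (default 10000).
#' @param seed RNG seed.
#' @return list of class \code{D2PermResult}: \code{observed_d2},
#'   \code{null_d2} (per distinct substitution, named), \code{perm_p},
#'   \code{ci} (95% Clopper-Pearson), \code{n_perm}.
#' @export
d2_scan <- function(block_snps, gt, expr, gene_id, eqtl_id, hqtl_id,
                    n_perm = 10000, seed = 1) {
  set.seed(seed)
  others <- setdiff(block_snps, c(eqtl_id, hqtl_id))
  if (length(others) < 1)
    stop("block has no non-QTL variant to permute over")
  y <- gene_counts(expr, gene_id)
  d_e <- dosages(gt, eqtl_id)[1, ]
  joint_d2 <- function(d_h) {
    f <- fit_nb_glm(y, data.frame(eqtl = d_e, hqtl = d_h,
                                  interaction = d_e * d_h))
    f$d2
  }
  observed <- joint_d2(dosages(gt, hqtl_id)[1, ])
  null_d2 <- vapply(others, function(v) {
    tryCatch(joint_d2(dosages(gt, v)[1, ]), error = function(e) NA_real_)
  }, numeric(1))
  null_ok <- null_d2[!is.na(null_d2)]
  if (!length(null_ok)) stop("no usable null substitution in block")
  draws <- if (length(null_ok) >= n_perm) {
    sample(null_ok, n_perm)
  } else {
    c(null_ok, sample(null_ok, n_perm - length(null_ok), replace = TRUE))
  }
  k <- sum(draws >= observed)
  perm_p <- (1 + k) / (1 + n_perm)
  ci <- c(lower = if (k == 0) 0 else qbeta(0.025, k, n_perm - k + 1),
          upper = if (k == n_perm) 1 else qbeta(0.975, k + 1, n_perm - k))
  structure(list(observed_d2 = observed, null_d2 = null_d2,
                 perm_p = perm_p, ci = ci, n_perm = n_perm,
                 lead_eqtl = eqtl_id, lead_hqtl = hqtl_id,
                 gene_id = gene_id),
            class = "D2PermResult")
}

#' @export
print.D2PermResult <- function(x, ...) {
  cat(sprintf(
    "D2 scan %s x %s -> %s: observed D2 %.4f, perm p %.4g [%.4g, %.4g]\n",
    x$lead_eqtl, x$lead_hqtl, x$gene_id, x$observed_d2, x$perm_p,
    x$ci["lower"], x$ci["upper"]))
  invisible(x)
}

#' Filter HiChIP loops
#'
#' Keeps loops with at least \code{min_pets} supporting paired-end tags and
#' an anchor-midpoint span within [\code{min_len}, \code{max_len}].
#'
#' @param loops loop data.frame (\code{\link{read_loops}}).
#' @param min_pets minimum PET support (4).
#' @param min_len,max_len span bounds in bp (5 kb, 2 Mb).
#' @return filtered loop data.frame.
#' @export
filter_loops <- function(loops, min_pets = 4, min_len = 5e3, max_len = 2e6) {
  span <- (loops$start_b + loops$end_b) / 2 - (loops$start_a + loops$end_a) / 2
  loops[loops$pet_count >= min_pets & span >= min_len & span <= max_len, ,
        drop = FALSE]
}

## Loop-graph machinery: overlapping anchors collapse into one node; loops
## are edges; a chromatin network is a connected component.
.loop_graph <- function(loops) {
  if (!nrow(loops)) {
    return(list(nodes = data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0)),
                node_a = integer(0), node_b = integer(0),
                membership = integer(0)))
  }
  anch <- rbind(data.frame(chrom = loops$chrom, start = loops$start_a,
                           end = loops$end_a),
                data.frame(chrom = loops$chrom, start = loops$start_b,
                           end = loops$end_b))
  nodes <- do.call(rbind, lapply(unique(anch$chrom), function(ch) {
    a <- anch[anch$chrom == ch, ]
    m <- IRanges::reduce(.as_iranges(a$start, a$end))
    data.frame(chrom = ch, start = IRanges::start(m) - 1L,
               end = IRanges::end(m), stringsAsFactors = FALSE)
  }))
  node_of <- function(chrom, start, end) {
    which(nodes$chrom == chrom & nodes$start <= start & nodes$end >= end)[1]
  }
  node_a <- mapply(node_of, loops$chrom, loops$start_a, loops$end_a)
  node_b <- mapply(node_of, loops$chrom, loops$start_b, loops$end_b)
  g <- igraph::graph_from_edgelist(cbind(node_a, node_b), directed = FALSE)
  memb <- igraph::components(g)$membership
  if (length(memb) < nrow(nodes))
    memb <- c(memb, seq(max(memb) + 1,
                        length.out = nrow(nodes) - length(memb)))
  list(nodes = nodes, node_a = node_a, node_b = node_b, membership = memb)
}

.nodes_at_point <- function(graph, chrom, pos) {
  which(graph$nodes$chrom == chrom & graph$nodes$start <= pos &
          graph$nodes$end > pos)
}

.nodes_in_range <- function(graph, chrom, start, end) {
  which(graph$nodes$chrom == chrom &
          .overlaps(graph$nodes$start, graph$nodes$end, start, end))
}

#' Strand-aware eQTL target transcript range
#'
#' 10 kb upstream of the transcription start site through the transcription
#' end site; upstream respects strand.
#'
#' @param gene one-row gene annotation (\code{chrom}, \code{tss},
#'   \code{tes}, \code{strand}).
#' @param upstream upstream extension in bp (10 kb).
#' @return list(chrom, start, end), 0-based half-open.
#' @export
target_range <- function(gene, upstream = 1e4) {
  if (is.na(gene$tss) || is.na(gene$tes)) stop("gene missing annotation: ",
                                               gene$gene_id)
  if (gene$strand == "-") {
    list(chrom = gene$chrom, start = min(gene$tss, gene$tes),
         end = max(gene$tss, gene$tes) + upstream)
  } else {
    list(chrom = gene$chrom, start = min(gene$tss, gene$tes) - upstream,
         end = max(gene$tss, gene$tes))
  }
}

#' Eligible distal eQTL x hQTL pairs
#'
#' Evaluates every supplied eQTL x hQTL combination against the distal
#' interaction filters: LD independence (\eqn{r^2 <} \code{r2_max} and
#' \eqn{D' <} \code{dprime_max}); residence on separate haplotype blocks;
#' hQTL inside an H3K27ac loop anchor; hQTL's loop network connected
#' (transitively through shared anchors) to the target gene's transcript
#' range; and all nine eQTL x hQTL dosage combinations observed. Reasons
#' for exclusion are recorded, not raised.
#'
#' @param eqtls data.frame with \code{snp_id}, \code{gene_id}.
#' @param hqtls data.frame with \code{snp_id}.
#' @param loops filtered H3K27ac loops (\code{\link{filter_loops}}).
#' @param blocks haplotype blocks.
#' @param gt genotypes.
#' @param genes gene annotation data.frame.
#' @param r2_max,dprime_max LD independence thresholds (both 0.6).
#' @return data.frame of pairs with \code{eligible} flag and \code{reason}.
#' @export
eligible_pairs <- function(eqtls, hqtls, loops, blocks, gt, genes,
                           r2_max = 0.6, dprime_max = 0.6) {
  graph <- .loop_graph(loops)
  v <- gt$variants
  dos <- dosages(gt)
  rows <- list()
  for (ei in seq_len(nrow(eqtls))) for (hi in seq_len(nrow(hqtls))) {
    e_id <- eqtls$snp_id[ei]; h_id <- hqtls$snp_id[hi]
    gene <- genes[genes$gene_id == eqtls$gene_id[ei], ]
    reason <- NA_character_
    if (e_id == h_id) reason <- "identical"
    if (is.na(reason)) {
      ld <- ld_stats(e_id, h_id, gt)
      if (!(ld$r2 < r2_max && ld$d_prime < dprime_max)) reason <- "ld"
    }
    if (is.na(reason) &&
        block_of(e_id, blocks) == block_of(h_id, blocks))
      reason <- "same_block"
    if (is.na(reason)) {
      hv <- v[v$id == h_id, ]
      h_nodes <- .nodes_at_point(graph, hv$chrom, hv$pos)
      if (!length(h_nodes)) reason <- "anchor"
      else {
        tr <- target_range(gene)
        t_nodes <- .nodes_in_range(graph, tr$chrom, tr$start, tr$end)
        if (!length(t_nodes) ||
            !any(graph$membership[t_nodes] %in% graph$membership[h_nodes]))
          reason <- "network"
      }
    }
    if (is.na(reason)) {
      tab <- table(factor(dos[e_id, ], levels = 0:2),
                   factor(dos[h_id, ], levels = 0:2))
      if (any(tab == 0)) reason <- "genotype_combinations"
    }
    rows[[length(rows) + 1]] <-
      data.frame(eqtl_id = e_id, hqtl_id = h_id,
                 gene_id = eqtls$gene_id[ei],
                 eligible = is.na(reason), reason = reason,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Distal eQTL x hQTL interaction scan
#'
#' Per eligible pair, fits the NB joint-effect model of the target gene's
#' counts on eQTL dosage, hQTL dosage and their product; significance of
#' the multiplicative interaction is a two-tailed z-test of its
#' coefficient, controlled by BH FDR across all fitted pairs.
#'
#' @param pairs data.frame from \code{\link{eligible_pairs}} (only rows
#'   with \code{eligible = TRUE} are fitted).
#' @param gt genotypes. @param expr expression set.
#' @param fdr FDR level (0.05).
#' @return list with \code{records} (one row per fitted pair:
#'   coefficients, z, p, q, significance) and \code{fits} (the
#'   \code{JointModelFit} objects, for classification).
#' @export
interaction_scan <- function(pairs, gt, expr, fdr = 0.05) {
  pairs <- pairs[pairs$eligible, , drop = FALSE]
  fits <- vector("list", nrow(pairs))
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    y <- gene_counts(expr, pairs$gene_id[i])
    d_e <- dosages(gt, pairs$eqtl_id[i])[1, ]
    d_h <- dosages(gt, pairs$hqtl_id[i])[1, ]
    f <- fit_nb_glm(y, data.frame(eqtl = d_e, hqtl = d_h,
                                  interaction = d_e * d_h))
    fits[[i]] <- f
    rows[[i]] <- data.frame(
      eqtl_id = pairs$eqtl_id[i], hqtl_id = pairs$hqtl_id[i],
      gene_id = pairs$gene_id[i],
      beta_eqtl = if (f$converged) f$coefficients["eqtl"] else NA_real_,
      beta_hqtl = if (f$converged) f$coefficients["hqtl"] else NA_real_,
      gamma = if (f$converged) f$coefficients["interaction"] else NA_real_,
      z = if (f$converged) f$z else NA_real_,
      p_interaction = if (f$converged) f$p_interaction else NA_real_,
      converged = f$converged, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  if (is.null(rec))
    rec <- data.frame(eqtl_id = character(0), hqtl_id = character(0),
                      gene_id = character(0), beta_eqtl = numeric(0),
                      beta_hqtl = numeric(0), gamma = numeric(0),
                      z = numeric(0), p_interaction = numeric(0),
                      converged = logical(0), stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  adj <- bh_fdr(rec$p_interaction, q = fdr)
  rec$q_value <- adj$qvalues
  rec$significant <- adj$reject
  list(records = rec, fits = fits)
}

#' Classify a distal interaction's loop topology
#'
#' First-match cascade over the six labels, evaluated in a fixed order:
#' \code{Anchored} if some loop anchor contains both the hQTL and
#' the eQTL; \code{Unanchored} if the hQTL lies in no anchor;
#' \code{Looped} if the eQTL lies in some (other) anchor;
#' \code{Off-target} if no loop containing the hQTL reaches the eQTL
#' target transcript range (10 kb upstream of TSS through TES,
#' strand-aware); \code{Joint} if the hQTL's and eQTL's haplotype blocks
#' are connected by a single loop (anchors overlapping the respective
#' blocks); \code{Disjoint} otherwise.
#'
#' @param record one interaction row (\code{eqtl_id}, \code{hqtl_id},
#'   \code{gene_id}).
#' @param loops filtered loops.
#' @param genes gene annotation.
#' @param gt genotypes (for variant positions).
#' @param blocks haplotype blocks (for Joint/Disjoint).
#' @return one of \code{"Anchored"}, \code{"Unanchored"}, \code{"Looped"},
#'   \code{"Off-target"}, \code{"Joint"}, \code{"Disjoint"}.
#' @export
classify_topology <- function(record, loops, genes, gt, blocks) {
  v <- gt$variants
  hv <- v[v$id == record$hqtl_id, ]; ev <- v[v$id == record$eqtl_id, ]
  gene <- genes[genes$gene_id == record$gene_id, ]
  if (!nrow(gene) || is.na(gene$tss)) stop("gene missing annotation: ",
                                           record$gene_id)
  in_anchor <- function(chrom, pos, s, e, lchrom) {
    lchrom == chrom & s <= pos & pos < e
  }
  h_in_a <- in_anchor(hv$chrom, hv$pos, loops$start_a, loops$end_a,
                      loops$chrom)
  h_in_b <- in_anchor(hv$chrom, hv$pos, loops$start_b, loops$end_b,
                      loops$chrom)
  e_in_a <- in_anchor(ev$chrom, ev$pos, loops$start_a, loops$end_a,
                      loops$chrom)
  e_in_b <- in_anchor(ev$chrom, ev$pos, loops$start_b, loops$end_b,
                      loops$chrom)
  if (any((h_in_a & e_in_a) | (h_in_b & e_in_b))) return("Anchored")
  if (!any(h_in_a | h_in_b)) return("Unanchored")
  if (any(e_in_a | e_in_b)) return("Looped")
  tr <- target_range(gene)
  partner_hits <- (h_in_a & loops$chrom == tr$chrom &
                     .overlaps(loops$start_b, loops$end_b, tr$start, tr$end)) |
    (h_in_b & loops$chrom == tr$chrom &
       .overlaps(loops$start_a, loops$end_a, tr$start, tr$end))
  if (!any(partner_hits)) return("Off-target")
  h_blk <- .block_interval(record$hqtl_id, blocks, hv)
  e_blk <- .block_interval(record$eqtl_id, blocks, ev)
  joint <- (loops$chrom == h_blk$chrom &
              .overlaps(loops$start_a, loops$end_a, h_blk$start, h_blk$end) &
              loops$chrom == e_blk$chrom &
              .overlaps(loops$start_b, loops$end_b, e_blk$start, e_blk$end)) |
    (loops$chrom == e_blk$chrom &
       .overlaps(loops$start_a, loops$end_a, e_blk$start, e_blk$end) &
       loops$chrom == h_blk$chrom &
       .overlaps(loops$start_b, loops$end_b, h_blk$start, h_blk$end))
  if (any(joint)) "Joint" else "Disjoint"
}

.block_interval <- function(id, blocks, variant_row) {
  hit <- which(vapply(blocks$snps, function(s) id %in% s, logical(1)))
  if (length(hit)) {
    list(chrom = blocks$chrom[hit[1]], start = blocks$start[hit[1]],
         end = blocks$end[hit[1]])
  } else {
    list(chrom = variant_row$chrom, start = variant_row$pos,
         end = variant_row$pos + 1L)
  }
}

#' Classify the effect-sign quadrant of an interaction fit
#'
#' Sign of the eQTL main effect crossed with the sign of the interaction
#' coefficient: (+, -) \code{enhancing-opposed}; (-, +)
#' \code{repressive-opposed}; (+, +) \code{enhancing-concordant}; (-, -)
#' \code{repressive-concordant}. A zero coefficient yields
#' \code{"boundary"} (excluded from quadrant counts).
#'
#' @param fit a converged \code{JointModelFit} (or any list with
#'   \code{coefficients["eqtl"]} and \code{coefficients["interaction"]}).
#' @return quadrant label.
#' @export
classify_quadrant <- function(fit) {
  be <- unname(fit$coefficients["eqtl"])
  ga <- unname(fit$coefficients["interaction"])
  if (is.na(be) || is.na(ga)) return(NA_character_)
  if (be == 0 || ga == 0) return("boundary")
  if (be > 0 && ga < 0) "enhancing-opposed"
  else if (be < 0 && ga > 0) "repressive-opposed"
  else if (be > 0 && ga > 0) "enhancing-concordant"
  else "repressive-concordant"
}

#' Quadrant count summary over interaction records
#' @param records interaction records with \code{beta_eqtl}, \code{gamma}.
#' @return named integer vector of quadrant counts.
#' @export
quadrant_summary <- function(records) {
  labs <- vapply(seq_len(nrow(records)), function(i) {
    classify_quadrant(list(coefficients = c(
      eqtl = records$beta_eqtl[i], interaction = records$gamma[i])))
  }, character(1))
  table(factor(labs, levels = c("enhancing-opposed", "repressive-opposed",
                                "enhancing-concordant",
                                "repressive-concordant", "boundary")))
}
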