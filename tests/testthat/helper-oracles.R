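## Independent brute-force oracles. Each is coded from the defining
## procedure, not by calling the package path it checks.

## Holm step-down: sort ascending, reject while p_(k) <= alpha/(m-k+1);
## adjusted p = running max of (m-k+1) * p_(k), capped at 1.
oracle_holm <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    running <- max(running, (m - k + 1) * p[ord[k]])
    adj[ord[k]] <- min(running, 1)
  }
  reject <- logical(m)
  for (k in seq_len(m)) {
    if (p[ord[k]] <= alpha / (m - k + 1)) reject[ord[k]] <- TRUE else break
  }
  list(adjusted = adj, reject = reject)
}

## BH step-up: q-values are the running min from the top of m * p_(k) / k;
## reject all p up to the largest k with p_(k) <= k * q / m.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  qv <- numeric(m)
  running <- Inf
  for (k in rev(seq_len(m))) {
    running <- min(running, m * p[ord[k]] / k)
    qv[ord[k]] <- min(running, 1)
  }
  kmax <- 0
  for (k in seq_len(m)) if (p[ord[k]] <= k * q / m) kmax <- k
  reject <- logical(m)
  if (kmax > 0) reject[ord[seq_len(kmax)]] <- TRUE
  list(qvalues = qv, reject = reject)
}

## Consensus peaks by literal per-base coverage counting on small ranges.
oracle_consensus <- function(peak_sets, min_support, merge_gap,
                             max_bp = 20000) {
  cover <- integer(max_bp)  # cover[i] = support of base i-1 (0-based)
  for (p in peak_sets) {
    for (r in seq_len(nrow(p))) {
      idx <- (p$start[r] + 1):p$end[r]
      cover[idx] <- cover[idx] + 1L
    }
  }
  keep <- which(cover >= min_support)
  if (!length(keep)) return(data.frame(start = integer(0), end = integer(0)))
  runs <- split(keep, cumsum(c(1, diff(keep) != 1)))
  iv <- do.call(rbind, lapply(runs, function(r)
    c(start = r[1] - 1L, end = r[length(r)])))
  iv <- as.data.frame(iv)
  ## merge adjacent intervals with gap strictly below merge_gap
  i <- 1
  while (i < nrow(iv)) {
    if (iv$start[i + 1] - iv$end[i] < merge_gap) {
      iv$end[i] <- iv$end[i + 1]
      iv <- iv[-(i + 1), , drop = FALSE]
    } else i <- i + 1
  }
  rownames(iv) <- NULL
  iv
}

## One-sided Fisher p as an explicit hypergeometric tail sum for the table
## rbind(c(a, b), c(c, d)) testing over-representation of the first cell.
oracle_fisher_greater <- function(a, b, c_, d) {
  m <- a + c_   # catalog variants
  n_ <- b + d   # non-catalog variants
  k <- a + b    # set size
  xs <- a:min(k, m)
  sum(exp(lchoose(m, xs) + lchoose(n_, k - xs) - lchoose(m + n_, k)))
}

## NB deviances by hand-rolled IRLS at fixed dispersion theta (log link).
## Returns null (intercept-only) and residual deviance.
oracle_nb_irls <- function(y, X, theta, tol = 1e-12, maxit = 200) {
  dev_fun <- function(mu) {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) -
              (y + theta) * log((y + theta) / (mu + theta)))
  }
  irls <- function(Xm) {
    eta <- log(pmax(mean(y), 0.5)) + numeric(length(y))
    dev_old <- Inf
    for (it in seq_len(maxit)) {
      mu <- exp(eta)
      w <- mu^2 / (mu + mu^2 / theta)   # 1 / (V(mu) * g'(mu)^2)
      z <- eta + (y - mu) / mu
      fit <- lm.wfit(Xm, z, w)
      eta <- drop(Xm %*% fit$coefficients)
      dev <- dev_fun(exp(eta))
      if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) break
      dev_old <- dev
    }
    dev
  }
  list(null_deviance = irls(matrix(1, length(y), 1)),
       residual_deviance = irls(cbind(1, X)))
}

## Loop-topology truth table on plain loop lists, written directly from the
## label definitions with first-match-wins semantics.
oracle_topology <- function(h_pos, e_pos, target, loops, h_block, e_block) {
  within <- function(pos, s, e) pos >= s & pos < e
  ovl <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  h_a <- within(h_pos, loops$start_a, loops$end_a)
  h_b <- within(h_pos, loops$start_b, loops$end_b)
  e_a <- within(e_pos, loops$start_a, loops$end_a)
  e_b <- within(e_pos, loops$start_b, loops$end_b)
  if (any((h_a & e_a) | (h_b & e_b))) return("Anchored")
  if (!any(h_a | h_b)) return("Unanchored")
  if (any(e_a | e_b)) return("Looped")
  reach <- (h_a & ovl(loops$start_b, loops$end_b, target[1], target[2])) |
    (h_b & ovl(loops$start_a, loops$end_a, target[1], target[2]))
  if (!any(reach)) return("Off-target")
  joint <- (ovl(loops$start_a, loops$end_a, h_block[1], h_block[2]) &
              ovl(loops$start_b, loops$end_b, e_block[1], e_block[2])) |
    (ovl(loops$start_a, loops$end_a, e_block[1], e_block[2]) &
       ovl(loops$start_b, loops$end_b, h_block[1], h_block[2]))
  if (any(joint)) "Joint" else "Disjoint"
}

## Random loop/variant/gene/block configurations for exercising the
## topology classifier against its truth table.
random_topology_config <- function(seed) {
  set.seed(seed)
  n_loops <- sample(1:6, 1)
  start_a <- sample(0:50, n_loops, replace = TRUE) * 1000
  start_b <- start_a + sample(5:40, n_loops, replace = TRUE) * 1000
  loops <- data.frame(chrom = "chr1", start_a = start_a,
                      end_a = start_a + 2000, start_b = start_b,
                      end_b = start_b + 2000, pet_count = 5,
                      mark = "H3K27ac")
  list(loops = loops,
       h_pos = sample(0:100, 1) * 1000 + sample(0:999, 1),
       e_pos = sample(0:100, 1) * 1000 + sample(0:999, 1),
       tss = sample(0:100, 1) * 1000,
       h_block = sort(sample(0:100, 2)) * 1000,
       e_block = sort(sample(0:100, 2)) * 1000)
}

## LD measures tallied directly from a 2 x 2 haplotype count table
## (counts named AB, Ab, aB, ab; upper case = alternate allele carried).
oracle_ld <- function(nAB, nAb, naB, nab) {
  n <- nAB + nAb + naB + nab
  pAB <- nAB / n
  pA <- (nAB + nAb) / n
  pB <- (nAB + naB) / n
  D <- pAB - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(d = D, d_prime = abs(D) / dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

## Build a GenotypeTable directly from explicit haplotype pools so LD is an
## exact function of the counts (each "sample" holds two pool haplotypes in
## sequence).
gt_from_haplotypes <- function(hapmat, ids = NULL, chrom = "chr1",
                               pos = NULL) {
  n_hap <- nrow(hapmat); n_var <- ncol(hapmat)
  stopifnot(n_hap %% 2 == 0)
  n_s <- n_hap / 2
  h1 <- t(hapmat[seq(1, n_hap, by = 2), , drop = FALSE])
  h2 <- t(hapmat[seq(2, n_hap, by = 2), , drop = FALSE])
  if (is.null(ids)) ids <- paste0("v", seq_len(n_var))
  if (is.null(pos)) pos <- 1000L * seq_len(n_var)
  genotype_table(h1, h2,
                 data.frame(id = ids, chrom = chrom, pos = pos,
                            ref = "A", alt = "G", stringsAsFactors = FALSE),
                 sprintf("s%03d", seq_len(n_s)))
}

## Expand haplotype class counts (AB, Ab, aB, ab) into a two-variant
## haplotype matrix.
haps_from_counts <- function(nAB, nAb, naB, nab) {
  rbind(matrix(rep(c(1, 1), nAB), ncol = 2, byrow = TRUE),
        matrix(rep(c(1, 0), nAb), ncol = 2, byrow = TRUE),
        matrix(rep(c(0, 1), naB), ncol = 2, byrow = TRUE),
        matrix(rep(c(0, 0), nab), ncol = 2, byrow = TRUE))
}
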