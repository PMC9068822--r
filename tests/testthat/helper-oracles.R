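# Independent oracles used across the suite. Each is deliberately naive
# (enumeration / coverage vectors / direct formulas) and shares no code
# with the implementation it checks.

# Exhaustive LP oracle: maximize obj'x s.t. S x = 0, 0 <= x <= ub.
# Enumerates every assignment of each variable to {0, ub, free}; for each,
# the free variables are solved from the equalities and the candidate kept
# if it is uniquely determined, balanced and within bounds. Every vertex of
# the polytope appears among the candidates, so the maximum over
# candidates is the LP optimum. Feasible only for small n (3^n).
oracle_lp_vertex <- function(obj, S, ub, tol = 1e-8) {
  S <- as.matrix(S)
  n <- length(obj)
  stopifnot(n <= 9)
  best <- -Inf
  states <- expand.grid(rep(list(0:2), n))  # 0 = at 0, 1 = at ub, 2 = free
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    x <- numeric(n)
    x[st == 1L] <- ub[st == 1L]
    free <- which(st == 2L)
    if (length(free)) {
      Sf <- S[, free, drop = FALSE]
      if (qr(Sf)$rank < length(free)) next    # not uniquely determined
      rhs <- -S[, -free, drop = FALSE] %*% x[-free]
      xf <- qr.solve(qr(Sf), rhs)
      x[free] <- xf
    }
    if (max(abs(S %*% x)) > tol) next
    if (any(x < -tol) || any(x > ub + tol)) next
    val <- sum(obj * x)
    if (val > best) best <- val
  }
  best
}

# Coverage-vector interval oracles (0-based half-open coordinates).
# Small genomes only: one logical per base.
oracle_coverage <- function(intervals, genome) {
  cov <- lapply(genome, function(len) logical(len))
  for (i in seq_len(nrow(intervals))) {
    ch <- intervals$chrom[i]
    cov[[ch]][(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  }
  cov
}

oracle_runs <- function(cov) {
  out <- list()
  for (ch in names(cov)) {
    v <- cov[[ch]]
    if (!any(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                            end = ends[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

oracle_merge <- function(intervals, genome) {
  oracle_runs(oracle_coverage(intervals, genome))
}

oracle_intersect <- function(a, b, genome) {
  ca <- oracle_coverage(a, genome)
  cb <- oracle_coverage(b, genome)
  oracle_runs(mapply(function(x, y) x & y, ca, cb, SIMPLIFY = FALSE))
}

# Benjamini-Hochberg step-up, written from the definition:
# p_adj_(i) = min_{j >= i} min(1, p_(j) * n / j).
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  padj_sorted <- pmin(1, p[o] * n / seq_len(n))
  padj_sorted <- rev(cummin(rev(padj_sorted)))
  out <- numeric(n)
  out[o] <- padj_sorted
  out
}

# Spearman rho from first principles: Pearson correlation of midranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Random small flux networks for LP oracle comparisons: a chain with
# random branches, random bounds, random category weights.
random_small_lp <- function(seed) {
  set.seed(seed)
  n <- sample(3:8, 1)
  m <- sample(2:4, 1)
  repeat {
    S <- matrix(sample(c(-1, 0, 1), m * n, replace = TRUE,
                       prob = c(0.35, 0.3, 0.35)), nrow = m)
    if (all(colSums(S != 0) > 0)) break
  }
  ub <- round(runif(n, 0, 10), 2)
  obj <- sample(c(-1, 0, 1), n, replace = TRUE) - 1e-4
  list(obj = obj, S = S, ub = ub)
}

# Random interval fixtures on a small genome.
random_interval_df <- function(n, genome, max_len = 50) {
  chrom <- sample(names(genome), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, genome[chrom] - len))
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}
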