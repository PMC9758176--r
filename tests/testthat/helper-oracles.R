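# Independent oracles and small fixture builders used across tests.

# Build a two-sample genotype matrix from raw code vectors.
make_pair_gm <- function(g1, g2, pos = NULL, chrom = "1") {
  n <- length(g1)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  genotype_matrix(c("S1", "S2"), sites, rbind(g1, g2))
}

# Brute-force streak oracle: exhaustively enumerates every window of
# consecutive sites, keeps those with <= k incompatible sites that cannot be
# extended in either direction, trims boundaries to informative compatible
# markers, drops contained duplicates, greedily selects a non-overlapping set
# preferring more informative markers, then applies the min filters.
oracle_segments <- function(g1, g2, pos, k, min_markers, min_span) {
  inc <- !is.na(g1) & !is.na(g2) & abs(g1 - g2) == 2
  inf <- !is.na(g1) & !is.na(g2) & !inc
  n <- length(inc)
  wins <- list()
  for (i in seq_len(n)) {
    m <- 0
    for (j in i:n) {
      m <- m + inc[j]
      if (m > k) break
      left_blocked <- (i == 1) || (m + inc[i - 1] > k)
      right_blocked <- (j == n) || (m + inc[j + 1] > k)
      if (left_blocked && right_blocked) wins[[length(wins) + 1]] <- c(i, j)
    }
  }
  segs <- list()
  for (w in wins) {
    ii <- w[1]; jj <- w[2]
    while (ii <= jj && !inf[ii]) ii <- ii + 1
    while (jj >= ii && !inf[jj]) jj <- jj - 1
    if (ii <= jj) segs[[length(segs) + 1]] <- c(ii, jj)
  }
  segs <- unique(segs)
  if (length(segs) > 1) {
    keep <- rep(TRUE, length(segs))
    for (a in seq_along(segs)) for (b in seq_along(segs)) {
      if (a != b && keep[a] &&
          segs[[b]][1] <= segs[[a]][1] && segs[[b]][2] >= segs[[a]][2] &&
          !identical(segs[[b]], segs[[a]])) keep[a] <- FALSE
    }
    segs <- segs[keep]
  }
  nm <- vapply(segs, function(s) sum(inf[s[1]:s[2]]), numeric(1))
  ord <- order(-nm, vapply(segs, `[`, numeric(1), 1))
  chosen <- list()
  for (r in ord) {
    s <- segs[[r]]
    free <- TRUE
    for (c in chosen) if (!(s[2] < c[1] || s[1] > c[2])) free <- FALSE
    if (free) chosen[[length(chosen) + 1]] <- s
  }
  if (length(chosen) == 0)
    return(data.frame(start = integer(), end = integer(),
                      n_markers = integer(), n_mismatches = integer()))
  out <- do.call(rbind, lapply(chosen, function(s) {
    data.frame(start = pos[s[1]], end = pos[s[2]],
               n_markers = sum(inf[s[1]:s[2]]),
               n_mismatches = sum(inc[s[1]:s[2]]))
  }))
  out <- out[out$n_markers >= min_markers & (out$end - out$start) >= min_span, ,
             drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive two-sided permutation p-value for the rank-sum statistic.
perm_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2, function(s) sum(r[s]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# Random HWE genotype vector at alt frequency q.
rand_geno <- function(n, q, missing_rate = 0) {
  g <- stats::rbinom(n, 1, q) + stats::rbinom(n, 1, q)
  if (missing_rate > 0) g[stats::runif(n) < missing_rate] <- NA_integer_
  as.integer(g)
}
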