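#' Streak-detection parameters
#'
#' Controls for the SNP-streak IBD scan. `max_mismatches` is the number of
#' IBD-incompatible sites tolerated inside one streak; `min_markers` and
#' `min_span_bp` filter out short chance runs. The defaults are conservative
#' for array-scale marker density: at a per-site chance-compatibility around
#' 0.9 between unrelated diploids, compatible runs of 100 informative markers
#' essentially never arise by chance.
#'
#' @param max_mismatches non-negative integer, incompatible sites allowed per streak.
#' @param min_markers minimum informative compatible markers per reported segment.
#' @param min_span_bp minimum physical span (bp) per reported segment.
#' @return list of class `streak_params`.
#' @export
streak_params <- function(max_mismatches = 0L, min_markers = 100L, min_span_bp = 100000L) {
  if (max_mismatches < 0 || min_markers < 0 || min_span_bp < 0)
    stop_invalid("streak parameters must be non-negative")
  structure(list(max_mismatches = as.integer(max_mismatches),
                 min_markers = as.integer(min_markers),
                 min_span_bp = as.integer(min_span_bp)),
            class = "streak_params")
}

# internal: per-site status of a sample pair.
# A site is IBD-incompatible only when the two unphased genotypes are opposite
# homozygotes (codes {0,2}) — any other combination can be carried on a shared
# haplotype. Missing genotypes are neutral: compatible but uninformative.
pair_site_status <- function(g1, g2) {
  obs <- !is.na(g1) & !is.na(g2)
  inc <- obs & abs(g1 - g2) == 2L
  list(incompatible = inc, informative = obs & !inc)
}

# internal: maximal windows with at most k incompatible sites, then trimmed so
# both boundary markers are informative and compatible. Returns a data.frame of
# site index ranges. Two-pointer over the cumulative incompatibility count:
# the window starting at i extends to the largest j with <= k incompatibles;
# a window is maximal iff it is not contained in the window of any earlier start.
max_windows <- function(inc, k) {
  n <- length(inc)
  if (n == 0) return(data.frame(i = integer(), j = integer()))
  cs <- cumsum(inc)
  cs0 <- c(0, cs[-n])
  jmax <- findInterval(k + cs0, cs)          # last j with cs[j] <= k + cs[i-1]
  jmax <- pmax(jmax, seq_len(n) - 1L)        # guard (jmax >= i-1 by construction)
  keep <- c(TRUE, diff(jmax) > 0L)
  keep <- keep & jmax >= seq_len(n)          # drop empty windows (site i itself over budget)
  data.frame(i = which(keep), j = jmax[keep])
}

# internal: trim window boundaries inward to informative compatible markers
trim_windows <- function(win, informative) {
  if (nrow(win) == 0) return(win)
  idx <- which(informative)
  if (length(idx) == 0) return(win[0, ])
  ti <- idx[findInterval(win$i - 1L, idx) + 1L]   # first informative >= i
  ti[is.na(ti)] <- Inf
  tj <- idx[pmax(findInterval(win$j, idx), 1L)]   # last informative <= j
  ok <- is.finite(ti) & ti <= tj
  out <- unique(data.frame(i = ti[ok], j = tj[ok]))
  out[order(out$i, out$j), , drop = FALSE]
}

# internal: drop windows contained in another, then greedily select a
# non-overlapping set preferring more informative markers (ties: leftmost)
select_segments <- function(win, informative) {
  if (nrow(win) == 0) return(win)
  contained <- vapply(seq_len(nrow(win)), function(r) {
    any(win$i <= win$i[r] & win$j >= win$j[r] & seq_len(nrow(win)) != r &
          !(win$i == win$i[r] & win$j == win$j[r]))
  }, logical(1))
  win <- win[!contained, , drop = FALSE]
  csum <- cumsum(informative)
  nm <- csum[win$j] - csum[win$i] + informative[win$i]
  ord <- order(-nm, win$i)
  chosen <- logical(nrow(win))
  taken <- matrix(numeric(0), ncol = 2)
  for (r in ord) {
    if (nrow(taken) == 0 || all(win$j[r] < taken[, 1] | win$i[r] > taken[, 2])) {
      chosen[r] <- TRUE
      taken <- rbind(taken, c(win$i[r], win$j[r]))
    }
  }
  out <- win[chosen, , drop = FALSE]
  out[order(out$i), , drop = FALSE]
}

# internal: segment table from index ranges
windows_to_segments <- function(win, pos, chrom, status, pair) {
  if (nrow(win) == 0)
    return(data.frame(sample1 = character(), sample2 = character(),
                      chrom = character(), start = integer(), end = integer(),
                      n_markers = integer(), n_mismatches = integer(),
                      span_bp = integer(), stringsAsFactors = FALSE))
  ci <- cumsum(status$informative); cm <- cumsum(status$incompatible)
  rngsum <- function(cs, v, i, j) cs[j] - cs[i] + v[i]
  data.frame(
    sample1 = pair[1], sample2 = pair[2], chrom = chrom,
    start = pos[win$i], end = pos[win$j],
    n_markers = rngsum(ci, as.integer(status$informative), win$i, win$j),
    n_mismatches = rngsum(cm, as.integer(status$incompatible), win$i, win$j),
    span_bp = pos[win$j] - pos[win$i],
    stringsAsFactors = FALSE
  )
}

#' Pairwise IBD segment detection by SNP streaks
#'
#' Scans the genotypes of one sample pair for maximal runs of consecutive sites
#' compatible with sharing a haplotype identical by descent. Under unphased
#' diploid genotypes, a site is incompatible with IBD sharing only when the two
#' samples are opposite homozygotes; every streak reported contains at most
#' `max_mismatches` incompatible sites, is trimmed so both boundary markers are
#' informative and compatible, cannot be extended in either direction without
#' exceeding the mismatch budget, and reported segments do not overlap (when
#' maximal windows overlap, the one with more informative markers wins).
#'
#' @param gm a [genotype_matrix()].
#' @param pair character vector of two sample identifiers.
#' @param params a [streak_params()].
#' @return data.frame with one row per segment: `sample1`, `sample2`, `chrom`,
#'   `start`, `end` (1-based inclusive marker positions), `n_markers`
#'   (informative compatible markers), `n_mismatches`, `span_bp` (`end - start`).
#' @seealso [multiway_shared_segments()], [segment_span_kb()]
#' @export
pairwise_ibd_segments <- function(gm, pair, params = streak_params()) {
  if (length(pair) != 2) stop_invalid("pair must name exactly two samples")
  g1 <- gm_row(gm, pair[1]); g2 <- gm_row(gm, pair[2])
  out <- lapply(unique(gm$sites$chrom), function(ch) {
    sel <- gm$sites$chrom == ch
    status <- pair_site_status(g1[sel], g2[sel])
    win <- max_windows(status$incompatible, params$max_mismatches)
    win <- trim_windows(win, status$informative)
    win <- select_segments(win, status$informative)
    seg <- windows_to_segments(win, gm$sites$pos[sel], ch, status, pair)
    seg[seg$n_markers >= params$min_markers & seg$span_bp >= params$min_span_bp, ,
        drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Segment span in kb, rounded to the nearest 10 kb
#'
#' Physical span `(end - start)` of an IBD segment expressed in kb at the
#' 10-kb resolution used when quoting founder-segment sizes.
#'
#' @param start,end 1-based marker positions, or a segment data.frame via
#'   `segment` (in which case `start`/`end` are taken from its columns).
#' @param segment optional data.frame with `start` and `end` columns.
#' @return integer kb value(s), half-up at the tens of kb.
#' @examples
#' segment_span_kb(36118198, 37898880)  # 1780
#' segment_span_kb(36137298, 36818382)  # 680
#' @export
segment_span_kb <- function(start, end, segment = NULL) {
  if (!is.null(segment)) { start <- segment$start; end <- segment$end }
  if (any(end < start)) stop_invalid("segment end before start")
  as.integer(round_half_up((end - start) / 1000, -1))
}

#' Multiway shared IBD segments
#'
#' Intersects the pairwise streaks over all pairs of a sample set, reporting
#' each maximal interval compatible with IBD sharing across the whole group
#' (e.g. all carriers of one founder allele). For two samples this reduces to
#' [pairwise_ibd_segments()]. Marker and mismatch counts are re-tallied on the
#' intersected intervals against the first pair's site status; `min_markers`
#' and `min_span_bp` are applied to the intersections, not the per-pair input.
#'
#' @param gm a [genotype_matrix()].
#' @param samples character vector of >= 2 sample identifiers.
#' @param params a [streak_params()].
#' @return data.frame as for [pairwise_ibd_segments()], with `sample1`/`sample2`
#'   replaced by a single `group` column.
#' @export
multiway_shared_segments <- function(gm, samples, params = streak_params()) {
  if (length(samples) < 2) stop_invalid("need at least 2 samples")
  relaxed <- streak_params(params$max_mismatches, 1L, 0L)
  pairs <- utils::combn(samples, 2, simplify = FALSE)
  per_pair <- lapply(pairs, function(p) pairwise_ibd_segments(gm, p, relaxed))
  group <- paste(samples, collapse = ",")
  out <- lapply(unique(gm$sites$chrom), function(ch) {
    ivs <- lapply(per_pair, function(seg) {
      s <- seg[seg$chrom == ch, c("start", "end"), drop = FALSE]
      as.matrix(s)
    })
    shared <- Reduce(intersect_intervals, ivs)
    if (is.null(shared) || nrow(shared) == 0) return(NULL)
    sel <- gm$sites$chrom == ch
    pos <- gm$sites$pos[sel]
    # re-tally counts over group: informative where all pairs informative,
    # mismatch where any pair incompatible
    stats_list <- lapply(pairs, function(p)
      pair_site_status(gm_row(gm, p[1])[sel], gm_row(gm, p[2])[sel]))
    inc_any <- Reduce(`|`, lapply(stats_list, `[[`, "incompatible"))
    inf_all <- Reduce(`&`, lapply(stats_list, `[[`, "informative"))
    res <- do.call(rbind, lapply(seq_len(nrow(shared)), function(r) {
      in_iv <- pos >= shared[r, 1] & pos <= shared[r, 2]
      data.frame(group = group, chrom = ch,
                 start = shared[r, 1], end = shared[r, 2],
                 n_markers = sum(inf_all & in_iv),
                 n_mismatches = sum(inc_any & in_iv),
                 span_bp = shared[r, 2] - shared[r, 1],
                 stringsAsFactors = FALSE)
    }))
    res[res$n_markers >= params$min_markers & res$span_bp >= params$min_span_bp, ,
        drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(group = character(), chrom = character(), start = integer(),
                      end = integer(), n_markers = integer(),
                      n_mismatches = integer(), span_bp = integer())
  rownames(out) <- NULL
  out
}

# internal: intersection of two sets of closed intervals (n x 2 matrices)
intersect_intervals <- function(a, b) {
  if (is.null(a) || is.null(b) || nrow(a) == 0 || nrow(b) == 0)
    return(matrix(numeric(0), ncol = 2))
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (lo <= hi) out[[length(out) + 1]] <- c(lo, hi)
  }
  if (length(out) == 0) return(matrix(numeric(0), ncol = 2))
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

#' Write IBD segments as BED6
#'
#' Converts 1-based inclusive marker coordinates to the 0-based half-open BED
#' convention (`bed_start = start - 1`). The name field is the pair or group
#' identifier, the score field the informative marker count.
#'
#' @param segments data.frame from [pairwise_ibd_segments()] or
#'   [multiway_shared_segments()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(segments, path) {
  name <- if ("group" %in% names(segments)) segments$group
          else paste(segments$sample1, segments$sample2, sep = "_")
  bed <- data.frame(segments$chrom, segments$start - 1L, segments$end,
                    name, segments$n_markers, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
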