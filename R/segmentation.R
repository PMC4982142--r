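# Segmentation of the PD series by circular binary segmentation (CBS).
#
# The PD series of a chromosome is first cleaned of two kinds of outliers —
# very small PDs (non-overlapping reads from the two ends of one amplicon,
# not independent loci) and very large PDs (unmappable stretches: assembly
# gaps, repeats) — and then recursively split at the boundary pair that
# maximizes a two-sample mean contrast, each split validated by a
# permutation test. Adjacent segments whose means do not differ are
# re-merged in a pruning pass.

#' Trim configuration for the PD series
#'
#' @param pd_low PDs below this value (bp) are removed as within-amplicon
#'   artifacts: two non-overlapping reads from one amplicon sit closer than
#'   any two independent amplicon loci. Default 300 bp, roughly the upper
#'   amplicon length.
#' @param pd_high_quantile PDs above this genome-wide quantile are removed
#'   as gaps without mappable positions (assembly gaps, repeat deserts).
#'   Default 0.995.
#' @return object of class \code{trim_config}.
#' @export
trim_config <- function(pd_low = 300, pd_high_quantile = 0.995) {
  stopifnot(pd_low >= 0, pd_high_quantile > 0.5, pd_high_quantile <= 1)
  structure(list(pd_low = pd_low, pd_high_quantile = pd_high_quantile),
            class = "trim_config")
}

#' CBS configuration
#'
#' @param alpha significance level for accepting a split (default 0.01).
#' @param n_perm permutations per split test (default 1000).
#' @param min_width minimum positions per segment (default 4).
#' @param transform signal transform before segmentation: \code{"log2p1"}
#'   (log2(PD + 1); PD is heavy-tailed, and segmentation of copy-number-like
#'   signals conventionally works on the log scale) or \code{"identity"}.
#' @param seed integer seed for the permutation tests; part of the output
#'   metadata so runs are reproducible.
#' @return object of class \code{cbs_config}.
#' @export
cbs_config <- function(alpha = 0.01, n_perm = 1000, min_width = 4,
                       transform = c("log2p1", "identity"), seed = 1L) {
  transform <- match.arg(transform)
  stopifnot(alpha > 0, alpha < 1, n_perm >= 100, min_width >= 2)
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_width = as.integer(min_width), transform = transform,
                 seed = as.integer(seed)),
            class = "cbs_config")
}

apply_transform <- function(x, transform) {
  switch(transform, log2p1 = log2(x + 1), identity = x)
}

#' Remove outlier PD values before segmentation
#'
#' Keeps PDs in \code{[pd_low, pd_high]}. The upper cutoff is normally the
#' genome-wide \code{pd_high_quantile} quantile (computed by
#' \code{\link{segment_chromosomes}} over all chromosomes and passed via
#' \code{pd_high}); when \code{pd_high} is \code{NULL} the quantile of this
#' series alone is used.
#'
#' @param series one element of \code{\link{compute_pd}} output.
#' @param cfg \code{\link{trim_config}}.
#' @param pd_high explicit upper cutoff in bp, overriding the quantile.
#' @return list with \code{chrom}, \code{pd} (retained values),
#'   \code{index_map} (strictly increasing indices of retained entries in
#'   the original series) and \code{positions}.
#' @export
trim_outliers <- function(series, cfg = trim_config(), pd_high = NULL) {
  if (is.null(pd_high))
    pd_high <- stats::quantile(series$pd, cfg$pd_high_quantile, names = FALSE)
  keep <- which(series$pd >= cfg$pd_low & series$pd <= pd_high)
  if (length(keep) == 0)
    warning("all PD values trimmed on ", series$chrom,
            "; chromosome will be skipped")
  list(chrom = series$chrom, pd = series$pd[keep], index_map = keep,
       positions = series$positions)
}

# deterministic per-window seed below 2^31
derive_seed <- function(seed, lo, hi) {
  as.integer((as.numeric(seed) + 7919 * lo + 104729 * hi) %% 2147483647)
}

#' Circular binary segmentation of a numeric series
#'
#' Recursively locates the boundary pair (i, j) maximizing the two-sample
#' contrast between the arc (i, j] and its complement (the series is treated
#' as a circle at each level, so a single internal change shows up as an
#' arc against the wrap-around complement). A split is accepted when its
#' permutation p-value, \code{(count + 1) / (n_perm + 1)} over random
#' relabelings of the values, is below \code{alpha}; accepted splits recurse
#' on the resulting linear pieces. A final pruning pass re-merges adjacent
#' segments whose means do not differ at \code{alpha}, and absorbs any
#' fragment shorter than \code{min_width} into the neighbour with the
#' closer mean. Ties in the max statistic break toward the leftmost pair,
#' so results are deterministic given the seed.
#'
#' @param values numeric vector (already transformed as desired).
#' @param cfg \code{\link{cbs_config}}.
#' @return data.frame of segments: \code{first}, \code{last} (1-based
#'   inclusive indices into \code{values}), \code{n}, \code{mean}.
#' @export
cbs_segment <- function(values, cfg = cbs_config()) {
  if (length(values) == 0)
    return(data.frame(first = integer(), last = integer(),
                      n = integer(), mean = numeric()))
  if (any(!is.finite(values))) stop("non-finite values in series")

  segs <- list()
  recurse <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2 * cfg$min_width || stats::sd(values[lo:hi]) == 0) {
      segs[[length(segs) + 1]] <<- c(lo, hi)
      return(invisible())
    }
    x <- values[lo:hi]
    m <- .cbs_max_stat(x, cfg$min_width)
    if (m$i < 0) {
      segs[[length(segs) + 1]] <<- c(lo, hi)
      return(invisible())
    }
    pv <- .cbs_perm_pvalue(x, m$stat, cfg$min_width, cfg$n_perm, cfg$alpha,
                           derive_seed(cfg$seed, lo, hi))
    p <- (pv$count + 1) / (pv$n_done + 1)
    if (p >= cfg$alpha) {
      segs[[length(segs) + 1]] <<- c(lo, hi)
      return(invisible())
    }
    # local boundaries m$i < m$j split [1..n] into [1..i], (i..j], (j..n]
    cuts <- c(if (m$i > 0) c(1, m$i), c(m$i + 1, m$j),
              if (m$j < n) c(m$j + 1, n))
    pieces <- matrix(cuts, ncol = 2, byrow = TRUE)
    for (r in seq_len(nrow(pieces)))
      recurse(lo + pieces[r, 1] - 1, lo + pieces[r, 2] - 1)
  }
  recurse(1, length(values))

  segdf <- do.call(rbind, lapply(segs, function(s)
    data.frame(first = s[1], last = s[2])))
  segdf <- segdf[order(segdf$first), , drop = FALSE]
  segdf <- prune_segments(segdf, values, cfg)
  segdf <- absorb_small_segments(segdf, values, cfg$min_width)
  segdf$n <- segdf$last - segdf$first + 1
  segdf$mean <- vapply(seq_len(nrow(segdf)), function(r)
    mean(values[segdf$first[r]:segdf$last[r]]), numeric(1))
  rownames(segdf) <- NULL
  segdf
}

# merge adjacent segments whose means do not differ at alpha
prune_segments <- function(segdf, values, cfg) {
  repeat {
    if (nrow(segdf) < 2) break
    pvals <- vapply(seq_len(nrow(segdf) - 1), function(r) {
      a <- values[segdf$first[r]:segdf$last[r]]
      b <- values[segdf$first[r + 1]:segdf$last[r + 1]]
      adjacent_pvalue(a, b, cfg, derive_seed(cfg$seed, segdf$first[r],
                                             segdf$last[r + 1]))
    }, numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] < cfg$alpha) break
    segdf$last[worst] <- segdf$last[worst + 1]
    segdf <- segdf[-(worst + 1), , drop = FALSE]
  }
  segdf
}

adjacent_pvalue <- function(a, b, cfg, seed) {
  if (length(a) >= 2 && length(b) >= 2 &&
      (stats::sd(a) > 0 || stats::sd(b) > 0)) {
    return(tryCatch(stats::t.test(a, b)$p.value,
                    error = function(e) .perm_mean_diff_pvalue(
                      a, b, cfg$n_perm, seed)))
  }
  if (stats::sd(c(a, b)) == 0) return(1)  # identical flat pieces
  .perm_mean_diff_pvalue(a, b, cfg$n_perm, seed)
}

# fragments below min_width join the neighbour with the closer mean
absorb_small_segments <- function(segdf, values, min_width) {
  repeat {
    n <- segdf$last - segdf$first + 1
    small <- which(n < min_width)
    if (length(small) == 0 || nrow(segdf) < 2) break
    r <- small[1]
    mu <- function(r) mean(values[segdf$first[r]:segdf$last[r]])
    into <- if (r == 1) 2
    else if (r == nrow(segdf)) r - 1
    else if (abs(mu(r) - mu(r - 1)) <= abs(mu(r) - mu(r + 1))) r - 1
    else r + 1
    lo <- min(segdf$first[r], segdf$first[into])
    hi <- max(segdf$last[r], segdf$last[into])
    segdf$first[min(r, into)] <- lo
    segdf$last[min(r, into)] <- hi
    segdf <- segdf[-max(r, into), , drop = FALSE]
  }
  segdf
}

#' Trim and segment every chromosome's PD series
#'
#' Applies outlier trimming (with a genome-wide upper PD quantile) and CBS
#' per chromosome, then reports each segment with its genomic span and mean
#' PD on the untransformed scale — the per-region statistics table that
#' drives target-region classification, plus the per-chromosome data behind
#' the mean-PD plots.
#'
#' @param pd_by_chrom output of \code{\link{compute_pd}}.
#' @param trim_cfg \code{\link{trim_config}}.
#' @param cbs_cfg \code{\link{cbs_config}}.
#' @return data.frame of segments: \code{chrom}, \code{first_idx},
#'   \code{last_idx} (indices into that chromosome's position table),
#'   \code{start_bp}, \code{end_bp} (span of the first to last retained
#'   position), \code{n_positions}, \code{mean_pd} (bp, untransformed),
#'   \code{segment_stat} (transformed-scale mean), \code{flagged}
#'   (TRUE for whole-chromosome remainders with fewer than
#'   \code{min_width} retained positions). Attribute \code{seed} records
#'   the permutation seed.
#' @export
segment_chromosomes <- function(pd_by_chrom, trim_cfg = trim_config(),
                                cbs_cfg = cbs_config()) {
  all_pd <- unlist(lapply(pd_by_chrom, `[[`, "pd"), use.names = FALSE)
  if (length(all_pd) == 0)
    return(structure(empty_segment_table(), seed = cbs_cfg$seed))
  pd_high <- stats::quantile(all_pd, trim_cfg$pd_high_quantile, names = FALSE)

  rows <- lapply(pd_by_chrom, function(series) {
    tr <- suppressWarnings(trim_outliers(series, trim_cfg, pd_high = pd_high))
    if (length(tr$pd) == 0) return(NULL)
    pos <- series$positions
    if (length(tr$pd) < cbs_cfg$min_width) {
      segdf <- data.frame(first = 1L, last = length(tr$pd),
                          n = length(tr$pd), mean = mean(
                            apply_transform(tr$pd, cbs_cfg$transform)))
      flagged <- TRUE
    } else {
      segdf <- cbs_segment(apply_transform(tr$pd, cbs_cfg$transform), cbs_cfg)
      flagged <- FALSE
    }
    data.frame(
      chrom = series$chrom,
      first_idx = tr$index_map[segdf$first],
      last_idx = tr$index_map[segdf$last],
      start_bp = pos$start[tr$index_map[segdf$first]],
      end_bp = pos$end[tr$index_map[segdf$last]],
      n_positions = segdf$last - segdf$first + 1,
      mean_pd = vapply(seq_len(nrow(segdf)), function(r)
        mean(tr$pd[segdf$first[r]:segdf$last[r]]), numeric(1)),
      segment_stat = segdf$mean,
      flagged = flagged,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_segment_table()
  rownames(out) <- NULL
  structure(out, seed = cbs_cfg$seed)
}

empty_segment_table <- function() {
  data.frame(chrom = character(), first_idx = integer(),
             last_idx = integer(), start_bp = numeric(), end_bp = numeric(),
             n_positions = integer(), mean_pd = numeric(),
             segment_stat = numeric(), flagged = logical(),
             stringsAsFactors = FALSE)
}
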