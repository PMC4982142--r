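# DOP-positions and the pairwise-distance (PD) signal.
#
# Overlapping (or book-ended) reads collapse into a "DOP-position": one
# interval standing for one DOP-PCR amplicon locus. The ordered gaps between
# consecutive positions on a chromosome — the PD series — carry the signal
# that separates target regions (dense amplicons, small PD) from the
# whole-genome background (sparse amplicons, large PD).

#' Merge read intervals into DOP-positions
#'
#' Computes the union of overlapping-or-book-ended read intervals per
#' chromosome (the behaviour of \code{bedtools merge} on a read BED), with
#' the number of contributing reads attached to each merged interval.
#'
#' @param read_intervals data.frame with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open); may be unsorted.
#' @return data.frame of positions: \code{chrom}, \code{start}, \code{end},
#'   \code{read_count}, sorted by (chrom, start); within a chromosome,
#'   positions are disjoint and separated by at least 1 bp.
#' @export
merge_reads_to_positions <- function(read_intervals) {
  df <- read_intervals
  if (nrow(df) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), read_count = integer(),
                      stringsAsFactors = FALSE))
  bad <- df$end <= df$start
  if (any(bad)) {
    warning(sum(bad), " read interval(s) with end <= start rejected")
    df <- df[!bad, , drop = FALSE]
  }
  gr <- as_granges(df)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)  # merges book-ended
  out <- granges_to_df(red)
  out$read_count <- S4Vectors::elementNROWS(S4Vectors::mcols(red)$revmap)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute per-chromosome pairwise distances (PD)
#'
#' For every chromosome, the distance from each DOP-position to the one on
#' its left: \code{pd[1]} is the start coordinate of the first position
#' (its distance to the chromosome's 0-coordinate) and
#' \code{pd[i] = start[i] - end[i-1]} thereafter. The conservation identity
#' \code{sum(pd) + sum(widths) = end of last position} holds per chromosome.
#'
#' @param positions DOP-position data.frame (\code{\link{merge_reads_to_positions}}).
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   given, a position extending beyond its chromosome is an error.
#' @return named list (one element per chromosome, in sorted order) of lists
#'   with \code{chrom}, \code{pd} (numeric vector) and \code{positions}
#'   (that chromosome's position rows, sorted).
#' @export
compute_pd <- function(positions, chrom_lengths = NULL) {
  if (nrow(positions) == 0) return(structure(list(), names = character()))
  positions <- positions[order(positions$chrom, positions$start), , drop = FALSE]
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[positions$chrom]
    over <- is.na(len) | positions$end > len
    if (any(over)) {
      i <- which(over)[1]
      stop("position beyond chromosome length: ", positions$chrom[i],
           ":", positions$start[i], "-", positions$end[i])
    }
  }
  by_chrom <- split(positions, positions$chrom)
  lapply(by_chrom, function(p) {
    pd <- c(p$start[1], if (nrow(p) > 1) p$start[-1] - p$end[-nrow(p)])
    if (any(pd < 0)) stop("overlapping positions on ", p$chrom[1],
                          "; merge reads first")
    list(chrom = p$chrom[1], pd = as.numeric(pd), positions = p)
  })
}

#' DOP-position length histogram with mode detection
#'
#' Bins position lengths at a fixed bin width and reports local maxima as
#' modes. DOP-PCR amplicon lengths are characteristically bimodal (a short
#' peak near 100 bp from fragmented amplicons and a long peak at 180-200 bp
#' from intact ones), so the histogram is a quick library QC.
#'
#' @param positions DOP-position data.frame; may be empty.
#' @param bin_width histogram bin width in bp (default 10).
#' @param min_prominence a bin is a mode only if its count is at least this
#'   fraction of the maximum bin count (default 0.25) and it is a strict
#'   local maximum over a +/- 2-bin window.
#' @return list with \code{histogram} (data.frame \code{bin_start},
#'   \code{bin_end}, \code{count}) and \code{modes} (bin start coordinates
#'   of detected modes, possibly empty).
#' @export
position_length_histogram <- function(positions, bin_width = 10,
                                      min_prominence = 0.25) {
  if (nrow(positions) == 0)
    return(list(histogram = data.frame(bin_start = numeric(),
                                       bin_end = numeric(),
                                       count = integer()),
                modes = numeric()))
  len <- positions$end - positions$start
  bin <- floor(len / bin_width)
  bins <- seq(0, max(bin))
  count <- tabulate(bin + 1, nbins = max(bin) + 1)
  hist <- data.frame(bin_start = bins * bin_width,
                     bin_end = (bins + 1) * bin_width,
                     count = count)
  thr <- min_prominence * max(count)
  is_mode <- vapply(seq_along(count), function(i) {
    if (count[i] < thr || count[i] == 0) return(FALSE)
    win_idx <- max(1, i - 2):min(length(count), i + 2)
    m <- max(count[win_idx])
    # a plateau of tied bins yields one mode, at its leftmost bin
    count[i] == m && i == min(win_idx[count[win_idx] == m])
  }, logical(1))
  list(histogram = hist, modes = hist$bin_start[is_mode])
}

#' Occupancy statistics of positions over target regions
#'
#' Summarizes how DOP-positions relate to a set of (disjoint) target
#' regions: the fraction of all positions that fall inside the regions
#' (membership by position midpoint) and the fraction of the regions' length
#' occupied by positions.
#'
#' @param positions DOP-position data.frame.
#' @param target_regions data.frame of disjoint intervals (\code{chrom},
#'   \code{start}, \code{end}); may be empty, in which case target-relative
#'   fields are \code{NA} (undefined, distinct from 0).
#' @return one-row data.frame: \code{n_positions_genome},
#'   \code{bp_positions_genome}, \code{target_region_bp},
#'   \code{n_positions_in_target}, \code{pct_positions_in_target},
#'   \code{occupancy_pct}, \code{positions_per_kbp_target}.
#' @export
occupancy_stats <- function(positions, target_regions) {
  n_pos <- nrow(positions)
  bp_pos <- sum(positions$end - positions$start)
  if (is.null(target_regions) || nrow(target_regions) == 0)
    return(data.frame(n_positions_genome = n_pos,
                      bp_positions_genome = bp_pos,
                      target_region_bp = 0,
                      n_positions_in_target = NA_real_,
                      pct_positions_in_target = NA_real_,
                      occupancy_pct = NA_real_,
                      positions_per_kbp_target = NA_real_))
  tr <- as_granges(target_regions)
  if (!IRanges::isDisjoint(tr)) stop("target regions must be disjoint")
  target_bp <- sum(target_regions$end - target_regions$start)
  # midpoint membership: unambiguous for 100-200 bp positions vs kbp regions
  mid <- floor((positions$start + positions$end) / 2)
  mid_gr <- GenomicRanges::GRanges(positions$chrom,
                                   IRanges::IRanges(mid + 1, width = 1))
  in_target <- IRanges::overlapsAny(mid_gr, tr)
  cov_bp <- sum(IRanges::width(GenomicRanges::intersect(
    GenomicRanges::reduce(as_granges(positions)), GenomicRanges::reduce(tr))))
  data.frame(
    n_positions_genome = n_pos,
    bp_positions_genome = bp_pos,
    target_region_bp = target_bp,
    n_positions_in_target = sum(in_target),
    pct_positions_in_target = if (n_pos) 100 * sum(in_target) / n_pos else NA_real_,
    occupancy_pct = 100 * cov_bp / target_bp,
    positions_per_kbp_target = sum(in_target) / (target_bp / 1000))
}
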