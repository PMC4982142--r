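# Target-region calling from labeled segments: classification of segments
# into target vs background, margin calling, putative internal deletions,
# and gene completeness annotation.

#' Classify segments into target and background
#'
#' Regions physically present on the sorted chromosome show a much smaller
#' mean PD than the whole-genome background, so segments separate on
#' \code{log2(mean_pd)}. The default method is an exact 1-D 2-means on that
#' scale; the low-mean cluster is target. Segments whose mean PD falls
#' within \code{margin_factor} of the cluster boundary are flagged
#' \code{"ambiguous"} for visual review, as are sparse segments at
#' chromosome ends (a known artifact of spurious telomeric-read mapping).
#' The classifier is a provisional screen: borderline calls are meant to be
#' checked against the per-chromosome PD plots.
#'
#' @param segments segment table from \code{\link{segment_chromosomes}}.
#' @param method \code{"two_cluster"} (default) or \code{"threshold"}.
#' @param threshold mean-PD cutoff in bp for \code{method = "threshold"};
#'   segments at or below it are target.
#' @param margin_factor half-width (as a multiplicative factor, default 2)
#'   of the ambiguous band around the cluster boundary.
#' @param min_contrast minimum ratio between the background and target
#'   cluster mean-PD (geometric means) for the clustering to be trusted;
#'   below it everything is background with a warning (default 3).
#' @param min_region_positions target segments with fewer positions than
#'   this (default 10) lying first or last on their chromosome are demoted
#'   to \code{"ambiguous"} (telomeric-artifact suppression).
#' @return the segment table with a \code{label} column
#'   (\code{"target"}, \code{"background"}, \code{"ambiguous"}) and an
#'   attribute \code{boundary_pd} (bp; NA for \code{threshold} method).
#' @export
classify_segments <- function(segments,
                              method = c("two_cluster", "threshold"),
                              threshold = NULL, margin_factor = 2,
                              min_contrast = 3,
                              min_region_positions = 10) {
  method <- match.arg(method)
  if (nrow(segments) == 0) {
    segments$label <- character(0)
    return(structure(segments, boundary_pd = NA_real_))
  }
  if (method == "threshold") {
    if (is.null(threshold)) stop("threshold method needs a mean_pd cutoff")
    segments$label <- ifelse(segments$mean_pd <= threshold,
                             "target", "background")
    boundary <- threshold
  } else {
    if (nrow(segments) < 2) {
      warning("single segment genome-wide: no contrast, all background")
      segments$label <- "background"
      return(structure(segments, boundary_pd = NA_real_))
    }
    lp <- log2(segments$mean_pd)
    km <- kmeans_1d_2(lp)
    lo <- which.min(km$centers)
    contrast <- 2^abs(diff(km$centers))
    if (contrast < min_contrast) {
      warning("mean-PD contrast between clusters (", round(contrast, 2),
              "x) below min_contrast: no target called")
      segments$label <- "background"
      return(structure(segments, boundary_pd = NA_real_))
    }
    boundary <- 2^((max(lp[km$cluster == lo]) +
                      min(lp[km$cluster != lo])) / 2)
    segments$label <- ifelse(km$cluster == lo, "target", "background")
    band <- segments$mean_pd >= boundary / margin_factor &
      segments$mean_pd <= boundary * margin_factor
    segments$label[band] <- "ambiguous"
  }
  # telomeric-artifact suppression: sparse target segments at chromosome ends
  for (ch in unique(segments$chrom)) {
    idx <- which(segments$chrom == ch)
    ends <- c(idx[1], idx[length(idx)])
    demote <- intersect(ends, which(segments$label == "target" &
                                      segments$n_positions < min_region_positions))
    segments$label[demote] <- "ambiguous"
  }
  structure(segments, boundary_pd = boundary)
}

# exact 1-D 2-means: best split of the sorted values by within-SS
kmeans_1d_2 <- function(x) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  ss <- vapply(seq_len(n - 1), function(k) {
    (cs2[k] - cs[k]^2 / k) +
      ((cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k))
  }, numeric(1))
  k <- which.min(ss)
  cluster <- integer(n)
  cluster[o[seq_len(k)]] <- 1L
  cluster[o[(k + 1):n]] <- 2L
  centers <- c(mean(xs[seq_len(k)]), mean(xs[(k + 1):n]))
  list(cluster = cluster, centers = centers)
}

#' Call target regions from labeled segments
#'
#' Adjacent target segments on one chromosome merge into a single region;
#' region margins are the outermost positions of the merged dense run.
#' Because each PD value describes the gap to the position on its left, a
#' segment of small PDs spans one position more than its index range: the
#' position immediately left of its first retained index is the true left
#' margin and is included when available.
#'
#' Margins are then refined: edge positions whose gap into the rest of the
#' run exceeds \code{refine_pd} (by default the classification boundary
#' between target and background PD) are stripped, so stray background
#' positions absorbed at a segment boundary do not stretch the region.
#'
#' @param labeled_segments output of \code{\link{classify_segments}}.
#' @param positions DOP-position table; used to place the extended left
#'   margin, refine the margins, and recompute the per-region position
#'   count. When omitted, margins fall back to the segment spans.
#' @param refine_pd gap cutoff (bp) for margin refinement; defaults to the
#'   \code{boundary_pd} attribute of \code{labeled_segments}, and no
#'   refinement happens when that is absent.
#' @return data.frame of region calls: \code{region_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{n_positions}, \code{mean_pd},
#'   \code{label} ("target").
#' @export
call_regions <- function(labeled_segments, positions = NULL,
                         refine_pd = NULL) {
  if (is.null(refine_pd)) refine_pd <- attr(labeled_segments, "boundary_pd")
  seg <- labeled_segments[labeled_segments$label == "target", , drop = FALSE]
  if (nrow(seg) == 0)
    return(data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_positions = integer(), mean_pd = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  seg <- seg[order(seg$chrom, seg$start_bp), , drop = FALSE]
  # merge runs of adjacent target segments (consecutive retained indices)
  grp <- cumsum(c(TRUE, !(seg$chrom[-1] == seg$chrom[-nrow(seg)] &
                            seg$first_idx[-1] <= seg$last_idx[-nrow(seg)] + 1)))
  rows <- lapply(split(seq_len(nrow(seg)), grp), function(ii) {
    s <- seg[ii, , drop = FALSE]
    start <- min(s$start_bp)
    end <- max(s$end_bp)
    if (!is.null(positions)) {
      pos_c <- positions[positions$chrom == s$chrom[1], , drop = FALSE]
      pos_c <- pos_c[order(pos_c$start), , drop = FALSE]
      first <- min(s$first_idx)
      # pd[first] is the gap right of position first - 1: include it
      if (first > 1) start <- pos_c$start[first - 1]
      run <- pos_c[pos_c$start >= start & pos_c$end <= end, , drop = FALSE]
      if (nrow(run) >= 2 && is.finite(refine_pd)) {
        # blocks of positions separated by gaps above the boundary PD;
        # stray background blocks at the edges are small and get stripped
        gap <- run$start[-1] - run$end[-nrow(run)]
        block <- cumsum(c(1, as.integer(gap > refine_pd)))
        sizes <- tabulate(block)
        keep <- which(sizes >= min(4, max(sizes)))
        start <- run$start[match(min(keep), block)]
        end <- max(run$end[block == max(keep)])
      }
    }
    data.frame(chrom = s$chrom[1],
               start = start, end = end,
               n_positions = sum(s$n_positions),
               mean_pd = sum(s$mean_pd * s$n_positions) / sum(s$n_positions),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  if (!is.null(positions)) {
    out$n_positions <- vapply(seq_len(nrow(out)), function(r) {
      sum(positions$chrom == out$chrom[r] &
            positions$start >= out$start[r] & positions$end <= out$end[r])
    }, numeric(1))
  }
  out <- cbind(region_id = paste0(out$chrom, ":", out$start, "-", out$end),
               out, stringsAsFactors = FALSE)
  out$label <- "target"
  rownames(out) <- NULL
  out
}

#' Detect putative internal deletions in a target region
#'
#' Maximal stretches inside a target region with no read-covered position
#' and length at least \code{min_gap} are reported as putative deletions:
#' sequence plausibly absent from the sampled chromosome. Overlap with an
#' assembly gap is annotated as a possible alternative explanation (the gap
#' is unmappable, so absence of positions there is not evidence of
#' absence).
#'
#' @param region one row of a \code{\link{call_regions}} table (or a
#'   one-row data.frame with \code{chrom}, \code{start}, \code{end}).
#' @param positions DOP-position table.
#' @param gaps optional assembly-gap intervals (\code{chrom}, \code{start},
#'   \code{end}).
#' @param min_gap minimum deletion length in bp (default 100000).
#' @return data.frame of deletion calls: \code{chrom}, \code{start},
#'   \code{end}, \code{length}, \code{overlaps_assembly_gap}.
#' @export
detect_deletions <- function(region, positions, gaps = NULL,
                             min_gap = 100000) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), length = numeric(),
                      overlaps_assembly_gap = logical(),
                      stringsAsFactors = FALSE)
  if (region$end - region$start < min_gap) return(empty)
  p <- positions[positions$chrom == region$chrom &
                   positions$end > region$start &
                   positions$start < region$end, , drop = FALSE]
  if (nrow(p) == 0) return(empty)
  cov <- IRanges::reduce(IRanges::IRanges(p$start + 1, p$end))
  covdf <- data.frame(start = IRanges::start(cov) - 1, end = IRanges::end(cov))
  # gaps between consecutive covered stretches, clipped to the region
  if (nrow(covdf) < 2) return(empty)
  del <- data.frame(chrom = region$chrom,
                    start = utils::head(covdf$end, -1),
                    end = utils::tail(covdf$start, -1),
                    stringsAsFactors = FALSE)
  del$start <- pmax(del$start, region$start)
  del$end <- pmin(del$end, region$end)
  del$length <- del$end - del$start
  del <- del[del$length >= min_gap, , drop = FALSE]
  if (nrow(del) == 0) return(empty)
  if (!is.null(gaps) && nrow(gaps)) {
    del$overlaps_assembly_gap <- IRanges::overlapsAny(
      as_granges(del), as_granges(gaps))
  } else del$overlaps_assembly_gap <- FALSE
  rownames(del) <- NULL
  del
}

#' Detect deletions across all target regions
#'
#' @param regions \code{\link{call_regions}} table.
#' @inheritParams detect_deletions
#' @return combined deletion table with a \code{region_id} column.
#' @export
detect_deletions_all <- function(regions, positions, gaps = NULL,
                                 min_gap = 100000) {
  rows <- lapply(seq_len(nrow(regions)), function(r) {
    d <- detect_deletions(regions[r, , drop = FALSE], positions, gaps,
                          min_gap)
    if (nrow(d)) cbind(region_id = regions$region_id[r], d,
                       stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      length = numeric(), overlaps_assembly_gap = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Annotate gene completeness over target regions
#'
#' Each gene overlapping a target region is classified: \code{complete}
#' when fully inside the region and clear of putative deletions;
#' \code{partial_margin} ("(f)") when it crosses a region margin;
#' \code{partial_deletion} ("(f?)") when inside the region but overlapping
#' a putative deletion. A gene both crossing a margin and touching a
#' deletion is margin-first: \code{partial_margin}.
#'
#' @param regions \code{\link{call_regions}} table.
#' @param deletions \code{\link{detect_deletions_all}} table (may be empty).
#' @param models \code{\link{gene_models}} object, or a data.frame of gene
#'   spans (\code{chrom}, \code{start}, \code{end}, \code{gene_id}).
#' @return list with \code{genes} (data.frame \code{gene_id},
#'   \code{region_id}, \code{status}, \code{flag}) and \code{summary}
#'   (one-row data.frame \code{n_complete}, \code{n_partial},
#'   \code{n_partial_margin}, \code{n_partial_deletion}).
#' @export
annotate_genes <- function(regions, deletions, models) {
  spans <- if (inherits(models, "gene_models")) models$spans else models
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    reg <- regions[r, ]
    g <- spans[spans$chrom == reg$chrom & spans$end > reg$start &
                 spans$start < reg$end, , drop = FALSE]
    if (nrow(g) == 0) next
    del <- deletions[deletions$region_id == reg$region_id, , drop = FALSE]
    crosses <- g$start < reg$start | g$end > reg$end
    hits_del <- if (nrow(del)) IRanges::overlapsAny(
      as_granges(g), as_granges(del)) else rep(FALSE, nrow(g))
    status <- ifelse(crosses, "partial_margin",
                     ifelse(hits_del, "partial_deletion", "complete"))
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = g$gene_id, region_id = reg$region_id, status = status,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  if (is.null(genes))
    genes <- data.frame(gene_id = character(), region_id = character(),
                        status = character(), stringsAsFactors = FALSE)
  genes$flag <- c(complete = "", partial_margin = "(f)",
                  partial_deletion = "(f?)")[genes$status]
  rownames(genes) <- NULL
  list(genes = genes,
       summary = data.frame(
         n_complete = sum(genes$status == "complete"),
         n_partial = sum(genes$status != "complete"),
         n_partial_margin = sum(genes$status == "partial_margin"),
         n_partial_deletion = sum(genes$status == "partial_deletion")))
}

#' Total region size with and without putative deletions
#'
#' @param regions \code{\link{call_regions}}-style table.
#' @param deletions deletion table (clipped to regions before subtraction).
#' @return one-row data.frame: \code{n_regions}, \code{total_bp},
#'   \code{total_minus_deletions_bp}.
#' @export
region_size_accounting <- function(regions, deletions = NULL) {
  if (nrow(regions) == 0)
    return(data.frame(n_regions = 0L, total_bp = 0,
                      total_minus_deletions_bp = 0))
  total <- sum(regions$end - regions$start)
  del_bp <- 0
  if (!is.null(deletions) && nrow(deletions)) {
    inter <- GenomicRanges::intersect(
      GenomicRanges::reduce(as_granges(deletions)),
      GenomicRanges::reduce(as_granges(regions)))
    del_bp <- sum(IRanges::width(inter))
  }
  data.frame(n_regions = nrow(regions), total_bp = total,
             total_minus_deletions_bp = total - del_bp)
}

#' Report short low-PD runs as visual candidates
#'
#' Regions smaller than CBS can resolve (fewer than \code{2 * min_width}
#' positions) still show up as short runs of consecutive small PDs. This
#' secondary scan reports runs of at least \code{min_run} consecutive
#' positions with PD at or below \code{pd_cutoff} that fall outside the
#' called regions, as candidates for visual review of the PD plots.
#'
#' @param pd_by_chrom output of \code{\link{compute_pd}}.
#' @param regions called target regions (candidates overlapping them are
#'   dropped); may be empty.
#' @param pd_cutoff PD value (bp) at or below which a gap counts as
#'   target-like; a natural choice is the \code{boundary_pd} attribute of
#'   \code{\link{classify_segments}}.
#' @param min_run minimum run length in positions (default 4).
#' @return data.frame \code{chrom}, \code{start}, \code{end},
#'   \code{n_positions}, \code{label} = "candidate (visual)".
#' @export
candidate_regions <- function(pd_by_chrom, regions, pd_cutoff,
                              min_run = 4) {
  rows <- list()
  for (series in pd_by_chrom) {
    low <- series$pd <= pd_cutoff
    if (length(low) < 2) next
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_run)) {
      # pd[i] is the gap left of position i: a run of small pd values
      # from i0..i1 means positions (i0 - 1)..i1 are densely spaced
      i0 <- max(1, starts[k] - 1); i1 <- ends[k]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = series$chrom,
        start = series$positions$start[i0],
        end = series$positions$end[i1],
        n_positions = i1 - i0 + 1, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_positions = integer(),
                      label = character(), stringsAsFactors = FALSE))
  if (!is.null(regions) && nrow(regions)) {
    keep <- !IRanges::overlapsAny(as_granges(out), as_granges(regions))
    out <- out[keep, , drop = FALSE]
  }
  out$label <- rep("candidate (visual)", nrow(out))
  rownames(out) <- NULL
  out
}
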