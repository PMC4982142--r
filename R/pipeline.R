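# End-to-end orchestration: from dual alignments to called regions.

#' Run the full target-region detection pipeline
#'
#' Chains contamination filtering, DOP-position construction, PD
#' computation, CBS segmentation, target classification, region calling and
#' putative-deletion detection.
#'
#' @param dual_alignments dual-alignment table
#'   (\code{\link{read_dual_alignments}}, \code{\link{read_dual_tsv}}, or
#'   \code{simulate_experiment()$dual_alignments}).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param mapq_floor MAPQ floor for \code{\link{filter_contaminant_reads}}.
#' @param trim_cfg \code{\link{trim_config}}.
#' @param cbs_cfg \code{\link{cbs_config}}.
#' @param gaps optional assembly-gap intervals.
#' @param min_gap minimum putative-deletion length (bp).
#' @param classify_args list of extra arguments to
#'   \code{\link{classify_segments}}.
#' @return list with elements \code{decontam_stats}, \code{positions},
#'   \code{pd}, \code{segments}, \code{regions}, \code{deletions},
#'   \code{candidates}.
#' @export
run_pipeline <- function(dual_alignments, chrom_lengths,
                         mapq_floor = 20,
                         trim_cfg = trim_config(),
                         cbs_cfg = cbs_config(),
                         gaps = NULL, min_gap = 100000,
                         classify_args = list()) {
  filt <- filter_contaminant_reads(dual_alignments, mapq_floor = mapq_floor)
  positions <- merge_reads_to_positions(alignments_to_intervals(filt$kept))
  pd <- compute_pd(positions, chrom_lengths)
  segments <- segment_chromosomes(pd, trim_cfg, cbs_cfg)
  labeled <- do.call(classify_segments, c(list(segments), classify_args))
  regions <- call_regions(labeled, positions)
  deletions <- detect_deletions_all(regions, positions, gaps, min_gap)
  boundary <- attr(labeled, "boundary_pd")
  candidates <- if (is.finite(boundary))
    candidate_regions(pd, regions, boundary, min_run = cbs_cfg$min_width)
  else candidate_regions(pd, regions, -Inf)[0, ]
  list(decontam_stats = filt$stats, positions = positions, pd = pd,
       segments = labeled, regions = regions, deletions = deletions,
       candidates = candidates)
}
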