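# Dual-genome contamination filtering.
#
# Reads are aligned independently to the target genome and to a contaminant
# genome (typically human). Mapping quality on each genome serves as the
# alignment metric: a read whose contaminant-genome MAPQ exceeds its
# target-genome MAPQ is treated as contamination, and a MAPQ floor on the
# target genome removes non-unique / low-confidence alignments.

#' Build a dual-alignment table from two SAM/BAM files
#'
#' Joins per-read alignments from a target-genome and a contaminant-genome
#' alignment on (read name, mate). Secondary and supplementary alignments
#' are ignored; reads unmapped in the target genome are dropped (they carry
#' no target coordinates). A read present only in the target file gets
#' \code{contam_mapq = NA} (treated as 0 by the filter).
#'
#' @param target_path SAM/BAM of alignments to the target genome.
#' @param contam_path SAM/BAM of alignments to the contaminant genome.
#' @return data.frame of dual alignments with columns \code{read_id},
#'   \code{mate} (1 or 2), \code{target_mapq}, \code{contam_mapq},
#'   \code{target_chrom}, \code{target_start}, \code{target_end}
#'   (0-based half-open).
#' @export
read_dual_alignments <- function(target_path, contam_path) {
  scan1 <- function(path) {
    if (tolower(tools::file_ext(path)) == "sam")
      path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
    flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "qwidth", "mapq", "cigar"),
      flag = flag)
    res <- Rsamtools::scanBam(path, param = p)[[1]]
    mate <- ifelse(bitwAnd(res$flag, 128L) > 0, 2L, 1L)
    unmapped <- bitwAnd(res$flag, 4L) > 0
    width <- GenomicAlignments_width(res$cigar, res$qwidth)
    data.frame(read_id = res$qname, mate = mate,
               mapq = ifelse(unmapped, NA, res$mapq),
               chrom = as.character(res$rname),
               start = res$pos - 1, end = res$pos - 1 + width,
               unmapped = unmapped, stringsAsFactors = FALSE)
  }
  tg <- scan1(target_path)
  ct <- scan1(contam_path)
  tg <- tg[!tg$unmapped, , drop = FALSE]
  key_t <- paste(tg$read_id, tg$mate)
  key_c <- paste(ct$read_id, ct$mate)
  m <- match(key_t, key_c)
  data.frame(read_id = tg$read_id, mate = tg$mate,
             target_mapq = tg$mapq,
             contam_mapq = ifelse(is.na(m), NA, ct$mapq[m]),
             target_chrom = tg$chrom,
             target_start = tg$start, target_end = tg$end,
             stringsAsFactors = FALSE)
}

# reference-space width from CIGAR; falls back to query width when CIGAR "*".
GenomicAlignments_width <- function(cigar, qwidth) {
  out <- suppressWarnings(
    GenomicAlignments::cigarWidthAlongReferenceSpace(cigar))
  ifelse(is.na(out), qwidth, out)
}

#' Read a pre-joined dual-alignment TSV
#'
#' Tab-separated with header; columns as in
#' \code{\link{read_dual_alignments}}. Absent MAPQs may be empty, "NA" or ".".
#'
#' @param path path to the TSV.
#' @return dual-alignment data.frame.
#' @export
read_dual_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", "."))
  need <- c("read_id", "mate", "target_mapq", "contam_mapq",
            "target_chrom", "target_start", "target_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("dual-alignment TSV missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Filter contaminant and low-quality reads
#'
#' Applies the two-step cleanup to a dual-alignment table: (1) reads that
#' align better to the contaminant genome than to the target genome
#' (\code{contam_mapq > target_mapq}, absent MAPQ treated as 0) are removed
#' as contamination; (2) surviving reads must clear the target-genome MAPQ
#' floor (\code{target_mapq > mapq_floor}). Equal MAPQs keep the read:
#' only a strictly better contaminant alignment is evidence of
#' contamination. Filtering is per mate; a pair with one contaminant mate
#' keeps the clean mate.
#'
#' Reads unmapped in the target genome (no \code{target_mapq}) are dropped
#' before any accounting. Malformed records (negative MAPQ, or
#' \code{target_end <= target_start}) are rejected with a per-record
#' diagnostic attached to the result, never silently dropped.
#'
#' @param alignments dual-alignment data.frame
#'   (\code{\link{read_dual_alignments}} / \code{\link{read_dual_tsv}}).
#' @param mapq_floor minimum target MAPQ, exclusive (default 20: only
#'   alignments with MAPQ > 20 are kept).
#' @return list with \code{kept} (the filtered data.frame), \code{stats}
#'   (one-row data.frame: \code{n_input}, \code{n_contaminant_removed},
#'   \code{n_lowq_removed}, \code{n_kept}, \code{pct_contaminant},
#'   \code{pct_target}) and \code{rejected} (malformed records with a
#'   \code{reason} column).
#' @export
filter_contaminant_reads <- function(alignments, mapq_floor = 20) {
  al <- alignments
  # drop target-unmapped reads before stats: nothing to place on the genome
  al <- al[!is.na(al$target_mapq), , drop = FALSE]
  bad_mapq <- al$target_mapq < 0 |
    (!is.na(al$contam_mapq) & al$contam_mapq < 0)
  bad_coord <- !is.na(al$target_start) & !is.na(al$target_end) &
    al$target_end <= al$target_start
  bad <- bad_mapq | bad_coord
  rejected <- al[bad, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- ifelse(bad_mapq[bad], "negative MAPQ",
                              "end <= start")
    warning(nrow(rejected), " malformed dual-alignment record(s) rejected")
  }
  al <- al[!bad, , drop = FALSE]

  contam <- ifelse(is.na(al$contam_mapq), 0, al$contam_mapq)
  is_contam <- contam > al$target_mapq
  is_lowq <- !is_contam & al$target_mapq <= mapq_floor
  keep <- !is_contam & !is_lowq

  n_input <- nrow(al)
  stats <- data.frame(
    n_input = n_input,
    n_contaminant_removed = sum(is_contam),
    n_lowq_removed = sum(is_lowq),
    n_kept = sum(keep),
    pct_contaminant = if (n_input) 100 * sum(is_contam) / n_input else 0,
    pct_target = if (n_input) 100 * sum(keep) / n_input else 0)
  list(kept = al[keep, , drop = FALSE], stats = stats, rejected = rejected)
}

#' Kept reads as plain intervals
#'
#' Convenience accessor turning a filtered dual-alignment table into the
#' (chrom, start, end) intervals consumed by
#' \code{\link{merge_reads_to_positions}}.
#'
#' @param kept data.frame of kept dual alignments.
#' @return data.frame with \code{chrom}, \code{start}, \code{end}.
#' @export
alignments_to_intervals <- function(kept) {
  data.frame(chrom = kept$target_chrom,
             start = kept$target_start, end = kept$target_end,
             stringsAsFactors = FALSE)
}
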