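# Synthetic DOP-PCR chromosome-sequencing experiments with known truth.
#
# The generative model: amplicon start sites are a Poisson process along
# the genome — dense (target_rate per kbp) inside the truth regions minus
# their planted deletions, sparse (background_rate per kbp) elsewhere, and
# absent inside assembly gaps. Each amplicon has a length drawn from a
# two-component normal mixture (the short peak from fragmented amplicons,
# the long peak from intact ones) and emits one read pair; a configurable
# fraction of reads is marked as human contamination by giving the
# contaminant-genome alignment the higher mapping quality. Variants are
# planted only within amplicon footprints so that density accounting is
# exactly recoverable from the truth.

#' Configuration of a synthetic DOP-PCR experiment
#'
#' Defaults emulate the empirical picture from flow-sorted chromosome
#' libraries: about one amplicon per 2 kbp inside target regions versus one
#' per 40 kbp background, amplicon lengths bimodal around 100 bp and
#' 190 bp, and a percent-scale human contamination fraction.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param truth_regions data.frame (\code{chrom}, \code{start}, \code{end})
#'   of regions present on the sampled chromosome.
#' @param target_rate amplicons per kbp inside regions (default 0.5).
#' @param background_rate amplicons per kbp elsewhere (default 0.025).
#' @param length_mixture list with \code{mean}, \code{sd}, \code{weight}
#'   vectors for the amplicon-length mixture (defaults 100/190 +/- 10 bp,
#'   equal weights).
#' @param contamination_fraction fraction of reads aligning better to the
#'   contaminant genome (default 0.02).
#' @param planted_deletions data.frame of intervals inside truth regions
#'   with no amplicons (default none).
#' @param assembly_gaps data.frame of unmappable intervals (default none).
#' @param variant_rate variants per bp of amplicon footprint, named vector
#'   with elements \code{target} and \code{background} (defaults 1/300 and
#'   1/1000).
#' @param het_fraction fraction of heterozygous variants, same names
#'   (defaults 0.6 and 0.33).
#' @param read_length sequencing read length in bp (default 150).
#' @param seed integer seed.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(chrom_lengths, truth_regions,
                       target_rate = 0.5, background_rate = 0.025,
                       length_mixture = list(mean = c(100, 190),
                                             sd = c(10, 10),
                                             weight = c(0.5, 0.5)),
                       contamination_fraction = 0.02,
                       planted_deletions = NULL, assembly_gaps = NULL,
                       variant_rate = c(target = 1 / 300,
                                        background = 1 / 1000),
                       het_fraction = c(target = 0.6, background = 0.33),
                       read_length = 150, seed = 1L) {
  stopifnot(target_rate >= 0, background_rate >= 0,
            contamination_fraction >= 0, contamination_fraction <= 1,
            abs(sum(length_mixture$weight) - 1) < 1e-9)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
  if (is.null(planted_deletions)) planted_deletions <- empty
  if (is.null(assembly_gaps)) assembly_gaps <- empty
  check_inside <- function(iv, what) {
    if (nrow(iv) == 0) return()
    len <- chrom_lengths[iv$chrom]
    if (any(is.na(len)) || any(iv$end > len) || any(iv$start < 0))
      stop(what, " outside chromosome bounds")
  }
  check_inside(truth_regions, "truth region")
  check_inside(assembly_gaps, "assembly gap")
  if (nrow(planted_deletions)) {
    inside <- suppressWarnings(IRanges::overlapsAny(
      as_granges(planted_deletions), as_granges(truth_regions),
      type = "within"))
    if (!all(inside)) stop("planted deletions must lie inside truth regions")
  }
  structure(list(chrom_lengths = chrom_lengths,
                 truth_regions = truth_regions,
                 target_rate = target_rate,
                 background_rate = background_rate,
                 length_mixture = length_mixture,
                 contamination_fraction = contamination_fraction,
                 planted_deletions = planted_deletions,
                 assembly_gaps = assembly_gaps,
                 variant_rate = variant_rate,
                 het_fraction = het_fraction,
                 read_length = read_length,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# complement of (regions ∪ gaps) per chromosome, as a data.frame
interval_complement <- function(iv, chrom_lengths) {
  all_gr <- GenomicRanges::GRanges(
    names(chrom_lengths), IRanges::IRanges(1, chrom_lengths))
  sub <- if (nrow(iv)) GenomicRanges::setdiff(
    all_gr, GenomicRanges::reduce(as_granges(iv))) else all_gr
  granges_to_df(sub)
}

# Poisson process at `rate` per kbp over a set of intervals
draw_amplicon_starts <- function(iv, rate) {
  if (nrow(iv) == 0 || rate <= 0)
    return(iv[integer(0), c("chrom", "start"), drop = FALSE])
  n <- stats::rpois(nrow(iv), rate * (iv$end - iv$start) / 1000)
  idx <- rep(seq_len(nrow(iv)), n)
  if (length(idx) == 0)
    return(iv[integer(0), c("chrom", "start"), drop = FALSE])
  data.frame(chrom = iv$chrom[idx],
             start = floor(iv$start[idx] +
                             stats::runif(length(idx)) *
                             (iv$end[idx] - iv$start[idx])),
             stringsAsFactors = FALSE)
}

#' Simulate a DOP-PCR chromosome-sequencing experiment
#'
#' @param cfg \code{\link{sim_config}}.
#' @return list with \code{dual_alignments} (the read-pair alignment table
#'   consumed by \code{\link{filter_contaminant_reads}}), \code{amplicons}
#'   (true amplicon intervals, BED coords, with a \code{compartment}
#'   column) and \code{truth} (list: \code{regions}, \code{deletions},
#'   \code{gaps}, \code{variants}).
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  reg <- cfg$truth_regions
  # target compartment: regions minus planted deletions (and gaps)
  tgt_iv <- granges_to_df(GenomicRanges::setdiff(
    GenomicRanges::reduce(as_granges(reg)),
    GenomicRanges::reduce(as_granges(rbind(cfg$planted_deletions,
                                           cfg$assembly_gaps)))))
  bg_iv <- interval_complement(rbind(reg, cfg$assembly_gaps),
                               cfg$chrom_lengths)
  tgt <- draw_amplicon_starts(tgt_iv, cfg$target_rate)
  bg <- draw_amplicon_starts(bg_iv, cfg$background_rate)
  tgt$compartment <- rep("target", nrow(tgt))
  bg$compartment <- rep("background", nrow(bg))
  amp <- rbind(tgt, bg)
  if (nrow(amp) == 0)
    stop("simulation produced no amplicons; raise the rates")
  comp <- sample.int(length(cfg$length_mixture$weight), nrow(amp),
                     replace = TRUE, prob = cfg$length_mixture$weight)
  len <- pmax(50, round(stats::rnorm(nrow(amp),
                                     cfg$length_mixture$mean[comp],
                                     cfg$length_mixture$sd[comp])))
  amp$end <- pmin(amp$start + len, cfg$chrom_lengths[amp$chrom])
  amp <- amp[order(amp$chrom, amp$start), , drop = FALSE]
  rownames(amp) <- NULL

  # one read pair per amplicon
  rl <- cfg$read_length
  n <- nrow(amp)
  r1_end <- pmin(amp$start + rl, amp$end)
  r2_start <- pmax(amp$end - rl, amp$start)
  contam <- stats::runif(2 * n) < cfg$contamination_fraction
  target_mapq <- sample(21:42, 2 * n, replace = TRUE)
  contam_mapq <- ifelse(contam, pmin(60, target_mapq + sample(1:20, 2 * n,
                                                              replace = TRUE)),
                        ifelse(stats::runif(2 * n) < 0.3,
                               sample(0:20, 2 * n, replace = TRUE), NA))
  dual <- data.frame(
    read_id = rep(sprintf("amp%06d", seq_len(n)), each = 2),
    mate = rep(1:2, n),
    target_mapq = target_mapq,
    contam_mapq = contam_mapq,
    target_chrom = rep(amp$chrom, each = 2),
    target_start = as.vector(rbind(amp$start, r2_start)),
    target_end = as.vector(rbind(r1_end, amp$end)),
    stringsAsFactors = FALSE)

  truth_variants <- plant_variants(amp, cfg)
  list(dual_alignments = dual,
       amplicons = amp,
       truth = list(regions = reg, deletions = cfg$planted_deletions,
                    gaps = cfg$assembly_gaps, variants = truth_variants))
}

# Variants only within amplicon footprints, per-compartment rates.
plant_variants <- function(amp, cfg) {
  rows <- list()
  for (cmp in c("target", "background")) {
    a <- amp[amp$compartment == cmp, , drop = FALSE]
    if (nrow(a) == 0) next
    rate <- cfg$variant_rate[[cmp]]
    nv <- stats::rpois(nrow(a), rate * (a$end - a$start))
    idx <- rep(seq_len(nrow(a)), nv)
    if (length(idx) == 0) next
    pos0 <- floor(a$start[idx] + stats::runif(length(idx)) *
                    (a$end[idx] - a$start[idx]))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, length(idx), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    rows[[length(rows) + 1]] <- data.frame(
      chrom = a$chrom[idx], pos = pos0 + 1, ref = ref, alt = alt,
      zygosity = ifelse(stats::runif(length(idx)) <
                          cfg$het_fraction[[cmp]], "het", "hom"),
      depth = 1 + stats::rpois(length(idx), 3),
      compartment = cmp, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      zygosity = character(), depth = numeric(),
                      compartment = character(), stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive amplicon intervals from primer-motif positions in a sequence
#'
#' The DOP primer anchors at its fixed 3' hexamer, so candidate amplicons
#' run between an occurrence of the motif on the plus strand and a
#' downstream inward-facing occurrence on the minus strand (the reverse
#' complement of the motif). Every inward-facing pair whose span lies in
#' \code{[min_len, max_len]} yields one amplicon; the result is
#' deterministic given the sequence.
#'
#' @param sequences \code{Biostrings::DNAStringSet} (named by chromosome)
#'   or a single \code{DNAString}/character string (then named "seq").
#' @param primer_3prime the fixed 3' hexamer (default "ATGTGG").
#' @param min_len,max_len allowed amplicon span in bp (defaults 50, 2000).
#' @return data.frame of amplicon intervals (\code{chrom}, \code{start},
#'   \code{end}, BED coords), sorted.
#' @export
simulate_motif_amplicons <- function(sequences, primer_3prime = "ATGTGG",
                                     min_len = 50, max_len = 2000) {
  if (is.character(sequences) || methods::is(sequences, "DNAString"))
    sequences <- Biostrings::DNAStringSet(stats::setNames(
      as.character(sequences), "seq"))
  motif <- Biostrings::DNAString(primer_3prime)
  rc <- Biostrings::reverseComplement(motif)
  rows <- list()
  for (nm in names(sequences)) {
    seqc <- sequences[[nm]]
    plus <- Biostrings::start(Biostrings::matchPattern(motif, seqc))
    minus_end <- Biostrings::end(Biostrings::matchPattern(rc, seqc))
    for (p in plus) {
      ends <- minus_end[minus_end - p + 1 >= min_len &
                          minus_end - p + 1 <= max_len]
      if (length(ends))
        rows[[length(rows) + 1]] <- data.frame(
          chrom = nm, start = p - 1, end = ends, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
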