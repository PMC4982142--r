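# Bundled example data: region, deletion and gene-flag tables for the two
# published flow-sorted B-chromosome datasets (Siberian roe deer and grey
# brocket deer, coordinates on the bosTau7 cattle assembly), plus builders
# that turn count tables and flag tables into concrete synthetic objects
# the package functions can run on.
#
# Gene coordinates are NOT part of the bundled tables (only the reported
# completeness flags are); example_gene_models() places synthetic intervals
# consistent with those flags, and the brocket deletion table is likewise a
# synthetic placement (10 deletions totalling 1.03 Mbp) — both are labelled
# synthetic in their filenames.

dopseg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "dopseg")
  if (path == "") stop("bundled file not found: ", file)
  path
}

#' Bundled example B-chromosome region tables
#'
#' Region coordinates (cattle bosTau7 assembly) reported for B chromosomes
#' of the Siberian roe deer (2 regions) and the grey brocket deer
#' (26 regions).
#'
#' @param dataset \code{"roe"} or \code{"brocket"}.
#' @return data.frame \code{chrom}, \code{start}, \code{end}.
#' @export
example_b_regions <- function(dataset = c("roe", "brocket")) {
  dataset <- match.arg(dataset)
  read_bed(dopseg_extdata(paste0(dataset, "_b_regions.bed")))
}

#' Bundled example putative-deletion tables
#'
#' For the roe-deer dataset these are the two reported uncovered stretches
#' inside the chr3 region (coordinates as printed, 0.01-Mbp precision).
#' For the brocket dataset the individual coordinates were not reported —
#' only "10 putative deletions totalling 1.03 Mbp" — so the bundled table
#' is a synthetic placement of 10 deletions of 103 kbp inside the larger
#' regions, consistent with that summary.
#'
#' @param dataset \code{"roe"} or \code{"brocket"}.
#' @return data.frame \code{chrom}, \code{start}, \code{end}.
#' @export
example_b_deletions <- function(dataset = c("roe", "brocket")) {
  dataset <- match.arg(dataset)
  file <- if (dataset == "roe") "roe_b_deletions.bed"
  else "brocket_b_deletions_synthetic.bed"
  read_bed(dopseg_extdata(file))
}

#' Bundled gene completeness flags
#'
#' Gene lists per region with their reported completeness flags:
#' \code{""} complete, \code{"(f)"} partial at a region margin,
#' \code{"(f?)"} overlapping a putative deletion.
#'
#' @param dataset \code{"roe"} or \code{"brocket"}.
#' @return data.frame \code{region}, \code{gene_id}, \code{flag}.
#' @export
example_gene_flags <- function(dataset = c("roe", "brocket")) {
  dataset <- match.arg(dataset)
  df <- utils::read.table(dopseg_extdata(paste0(dataset, "_b_gene_flags.tsv")),
                          sep = "\t", header = TRUE, fill = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  df$flag[is.na(df$flag)] <- ""
  df
}

#' Synthetic gene spans consistent with a flag table
#'
#' Places one synthetic interval per flagged gene: complete genes inside
#' their region clear of deletions, \code{"(f)"} genes crossing a region
#' margin (alternating start/end margins within a region), \code{"(f?)"}
#' genes inside the region overlapping one of its deletions. The output is
#' suitable for \code{\link{annotate_genes}}; recovering the flag counts
#' from these spans exercises the classification rules end to end.
#'
#' @param regions region table (\code{chrom}, \code{start}, \code{end}).
#' @param flags flag table (\code{\link{example_gene_flags}}).
#' @param deletions deletion table; required when flags contain
#'   \code{"(f?)"}.
#' @param gene_length synthetic gene length in bp (default 5000).
#' @return data.frame of gene spans: \code{chrom}, \code{start},
#'   \code{end}, \code{gene_id}, \code{strand}.
#' @export
synthetic_gene_spans <- function(regions, flags, deletions = NULL,
                                 gene_length = 5000) {
  if (is.null(deletions))
    deletions <- data.frame(chrom = character(), start = numeric(),
                            end = numeric())
  regions$region <- paste0(regions$chrom, ":", regions$start, "-",
                           regions$end)
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    reg <- regions[r, ]
    fl <- flags[flags$region == reg$region, , drop = FALSE]
    if (nrow(fl) == 0) next
    del <- deletions[deletions$chrom == reg$chrom &
                       deletions$start >= reg$start &
                       deletions$end <= reg$end, , drop = FALSE]
    del <- del[order(del$start), , drop = FALSE]
    # free space inside the region, away from margins and deletions
    pad <- min(20000, floor((reg$end - reg$start) / 10))
    free <- GenomicRanges::setdiff(
      as_granges(data.frame(chrom = reg$chrom, start = reg$start + pad,
                            end = reg$end - pad)),
      if (nrow(del)) GenomicRanges::reduce(as_granges(del))
      else GenomicRanges::GRanges())
    freedf <- granges_to_df(free)
    freedf <- freedf[freedf$end - freedf$start > 3 * gene_length, ,
                     drop = FALSE]
    n_margin <- 0
    n_del <- 0
    n_complete <- 0
    complete_ids <- fl$gene_id[fl$flag == ""]
    # spread complete genes evenly over the free chunks
    slots <- list()
    if (length(complete_ids)) {
      per_chunk <- ceiling(length(complete_ids) / nrow(freedf))
      for (cki in seq_len(nrow(freedf))) {
        ck <- freedf[cki, ]
        at <- seq(ck$start + gene_length,
                  ck$end - 2 * gene_length,
                  length.out = per_chunk + 1)[seq_len(per_chunk)]
        for (a in at) slots[[length(slots) + 1]] <- floor(a)
      }
    }
    for (i in seq_len(nrow(fl))) {
      g <- fl[i, ]
      if (g$flag == "(f)") {
        n_margin <- n_margin + 1
        half <- floor(gene_length / 2)
        if (n_margin %% 2 == 1) {
          start <- reg$end - half; end <- reg$end + half
        } else {
          start <- reg$start - half; end <- reg$start + half
        }
      } else if (g$flag == "(f?)") {
        if (nrow(del) == 0)
          stop("flag (f?) for ", g$gene_id, " but no deletion in ",
               reg$region)
        n_del <- n_del + 1
        d <- del[1 + (n_del - 1) %% nrow(del), ]
        start <- d$start - floor(gene_length / 2)  # straddles the deletion
        end <- start + gene_length
      } else {
        n_complete <- n_complete + 1
        if (n_complete > length(slots))
          stop("no room for complete gene ", g$gene_id, " in ", reg$region)
        start <- slots[[n_complete]]
        end <- start + gene_length
      }
      rows[[length(rows) + 1]] <- data.frame(
        chrom = reg$chrom, start = start, end = end, gene_id = g$gene_id,
        strand = "+", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bundled variant accounting tables
#'
#' The covered-length table (bp per feature category per sample), the
#' variant count table (total and heterozygous calls per category), and
#' the novelty count ladder (depth filter, total, novel) reported for the
#' four chromosome-specific callsets: BTAMix (cattle autosome control),
#' CPYB (roe-deer B), CPYB-CCA (roe-deer B minus European roe deer
#' variants), MGOB (brocket B).
#'
#' @return list of data.frames \code{sizes}, \code{counts},
#'   \code{novelty}.
#' @export
example_variant_tables <- function() {
  list(sizes = read_tsv(dopseg_extdata("variant_table_sizes.tsv")),
       counts = read_tsv(dopseg_extdata("variant_table_counts.tsv")),
       novelty = read_tsv(dopseg_extdata("variant_novelty_counts.tsv")))
}

#' Build a synthetic callset realizing a count table
#'
#' Expands per-category (all, het) variant counts into a concrete variant
#' table with one row per variant, effects and zygosity set so that every
#' category count is met exactly. Positions are placed on a dummy
#' chromosome; only the counts matter to the density / ratio / novelty
#' accounting that consumes the result.
#'
#' @param counts data.frame with \code{category}, \code{n_all},
#'   \code{n_het} (the \code{total} row, being a different accounting
#'   margin when annotations overlap, is ignored here).
#' @param chrom chromosome name for the dummy coordinates.
#' @return variant table (chrom, pos, ref, alt, zygosity, depth, effect).
#' @export
callset_from_counts <- function(counts, chrom = "chrU") {
  counts <- counts[counts$category != "total", , drop = FALSE]
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$n_all[i]
    if (n == 0) return(NULL)
    data.frame(effect = counts$category[i],
               zygosity = rep(c("het", "hom"),
                              c(counts$n_het[i], n - counts$n_het[i])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      zygosity = character(), depth = numeric(),
                      effect = character(), stringsAsFactors = FALSE))
  data.frame(chrom = chrom, pos = seq_len(nrow(out)) * 10,
             ref = "A", alt = "G", zygosity = out$zygosity,
             depth = 10, effect = out$effect, stringsAsFactors = FALSE)
}

#' Synthetic genome layouts with the published region size spectra
#'
#' Desk-scale genome layouts for simulation studies: each bundled region is
#' kept at its published size but placed on its own synthetic chromosome
#' with \code{flank} bp on either side, so the target/background geometry
#' (2 regions of 1.94 Mbp and 41 kbp for \code{"roe"}; 26 regions of
#' 23 kbp to 1.83 Mbp for \code{"brocket"}) is preserved while the total
#' genome stays small enough for repeated runs.
#'
#' @param dataset \code{"roe"} or \code{"brocket"}.
#' @param flank background flank per side in bp (default 3 Mbp).
#' @return list with \code{chrom_lengths} (named vector) and
#'   \code{regions} (data.frame \code{chrom}, \code{start}, \code{end}).
#' @export
synthetic_truth_layout <- function(dataset = c("roe", "brocket"),
                                   flank = 3e6) {
  dataset <- match.arg(dataset)
  reg <- example_b_regions(dataset)
  size <- reg$end - reg$start
  chrom <- sprintf("sim%02d", seq_along(size))
  regions <- data.frame(chrom = chrom, start = flank, end = flank + size,
                        stringsAsFactors = FALSE)
  list(chrom_lengths = stats::setNames(size + 2 * flank, chrom),
       regions = regions)
}
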