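# Independent oracles used to freeze expected values: deliberately naive
# implementations, kept separate from the package code paths they check.

# pairwise-overlap-closure union of intervals (book-ended count as joined)
oracle_merge <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    iv <- df[df$chrom == ch, , drop = FALSE]
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    cur_s <- iv$start[1]; cur_e <- iv$end[1]; cur_n <- 1L
    if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
      if (iv$start[i] <= cur_e) {  # overlap or book-ended
        cur_e <- max(cur_e, iv$end[i]); cur_n <- cur_n + 1L
      } else {
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = cur_s,
                                             end = cur_e, read_count = cur_n)
        cur_s <- iv$start[i]; cur_e <- iv$end[i]; cur_n <- 1L
      }
    }
    out[[length(out) + 1]] <- data.frame(chrom = ch, start = cur_s,
                                         end = cur_e, read_count = cur_n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# exhaustive max arc statistic over all boundary pairs; leftmost tie-break
oracle_max_arc <- function(x, min_width) {
  n <- length(x)
  best <- list(stat = -Inf, i = NA, j = NA)
  if (n < 2 * min_width) return(best)
  for (i in 0:(n - min_width)) {
    for (j in (i + min_width):min(n, i + n - min_width)) {
      k <- j - i
      m_in <- mean(x[(i + 1):j])
      m_out <- (sum(x) - sum(x[(i + 1):j])) / (n - k)
      stat <- abs(m_in - m_out) / sqrt(1 / k + 1 / (n - k))
      if (stat > best$stat + 1e-9) best <- list(stat = stat, i = i, j = j)
    }
  }
  best
}

# random interval table on a few chromosomes
random_intervals <- function(n, chroms = c("chrA", "chrB", "chrC"),
                             max_pos = 1e5, max_len = 500) {
  start <- floor(runif(n, 0, max_pos))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + 1 + floor(runif(n, 0, max_len)),
             stringsAsFactors = FALSE)
}

# dual-alignment table with prescribed contaminant / low-quality makeup
make_dual_table <- function(n_clean, n_contam, n_lowq, chrom = "chr1") {
  n <- n_clean + n_contam + n_lowq
  target_mapq <- c(sample(21:42, n_clean, replace = TRUE),
                   sample(21:42, n_contam, replace = TRUE),
                   sample(0:20, n_lowq, replace = TRUE))
  contam_mapq <- c(sample(c(NA, 0:20), n_clean, replace = TRUE),
                   60 + integer(n_contam),
                   rep(0L, n_lowq))
  start <- seq_len(n) * 1000
  data.frame(read_id = sprintf("r%05d", seq_len(n)), mate = 1L,
             target_mapq = target_mapq, contam_mapq = contam_mapq,
             target_chrom = chrom, target_start = start,
             target_end = start + 150, stringsAsFactors = FALSE)
}

# gene-model object with one plus-strand gene; coordinates are BED-style
simple_gene <- function(gene_id, chrom, cds, utr5 = NULL, utr3 = NULL,
                        strand = "+") {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  blocks <- function(m) if (is.null(m)) empty else
    data.frame(chrom = chrom, start = m[, 1], end = m[, 2])
  ex <- rbind(blocks(cds), blocks(utr5), blocks(utr3))
  gene_models(list(list(gene_id = gene_id, chrom = chrom, strand = strand,
                        exons = ex, cds = blocks(cds),
                        utr5 = blocks(utr5), utr3 = blocks(utr3))))
}

# region table in call_regions shape from plain intervals
as_region_calls <- function(df) {
  df$region_id <- paste0(df$chrom, ":", df$start, "-", df$end)
  df$label <- "target"
  df
}

# assign each deletion the region_id of its containing region
deletions_with_region_ids <- function(deletions, regions) {
  regions <- as_region_calls(regions[c("chrom", "start", "end")])
  idx <- vapply(seq_len(nrow(deletions)), function(i) {
    hit <- which(regions$chrom == deletions$chrom[i] &
                   regions$start <= deletions$start[i] &
                   regions$end >= deletions$end[i])
    hit[1]
  }, integer(1))
  cbind(region_id = regions$region_id[idx], deletions,
        stringsAsFactors = FALSE)
}
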