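# Variant accounting on the covered fraction of target regions: callset
# subtraction, covered feature sizes, bp-per-variant densities,
# heterozygosity, novelty against a known-variant set, and a lightweight
# effect classifier.
#
# A variant table ("callset") is a data.frame with columns chrom, pos
# (1-based), ref, alt, and optionally zygosity ("het"/"hom") and depth, as
# produced by read_vcf_variants() or the simulator.

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = "\r")

#' Subtract one callset from another
#'
#' Returns the variants of \code{a} that are absent from \code{b}, matched
#' exactly on (chrom, pos, ref, alt); zygosity and depth are carried from
#' \code{a}. The typical use is removing species-level divergence (variants
#' also seen in a sister genome) to leave the variants private to the
#' sampled chromosome.
#'
#' @param a,b variant tables on the same reference coordinates.
#' @return the rows of \code{a} not matched in \code{b}.
#' @export
subtract_callsets <- function(a, b) {
  if (nrow(b)) {
    common <- intersect(unique(a$chrom), unique(b$chrom))
    if (length(common) == 0 && nrow(a))
      stop("no shared contig names between callsets; a has {",
           paste(utils::head(unique(a$chrom), 5), collapse = ", "),
           "}, b has {",
           paste(utils::head(unique(b$chrom), 5), collapse = ", "), "}")
  }
  out <- a[!(variant_key(a) %in% variant_key(b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Covered sequence length per gene-feature category
#'
#' Intersects the read-covered intervals with gene features and reports the
#' covered bp per category. Overlapping annotations resolve by precedence
#' coding > UTR > intron > intergenic, so the categories partition the
#' covered length exactly.
#'
#' @param covered_intervals data.frame (\code{chrom}, \code{start},
#'   \code{end}) of read-covered intervals (e.g. DOP-positions inside the
#'   target regions).
#' @param models \code{\link{gene_models}} object.
#' @return one-row data.frame: \code{total}, \code{intergenic},
#'   \code{intron}, \code{utr5}, \code{utr3}, \code{coding} (all bp).
#' @export
covered_feature_sizes <- function(covered_intervals, models) {
  zero <- data.frame(total = 0, intergenic = 0, intron = 0,
                     utr5 = 0, utr3 = 0, coding = 0)
  if (nrow(covered_intervals) == 0) return(zero)
  cov <- GenomicRanges::reduce(as_granges(covered_intervals))
  total <- sum(IRanges::width(cov))
  feat <- gene_feature_table(models)
  remaining <- cov
  sizes <- c(coding = 0, utr5 = 0, utr3 = 0, intron = 0)
  for (cls in list(c("coding", "cds"), c("utr5", "utr5"),
                   c("utr3", "utr3"), c("intron", "intron"))) {
    f <- feat[feat$type == cls[2], , drop = FALSE]
    if (nrow(f) == 0) next
    fg <- GenomicRanges::reduce(as_granges(f))
    hit <- GenomicRanges::intersect(remaining, fg)
    sizes[cls[1]] <- sum(IRanges::width(hit))
    remaining <- GenomicRanges::setdiff(remaining, fg)
  }
  data.frame(total = total,
             intergenic = total - sum(sizes),
             intron = unname(sizes["intron"]),
             utr5 = unname(sizes["utr5"]),
             utr3 = unname(sizes["utr3"]),
             coding = unname(sizes["coding"]))
}

#' Variant density (bp per 1 variant) per category
#'
#' Density is the covered length of a category divided by the number of
#' called variants in it, rounded to the nearest integer; the bracketed
#' companion uses heterozygous variants only. A category with no variants
#' has undefined density (reported as \code{NA}, printed as "-").
#'
#' @param sizes \code{\link{covered_feature_sizes}} row. The \code{coding}
#'   length serves both coding categories when variants carry the
#'   syn/nonsyn split.
#' @param variants variant table with an \code{effect} column
#'   (\code{intergenic}, \code{intron}, \code{utr5}, \code{utr3},
#'   \code{coding_syn}, \code{coding_nonsyn}) and \code{zygosity}.
#' @return data.frame with one row per category (\code{total},
#'   \code{intergenic}, \code{intron}, \code{utr5}, \code{utr3},
#'   \code{coding}): covered bp, variant counts and integer densities
#'   \code{density_all}, \code{density_het}.
#' @export
variant_density <- function(sizes, variants) {
  if (sizes$total <= 0) stop("sizes$total must be positive")
  eff <- variants$effect
  cats <- list(total = c("intergenic", "intron", "utr5", "utr3",
                         "coding_syn", "coding_nonsyn"),
               intergenic = "intergenic", intron = "intron",
               utr5 = "utr5", utr3 = "utr3",
               coding = c("coding_syn", "coding_nonsyn"))
  rows <- lapply(names(cats), function(nm) {
    sel <- if (nm == "total") rep(TRUE, nrow(variants)) else eff %in% cats[[nm]]
    n_all <- sum(sel)
    n_het <- sum(sel & variants$zygosity == "het")
    bp <- sizes[[nm]]
    data.frame(category = nm, bp = bp, n_all = n_all, n_het = n_het,
               density_all = if (n_all > 0) round(bp / n_all) else NA_real_,
               density_het = if (n_het > 0) round(bp / n_het) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heterozygous / homozygous variant ratio
#'
#' @param variants variant table with a \code{zygosity} column.
#' @return the ratio n_het / n_hom, or \code{NA} with a message when there
#'   are no homozygous calls.
#' @export
het_hom_ratio <- function(variants) {
  n_het <- sum(variants$zygosity == "het")
  n_hom <- sum(variants$zygosity == "hom")
  if (n_hom == 0) {
    message("no homozygous variants: het/hom ratio undefined")
    return(NA_real_)
  }
  n_het / n_hom
}

#' Novelty of a callset against a known-variant set
#'
#' Applies the depth filter first, then counts variants absent from the
#' known set (match on chrom, pos, ref, alt). Novel low-depth variants are
#' candidate artifacts, so the percentage is typically inspected across a
#' ladder of \code{min_depth} values.
#'
#' @param variants variant table with \code{depth}.
#' @param known known-variant table (e.g. a dbSNP export); only the keys
#'   are used.
#' @param min_depth minimum depth, inclusive (default 0: no filter).
#' @return one-row data.frame: \code{min_depth}, \code{n_total},
#'   \code{n_novel}, \code{pct_novel}.
#' @export
novelty_stats <- function(variants, known, min_depth = 0) {
  v <- variants[is.na(variants$depth) | variants$depth >= min_depth, ,
                drop = FALSE]
  if (min_depth > 0) v <- v[!is.na(v$depth), , drop = FALSE]
  novel <- !(variant_key(v) %in% variant_key(known))
  data.frame(min_depth = min_depth, n_total = nrow(v),
             n_novel = sum(novel),
             pct_novel = if (nrow(v)) 100 * sum(novel) / nrow(v) else NA_real_)
}

#' Classify variant effects against gene models
#'
#' A lightweight effect classifier: each variant gets one category by the
#' precedence coding > UTR > intron > intergenic. SNVs in coding sequence
#' are translated with and without the alternate allele under the standard
#' genetic code (synonymous vs non-synonymous); indels in coding sequence
#' are non-synonymous regardless of phase (frameshift and in-frame indels
#' are both protein-disrupting here). Variants outside any gene span are
#' intergenic.
#'
#' @param variants variant table.
#' @param models \code{\link{gene_models}} object (one transcript per
#'   gene).
#' @param reference \code{Biostrings::DNAStringSet} named by chromosome;
#'   needed only when coding SNVs are present. A variant whose ref allele
#'   disagrees with the reference sequence is an error.
#' @return the variant table with an \code{effect} column.
#' @export
classify_effect <- function(variants, models, reference = NULL) {
  feat <- gene_feature_table(models)
  spans <- models$spans
  eff <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    p0 <- v$pos - 1  # 0-based position of the first ref base
    at <- function(df) any(df$chrom == v$chrom & df$start <= p0 & df$end > p0)
    f <- feat[feat$chrom == v$chrom & feat$start <= p0 & feat$end > p0, ,
              drop = FALSE]
    if (any(f$type == "cds")) {
      gene <- models$genes[[match(f$gene_id[f$type == "cds"][1],
                                  vapply(models$genes, `[[`, "", "gene_id"))]]
      eff[i] <- classify_cds_variant(v, gene, reference)
    } else if (any(f$type == "utr5")) eff[i] <- "utr5"
    else if (any(f$type == "utr3")) eff[i] <- "utr3"
    else if (any(f$type == "intron")) eff[i] <- "intron"
    else if (at(spans)) eff[i] <- "intron"  # inside a gene span, unannotated
    else eff[i] <- "intergenic"
  }
  variants$effect <- eff
  variants
}

classify_cds_variant <- function(v, gene, reference) {
  if (nchar(v$ref) != nchar(v$alt)) return("coding_nonsyn")  # indel
  if (nchar(v$ref) > 1) return("coding_nonsyn")              # MNV: be strict
  if (is.null(reference))
    stop("coding SNV at ", v$chrom, ":", v$pos,
         " needs a reference sequence for codon lookup")
  cds <- gene$cds[order(gene$cds$start), , drop = FALSE]
  chrom_seq <- reference[[v$chrom]]
  if (is.null(chrom_seq)) stop("chromosome ", v$chrom, " not in reference")
  spliced <- do.call(Biostrings::xscat, lapply(seq_len(nrow(cds)), function(r)
    Biostrings::subseq(chrom_seq, cds$start[r] + 1, cds$end[r])))
  # offset of the variant within the spliced CDS (plus strand order)
  p0 <- v$pos - 1
  block <- which(cds$start <= p0 & cds$end > p0)
  off <- sum(cds$end[seq_len(block - 1)] - cds$start[seq_len(block - 1)]) +
    (p0 - cds$start[block])  # 0-based
  ref_base <- as.character(Biostrings::subseq(spliced, off + 1, off + 1))
  if (!identical(toupper(ref_base), toupper(v$ref)))
    stop("ref allele mismatch at ", v$chrom, ":", v$pos, " (VCF ", v$ref,
         ", reference ", ref_base, ")")
  alt_spliced <- spliced
  alt_spliced <- Biostrings::replaceLetterAt(
    alt_spliced, off + 1, v$alt)
  if (gene$strand == "-") {
    spliced <- Biostrings::reverseComplement(spliced)
    alt_spliced <- Biostrings::reverseComplement(alt_spliced)
  }
  usable <- 3 * (length(spliced) %/% 3)
  aa_ref <- Biostrings::translate(Biostrings::subseq(spliced, 1, usable),
                                  if.fuzzy.codon = "X")
  aa_alt <- Biostrings::translate(Biostrings::subseq(alt_spliced, 1, usable),
                                  if.fuzzy.codon = "X")
  if (as.character(aa_ref) == as.character(aa_alt)) "coding_syn"
  else "coding_nonsyn"
}

#' Variant densities from an externally tabulated count table
#'
#' The same bp-per-variant arithmetic as \code{\link{variant_density}}, but
#' starting from per-category (all, het) counts rather than a flat callset.
#' This is the right entry point when variants were annotated by a
#' multi-category annotator whose per-category counts overlap and therefore
#' do not add up to the total — the total row is then its own count, not a
#' sum.
#'
#' @param sizes one-row data.frame of covered bp per category
#'   (\code{total}, \code{intergenic}, \code{intron}, \code{utr5},
#'   \code{utr3}, \code{coding}).
#' @param counts data.frame with \code{category} (\code{total},
#'   \code{intergenic}, \code{intron}, \code{utr5}, \code{utr3},
#'   \code{coding_syn}, \code{coding_nonsyn}), \code{n_all}, \code{n_het};
#'   the two coding rows pool into the single coding length.
#' @return data.frame as \code{\link{variant_density}}.
#' @export
density_table_from_counts <- function(sizes, counts) {
  get_n <- function(cats, col)
    sum(counts[[col]][counts$category %in% cats])
  cats <- list(total = "total", intergenic = "intergenic",
               intron = "intron", utr5 = "utr5", utr3 = "utr3",
               coding = c("coding_syn", "coding_nonsyn"))
  rows <- lapply(names(cats), function(nm) {
    n_all <- get_n(cats[[nm]], "n_all")
    n_het <- get_n(cats[[nm]], "n_het")
    bp <- sizes[[nm]]
    data.frame(category = nm, bp = bp, n_all = n_all, n_het = n_het,
               density_all = if (n_all > 0) round(bp / n_all) else NA_real_,
               density_het = if (n_het > 0) round(bp / n_het) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
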