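# File readers/writers for the formats the pipeline consumes and emits.
# Interval tables are BED-convention data.frames (0-based half-open).

#' Read a chromosome-sizes table
#'
#' Two-column tab-separated file in the usual \code{chrom.sizes} convention:
#' chromosome name, length in bp.
#'
#' @param path path to the file.
#' @return named integer-ish numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (any(df$length <= 0)) stop("non-positive chromosome length in ", path)
  stats::setNames(df$length, df$chrom)
}

#' Read a BED3+ interval file
#'
#' @param path path to a BED file (no header). Columns beyond the third are
#'   kept under the names given in \code{extra}.
#' @param extra character vector naming columns 4, 5, ... if present.
#' @return data.frame with \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open) and any extra columns.
#' @export
read_bed <- function(path, extra = character()) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  nm <- c("chrom", "start", "end", extra)
  if (ncol(df) < 3) stop("BED file needs >= 3 columns: ", path)
  names(df)[seq_len(min(ncol(df), length(nm)))] <- nm[seq_len(min(ncol(df), length(nm)))]
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  bad <- df$end <= df$start
  if (any(bad)) stop(sum(bad), " BED records with end <= start in ", path)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Write a BED3+ interval table
#'
#' @param df data.frame with \code{chrom}, \code{start}, \code{end} and
#'   optionally further columns, written in order.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# data.frame (BED coords) -> GRanges; 1-based closed internally to IRanges.
as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

# GRanges -> BED-convention data.frame.
granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a variant callset from VCF
#'
#' Reads a VCF 4.x file (plain text or bgzipped) into the flat variant table
#' used throughout the package. Zygosity is taken from the first sample's GT
#' field (het if the two alleles differ), depth from the per-sample DP (or
#' INFO/DP as fallback); both default to \code{NA} when absent.
#'
#' @param path path to a VCF file.
#' @return data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}, \code{zygosity} ("het"/"hom"), \code{depth}.
#' @export
read_vcf_variants <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  # expand multi-allelic records to one row per ALT allele
  n_alt <- S4Vectors::elementNROWS(alt)
  idx <- rep(seq_along(rr), n_alt)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[idx],
    pos = GenomicRanges::start(rr)[idx],
    ref = as.character(VariantAnnotation::ref(vcf))[idx],
    alt = as.character(unlist(alt)),
    stringsAsFactors = FALSE)
  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT[, 1], error = function(e) NULL)
  if (!is.null(gt)) {
    a <- sub("[/|].*", "", gt); b <- sub(".*[/|]", "", gt)
    zyg <- ifelse(a == b, "hom", "het")
    out$zygosity <- zyg[idx]
  } else out$zygosity <- NA_character_
  dp <- tryCatch(VariantAnnotation::geno(vcf)$DP[, 1], error = function(e) NULL)
  if (is.null(dp)) dp <- tryCatch(as.numeric(VariantAnnotation::info(vcf)$DP),
                                  error = function(e) NULL)
  out$depth <- if (is.null(dp)) NA_real_ else as.numeric(dp)[idx]
  rownames(out) <- NULL
  out
}

#' Write a variant table as VCF
#'
#' @param variants data.frame as returned by \code{\link{read_vcf_variants}}.
#' @param path output path (".vcf" for plain text).
#' @param sample_name sample column name for the GT/DP fields.
#' @export
write_vcf_variants <- function(variants, path, sample_name = "sample") {
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  vr <- VariantAnnotation::VRanges(
    seqnames = v$chrom,
    ranges = IRanges::IRanges(start = v$pos, width = nchar(v$ref)),
    ref = v$ref, alt = v$alt,
    totalDepth = if (is.null(v$depth)) NA_integer_ else as.integer(v$depth),
    sampleNames = sample_name)
  vcf <- VariantAnnotation::asVCF(vr)
  zyg <- if (is.null(v$zygosity)) rep(NA_character_, nrow(v)) else v$zygosity
  hdr <- VariantAnnotation::header(vcf)
  VariantAnnotation::geno(hdr) <- rbind(
    VariantAnnotation::geno(hdr),
    S4Vectors::DataFrame(Number = "1", Type = "String",
                         Description = "Genotype", row.names = "GT"))
  VariantAnnotation::header(vcf) <- hdr
  VariantAnnotation::geno(vcf)$GT <- matrix(
    ifelse(is.na(zyg), "./.", ifelse(zyg == "het", "0/1", "1/1")),
    ncol = 1, dimnames = list(NULL, sample_name))
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Read gene models from GFF3 or BED12
#'
#' Builds the internal gene-model object used by gene annotation, covered
#' feature sizing, and effect classification. GFF3 input uses \code{gene},
#' \code{exon}, \code{CDS} and (optionally) \code{five_prime_UTR} /
#' \code{three_prime_UTR} features grouped by gene. BED12 input uses blocks
#' as exons and the thick interval as the CDS span.
#'
#' @param path path to a \code{.gff}/\code{.gff3} or \code{.bed} (BED12) file.
#' @return gene-model object, see \code{\link{gene_models}}.
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    read_gene_models_gff(gr)
  } else if (ext %in% c("bed", "bed12")) {
    gr <- rtracklayer::import(path, format = "bed")
    read_gene_models_bed12(gr)
  } else stop("unrecognized gene model format: ", path)
}

read_gene_models_gff <- function(gr) {
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  gene_of <- function(x) {
    g <- md$gene_id
    if (is.null(g)) g <- md$Parent
    if (is.null(g)) g <- md$ID
    as.character(unlist(lapply(g, function(el) if (length(el)) el[[1]] else NA)))[x]
  }
  keep <- type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  sub <- gr[keep]
  gid <- gene_of(keep)
  # strip transcript suffixes like ".t1" so features group per gene
  gid <- sub("\\.t[0-9]+$", "", gid)
  per_gene <- split(seq_along(sub), gid)
  genes <- lapply(names(per_gene), function(g) {
    ii <- per_gene[[g]]
    ss <- sub[ii]
    ty <- as.character(S4Vectors::mcols(ss)$type)
    list(gene_id = g,
         chrom = as.character(GenomicRanges::seqnames(ss))[1],
         strand = as.character(GenomicRanges::strand(ss))[1],
         exons = granges_to_df(ss[ty == "exon"]),
         cds = granges_to_df(ss[ty == "CDS"]),
         utr5 = granges_to_df(ss[ty == "five_prime_UTR"]),
         utr3 = granges_to_df(ss[ty == "three_prime_UTR"]))
  })
  gene_models(genes)
}

read_gene_models_bed12 <- function(gr) {
  genes <- lapply(seq_along(gr), function(i) {
    g <- gr[i]
    blocks <- S4Vectors::mcols(g)$blocks[[1]]
    ex <- GenomicRanges::shift(GenomicRanges::GRanges(
      GenomicRanges::seqnames(g), blocks), GenomicRanges::start(g) - 1)
    exdf <- granges_to_df(ex)
    th <- S4Vectors::mcols(g)$thick
    cds_start <- IRanges::start(th) - 1; cds_end <- IRanges::end(th)
    cds <- exdf
    cds$start <- pmax(cds$start, cds_start); cds$end <- pmin(cds$end, cds_end)
    cds <- cds[cds$end > cds$start, , drop = FALSE]
    strand <- as.character(GenomicRanges::strand(g))
    utr_left <- exdf; utr_left$end <- pmin(utr_left$end, cds_start)
    utr_left <- utr_left[utr_left$end > utr_left$start, , drop = FALSE]
    utr_right <- exdf; utr_right$start <- pmax(utr_right$start, cds_end)
    utr_right <- utr_right[utr_right$end > utr_right$start, , drop = FALSE]
    list(gene_id = as.character(S4Vectors::mcols(g)$name),
         chrom = as.character(GenomicRanges::seqnames(g)),
         strand = strand,
         exons = exdf,
         cds = cds,
         utr5 = if (strand == "-") utr_right else utr_left,
         utr3 = if (strand == "-") utr_left else utr_right)
  })
  gene_models(genes)
}

#' Construct a gene-model object programmatically
#'
#' @param genes list of per-gene lists with elements \code{gene_id},
#'   \code{chrom}, \code{strand}, and interval data.frames (\code{chrom},
#'   \code{start}, \code{end}; BED coords) \code{exons}, \code{cds},
#'   \code{utr5}, \code{utr3} (any may be empty).
#' @return object of class \code{gene_models}: the list plus a \code{spans}
#'   data.frame (one row per gene: chrom, start, end, gene_id, strand).
#' @export
gene_models <- function(genes) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  genes <- lapply(genes, function(g) {
    for (f in c("exons", "cds", "utr5", "utr3"))
      if (is.null(g[[f]]) || nrow(g[[f]]) == 0) g[[f]] <- empty
    if (is.null(g$strand) || is.na(g$strand) || g$strand == "*") g$strand <- "+"
    g
  })
  spans <- do.call(rbind, lapply(genes, function(g) {
    iv <- rbind(g$exons, g$cds, g$utr5, g$utr3)
    if (nrow(iv) == 0) stop("gene ", g$gene_id, " has no features")
    data.frame(chrom = g$chrom, start = min(iv$start), end = max(iv$end),
               gene_id = g$gene_id, strand = g$strand,
               stringsAsFactors = FALSE)
  }))
  structure(list(genes = genes, spans = spans), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$spans), "genes on",
      length(unique(x$spans$chrom)), "chromosome(s)\n")
  invisible(x)
}

# Flat feature table with one class per bp by precedence cds > utr > intron.
gene_feature_table <- function(models) {
  out <- lapply(models$genes, function(g) {
    rows <- list()
    add <- function(df, type) {
      if (nrow(df)) rows[[length(rows) + 1]] <<-
          cbind(df[c("chrom", "start", "end")], type = type,
                gene_id = g$gene_id, strand = g$strand)
    }
    add(g$cds, "cds"); add(g$utr5, "utr5"); add(g$utr3, "utr3")
    # introns: gaps between exons within the gene span
    ex <- g$exons
    if (nrow(ex) == 0) ex <- rbind(g$cds, g$utr5, g$utr3)[c("chrom", "start", "end")]
    if (nrow(ex) > 1) {
      ex <- ex[order(ex$start), , drop = FALSE]
      red <- IRanges::reduce(IRanges::IRanges(ex$start + 1, ex$end))
      if (length(red) > 1) {
        intr <- data.frame(chrom = g$chrom,
                           start = utils::head(IRanges::end(red), -1),
                           end = utils::tail(IRanges::start(red) - 1, -1),
                           stringsAsFactors = FALSE)
        add(intr, "intron")
      }
    }
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      type = character(), gene_id = character(),
                      strand = character(), stringsAsFactors = FALSE)
  res
}
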