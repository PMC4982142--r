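# Callset subtraction, covered sizes, density/heterozygosity/novelty and
# the effect classifier.

rand_callset <- function(n, chrom = "chr1", max_pos = 1e6) {
  pos <- sample.int(max_pos, n)
  data.frame(chrom = chrom, pos = pos,
             ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
             alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
             zygosity = sample(c("het", "hom"), n, replace = TRUE),
             depth = sample(1:20, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("callset subtraction is exact set difference on the allele key", {
  set.seed(41)
  a <- rand_callset(500)
  expect_equal(nrow(subtract_callsets(a, a)), 0)
  b_disjoint <- rand_callset(100, max_pos = 1e6)
  b_disjoint$pos <- b_disjoint$pos + 2e6
  expect_equal(subtract_callsets(a, b_disjoint), a, ignore_attr = TRUE)

  # B = 200 rows of A plus 100 novel records
  b <- rbind(a[sample(500, 200), c("chrom", "pos", "ref", "alt")],
             within(rand_callset(100), pos <- pos + 5e6)[
               c("chrom", "pos", "ref", "alt")])
  got <- subtract_callsets(a, b)
  expect_equal(nrow(got), 300)
  # oracle: plain set difference on pasted keys
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt)
  expect_setequal(key(got), setdiff(key(a), key(b)))
  # conservation: |A - B| + |A ∩ B| = |A|
  expect_equal(nrow(got) + sum(key(a) %in% key(b)), nrow(a))

  mismatched <- a
  mismatched$chrom <- "scaffold_1"
  expect_error(subtract_callsets(a, mismatched), "contig")
})

test_that("covered feature sizes partition the covered length", {
  gm <- simple_gene("g1", "chr1", cds = rbind(c(5000, 5300)),
                    utr5 = rbind(c(4800, 5000)),
                    utr3 = rbind(c(5300, 5500)))
  # wholly intronic kilobase
  gm2 <- simple_gene("g2", "chr1", cds = rbind(c(1000, 1100),
                                               c(9000, 9100)))
  covered <- data.frame(chrom = "chr1", start = 2000, end = 3000)
  sz <- covered_feature_sizes(covered, gm2)
  expect_equal(sz$intron, 1000)
  expect_equal(sz$total, 1000)
  expect_equal(sz$coding + sz$utr5 + sz$utr3 + sz$intergenic, 0)

  empty <- covered_feature_sizes(
    data.frame(chrom = character(), start = numeric(), end = numeric()), gm)
  expect_equal(unlist(empty), c(total = 0, intergenic = 0, intron = 0,
                                utr5 = 0, utr3 = 0, coding = 0))

  # categories sum to the total under the precedence rule
  covered2 <- data.frame(chrom = "chr1", start = 4500, end = 6000)
  sz2 <- covered_feature_sizes(covered2, gm)
  expect_equal(sz2$coding, 300)
  expect_equal(sz2$utr5, 200)
  expect_equal(sz2$utr3, 200)
  expect_equal(sz2$coding + sz2$utr5 + sz2$utr3 + sz2$intron +
                 sz2$intergenic, sz2$total)
})

test_that("a constructed annotation reproduces the printed covered lengths", {
  # one gene arranged so the covered 6,068,678 bp split exactly as printed
  gm <- simple_gene("mosaic", "chr1",
                    cds = rbind(c(0, 32035), c(1550150, 1550160)),
                    utr5 = rbind(c(32035, 33372)),
                    utr3 = rbind(c(33372, 48585)))
  covered <- data.frame(chrom = "chr1", start = 0, end = 6068678)
  sz <- covered_feature_sizes(covered, gm)
  expect_equal(sz$total, 6068678)
  expect_equal(sz$coding, 32045)
  expect_equal(sz$utr5, 1337)
  expect_equal(sz$utr3, 15213)
  expect_equal(sz$intron, 1501565)
  expect_equal(sz$intergenic, 4518518)
})

test_that("feature sizes are conserved under chromosome splitting", {
  gmA <- simple_gene("gA", "chrA", cds = rbind(c(100, 400)))
  gmB <- simple_gene("gB", "chrB", cds = rbind(c(100, 250)))
  both <- gene_models(c(gmA$genes, gmB$genes))
  covA <- data.frame(chrom = "chrA", start = 0, end = 1000)
  covB <- data.frame(chrom = "chrB", start = 0, end = 1000)
  sz_joint <- covered_feature_sizes(rbind(covA, covB), both)
  sz_split <- covered_feature_sizes(covA, gmA)$coding +
    covered_feature_sizes(covB, gmB)$coding
  expect_equal(sz_joint$coding, sz_split)
})

test_that("densities divide covered bp by variant counts, rounded", {
  sizes <- data.frame(total = 10000, intergenic = 6000, intron = 3000,
                      utr5 = 0, utr3 = 0, coding = 1000)
  v <- rbind(
    data.frame(effect = rep("intergenic", 30),
               zygosity = rep(c("het", "hom"), c(10, 20))),
    data.frame(effect = rep("intron", 9),
               zygosity = rep(c("het", "hom"), c(3, 6))),
    data.frame(effect = rep("coding_nonsyn", 3), zygosity = "het"))
  dt <- variant_density(sizes, v)
  expect_equal(dt$density_all[dt$category == "total"], round(10000 / 42))
  expect_equal(dt$density_all[dt$category == "intergenic"], 200)
  expect_equal(dt$density_het[dt$category == "intron"], 1000)
  expect_equal(dt$density_all[dt$category == "coding"], 333)
  expect_true(is.na(dt$density_all[dt$category == "utr5"]))
  # het density never smaller than all-variant density
  ok <- !is.na(dt$density_het) & !is.na(dt$density_all)
  expect_true(all(dt$density_het[ok] >= dt$density_all[ok]))
  expect_error(variant_density(within(sizes, total <- 0), v), "positive")
})

test_that("the printed density table is reproduced from its count table", {
  tabs <- example_variant_tables()
  dens <- function(sample) {
    density_table_from_counts(
      tabs$sizes[tabs$sizes$sample == sample, ],
      tabs$counts[tabs$counts$sample == sample, ])
  }
  bta <- dens("BTAMix")
  expect_equal(bta$density_all[bta$category == "total"], 316)
  expect_equal(bta$density_het[bta$category == "total"], 952)
  cca <- dens("CPYB-CCA")
  expect_equal(cca$density_all[cca$category == "total"], 96)
  expect_equal(cca$density_het[cca$category == "total"], 154)
  expect_equal(dens("CPYB")$density_all[1], 23)
  expect_equal(dens("MGOB")$density_all[1], 29)
})

test_that("het/hom ratio counts exactly and degrades loudly", {
  counts <- example_variant_tables()$counts
  tot <- counts[counts$sample == "BTAMix" & counts$category == "total", ]
  v <- data.frame(zygosity = rep(c("het", "hom"),
                                 c(tot$n_het, tot$n_all - tot$n_het)))
  expect_equal(round(het_hom_ratio(v), 2), 0.50)
  expect_message(r <- het_hom_ratio(data.frame(zygosity = rep("het", 5))),
                 "undefined")
  expect_true(is.na(r))
  set.seed(42)
  v2 <- data.frame(zygosity = rep(c("het", "hom"), c(300, 200)))
  expect_equal(het_hom_ratio(v2), 1.5)
})

test_that("novelty ladder reproduces the printed counts and percentages", {
  nv <- example_variant_tables()$novelty
  # depth-class construction realizing all three printed rows at once
  n_lo <- nv$n_total[1] - nv$n_total[2]      # depth < 4
  n_mid <- nv$n_total[2] - nv$n_total[3]     # depth 4-5
  n_hi <- nv$n_total[3]                      # depth >= 6
  nov_lo <- nv$n_novel[1] - nv$n_novel[2]
  nov_mid <- nv$n_novel[2] - nv$n_novel[3]
  nov_hi <- nv$n_novel[3]
  n <- n_lo + n_mid + n_hi
  v <- data.frame(chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
                  zygosity = "hom",
                  depth = rep(c(3, 4, 6), c(n_lo, n_mid, n_hi)))
  novel <- c(rep(c(TRUE, FALSE), c(nov_lo, n_lo - nov_lo)),
             rep(c(TRUE, FALSE), c(nov_mid, n_mid - nov_mid)),
             rep(c(TRUE, FALSE), c(nov_hi, n_hi - nov_hi)))
  known <- v[!novel, ]
  for (i in seq_len(nrow(nv))) {
    st <- novelty_stats(v, known, min_depth = nv$min_depth[i])
    expect_equal(st$n_total, nv$n_total[i])
    expect_equal(st$n_novel, nv$n_novel[i])
  }
  expect_equal(round(novelty_stats(v, known, 0)$pct_novel, 1), 64.5)
  expect_lt(abs(novelty_stats(v, known, 0)$pct_novel - 64.4), 0.06)
  # empty known set: everything novel
  expect_equal(novelty_stats(v, known[0, ], 0)$pct_novel, 100)
})

test_that("effect classification translates codons and ranks features", {
  # gene with a single CDS exon; reference spells Ala-Met-Stop
  refseq <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("T", 100), "GCTATGTAA", strrep("T", 100))))
  gm <- simple_gene("g", "chr1", cds = rbind(c(100, 109)))
  # third-codon-position GCT -> GCC is synonymous (Ala)
  v <- data.frame(chrom = "chr1", pos = 103, ref = "T", alt = "C",
                  zygosity = "hom", depth = 5)
  expect_equal(classify_effect(v, gm, refseq)$effect, "coding_syn")
  # first-codon-position GCT -> CCT is missense
  v2 <- data.frame(chrom = "chr1", pos = 101, ref = "G", alt = "C",
                   zygosity = "hom", depth = 5)
  expect_equal(classify_effect(v2, gm, refseq)$effect, "coding_nonsyn")
  # a 2 bp deletion in CDS is non-synonymous without translation
  v3 <- data.frame(chrom = "chr1", pos = 104, ref = "ATG", alt = "A",
                   zygosity = "hom", depth = 5)
  expect_equal(classify_effect(v3, gm, refseq)$effect, "coding_nonsyn")
  # far from any gene: intergenic
  v4 <- data.frame(chrom = "chr1", pos = 10000, ref = "A", alt = "G",
                   zygosity = "hom", depth = 5)
  expect_equal(classify_effect(v4, gm, NULL)$effect, "intergenic")
  # disagreeing ref allele is an error
  v5 <- data.frame(chrom = "chr1", pos = 103, ref = "A", alt = "C",
                   zygosity = "hom", depth = 5)
  expect_error(classify_effect(v5, gm, refseq), "mismatch")
})

test_that("effect precedence and strand handling are correct", {
  gm <- simple_gene("g", "chr1", cds = rbind(c(200, 230), c(300, 330)),
                    utr5 = rbind(c(180, 200)), utr3 = rbind(c(330, 350)))
  probes <- data.frame(chrom = "chr1", pos = c(190, 260, 340, 500),
                       ref = "A", alt = "G", zygosity = "hom", depth = 5)
  eff <- classify_effect(probes, gm, NULL)$effect[c(1, 2, 3, 4)]
  expect_equal(eff, c("utr5", "intron", "utr3", "intergenic"))

  # minus-strand gene: GCT read off the minus strand at the same locus
  minus_ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("A", 100),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString("ATGGCTTAA"))), strrep("A", 100))))
  gm_minus <- simple_gene("gm", "chr1", cds = rbind(c(100, 109)),
                          strand = "-")
  # plus-strand position 101 is the third base of the minus-strand Ala codon
  v <- data.frame(chrom = "chr1", pos = 104, ref = "A", alt = "G",
                  zygosity = "hom", depth = 5)
  # third codon position of the minus-strand Ala codon: synonymous
  expect_equal(classify_effect(v, gm_minus, minus_ref)$effect, "coding_syn")
})
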