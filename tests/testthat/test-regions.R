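# Target/background classification, region margins, deletions, genes.

make_segments <- function(mean_pd, chrom = NULL, n_positions = 50) {
  k <- length(mean_pd)
  if (is.null(chrom)) chrom <- paste0("chr", seq_len(k))
  first <- rep(1L, k)
  data.frame(chrom = chrom, first_idx = first,
             last_idx = first + n_positions - 1L,
             start_bp = seq_len(k) * 1e6,
             end_bp = seq_len(k) * 1e6 + n_positions * mean_pd,
             n_positions = n_positions, mean_pd = mean_pd,
             segment_stat = log2(mean_pd + 1), flagged = FALSE,
             stringsAsFactors = FALSE)
}

test_that("clearly bimodal segments split into target and background", {
  seg <- classify_segments(make_segments(c(2000, 2200, 40000, 45000)))
  expect_equal(seg$label, c("target", "target", "background", "background"))
  expect_true(attr(seg, "boundary_pd") > 2200 &&
                attr(seg, "boundary_pd") < 40000)
})

test_that("no contrast means no target calls, with a warning", {
  expect_warning(one <- classify_segments(make_segments(40000)), "single")
  expect_equal(one$label, "background")
  expect_warning(
    flat <- classify_segments(make_segments(c(40, 41, 42, 44) * 1000)),
    "contrast")
  expect_true(all(flat$label == "background"))
})

test_that("threshold method uses the user cutoff directly", {
  seg <- classify_segments(make_segments(c(1500, 9000, 30000)),
                           method = "threshold", threshold = 5000)
  expect_equal(seg$label, c("target", "background", "background"))
  expect_error(classify_segments(make_segments(c(1, 2)),
                                 method = "threshold"), "cutoff")
})

test_that("sparse target segments at chromosome ends are demoted", {
  seg <- make_segments(c(2000, 40000, 41000), chrom = rep("chr1", 3),
                       n_positions = c(6, 200, 200))
  seg$first_idx <- c(1L, 7L, 207L); seg$last_idx <- c(6L, 206L, 406L)
  out <- classify_segments(seg)
  expect_equal(out$label[1], "ambiguous")
  # same segment away from the chromosome end stays target
  seg2 <- make_segments(c(40000, 2000, 41000), chrom = rep("chr1", 3),
                        n_positions = c(200, 6, 200))
  seg2$first_idx <- c(1L, 201L, 207L); seg2$last_idx <- c(200L, 206L, 406L)
  out2 <- classify_segments(seg2)
  expect_equal(out2$label[2], "target")
})

test_that("region margins come from the positions, merging adjacent segments", {
  expect_equal(nrow(call_regions(
    classify_segments(make_segments(40000)) |> suppressWarnings())), 0)

  # dense grid flanked by sparse background on one chromosome
  pos <- data.frame(chrom = "chrZ",
                    start = c(seq(0, 4.96e6, by = 4e4),
                              seq(5e6, 6.9998e6, by = 2e3),
                              seq(7.04e6, 12e6, by = 4e4)))
  pos$end <- pos$start + 200
  pos$read_count <- 1
  pd <- compute_pd(pos, c(chrZ = 13e6))
  seg <- segment_chromosomes(pd, cbs_cfg = cbs_config(seed = 31))
  lab <- classify_segments(seg)
  reg <- call_regions(lab, pos)
  expect_equal(nrow(reg), 1)
  # margins are the outermost dense-grid positions
  expect_equal(reg$start, 5e6)
  expect_equal(reg$end, 6998000 + 200)  # last grid position
  expect_equal(reg$n_positions,
               sum(pos$start >= 5e6 & pos$start <= 6998000))
})

test_that("deletions are maximal uncovered stretches above min_gap", {
  region <- as_region_calls(data.frame(chrom = "chr3", start = 74548027,
                                       end = 76486586))
  # fully covered region: no calls
  dense <- data.frame(chrom = "chr3",
                      start = seq(74548027, 76486386, by = 2000))
  dense$end <- dense$start + 2000  # book-ended coverage
  expect_equal(nrow(detect_deletions(region, dense)), 0)

  # positions absent between 74.88 and 75.30 Mbp: one 420 kbp call
  holey <- dense[!(dense$start >= 74880000 & dense$end <= 75300000), ]
  # make coverage abut the deletion exactly
  holey$end[holey$end > 74880000 & holey$start < 74880000] <- 74880000
  holey$start[holey$start < 75300000 & holey$end > 75300000] <- 75300000
  del <- detect_deletions(region, holey,
                          gaps = data.frame(chrom = "chr3",
                                            start = 75290000,
                                            end = 75310000))
  expect_equal(nrow(del), 1)
  expect_equal(del$length, 420000)
  expect_equal(del$start, 74880000)
  expect_true(del$overlaps_assembly_gap)
  # deletions never extend past region margins
  expect_gte(del$start, region$start)
  expect_lte(del$end, region$end)

  # a region smaller than min_gap yields nothing
  small <- as_region_calls(data.frame(chrom = "chr3", start = 0, end = 5e4))
  expect_equal(nrow(detect_deletions(small, dense)), 0)
})

test_that("ten planted uncovered stretches are recovered bp-exact", {
  regions <- example_b_regions("brocket")
  dels <- example_b_deletions("brocket")
  # deterministic positions: 2 kbp grid over regions, clipped to abut the
  # planted deletions exactly
  pos <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    grid <- data.frame(chrom = r$chrom,
                       start = seq(r$start, r$end - 200, by = 2000))
    grid$end <- pmin(grid$start + 2000, r$end)
    d <- dels[dels$chrom == r$chrom & dels$start >= r$start &
                dels$end <= r$end, , drop = FALSE]
    for (j in seq_len(nrow(d))) {
      inside <- grid$start >= d$start[j] & grid$end <= d$end[j]
      grid <- grid[!inside, , drop = FALSE]
      grid$end[grid$start < d$start[j] & grid$end > d$start[j]] <- d$start[j]
      grid$start[grid$start < d$end[j] & grid$end > d$end[j]] <- d$end[j]
    }
    grid
  }))
  calls <- detect_deletions_all(as_region_calls(regions), pos,
                                min_gap = 100000)
  expect_equal(nrow(calls), 10)
  expect_equal(sum(calls$length), 1030000)
  expect_true(all(!duplicated(paste(calls$chrom, calls$start))))
})

test_that("gene completeness follows margin-first precedence", {
  region <- as_region_calls(data.frame(chrom = "c", start = 0, end = 1e5))
  no_del <- region[0, c("region_id", "chrom", "start", "end")]
  genes <- data.frame(chrom = "c",
                      start = c(10e3, 95e3, 40e3, -2e3),
                      end = c(20e3, 110e3, 52e3, 3e3),
                      gene_id = c("inside", "crosses_end", "on_del",
                                  "crosses_start_and_del"),
                      strand = "+")
  del <- data.frame(region_id = region$region_id, chrom = "c",
                    start = c(45e3, 0), end = c(50e3, 1e3),
                    length = c(5e3, 1e3), overlaps_assembly_gap = FALSE)
  ann <- annotate_genes(region, del, genes)
  st <- setNames(ann$genes$status, ann$genes$gene_id)
  expect_equal(st[["inside"]], "complete")
  expect_equal(st[["crosses_end"]], "partial_margin")
  expect_equal(st[["on_del"]], "partial_deletion")
  # margin-first tie-break
  expect_equal(st[["crosses_start_and_del"]], "partial_margin")
  expect_equal(ann$summary$n_complete, 1)
  expect_equal(ann$summary$n_partial, 3)
})

test_that("the bundled flag table is reproduced from synthetic gene spans", {
  regions <- example_b_regions("brocket")
  dels <- deletions_with_region_ids(example_b_deletions("brocket"), regions)
  flags <- example_gene_flags("brocket")
  spans <- synthetic_gene_spans(regions, flags, example_b_deletions("brocket"))
  expect_equal(nrow(spans), nrow(flags))
  ann <- annotate_genes(as_region_calls(regions), dels, spans)
  expect_equal(ann$summary$n_complete, 34)
  expect_equal(ann$summary$n_partial, 21)
  # recovered flags match gene by gene
  merged <- merge(ann$genes, flags, by = "gene_id")
  expect_equal(nrow(merged), nrow(flags))
  expect_true(all(merged$flag.x == merged$flag.y))
})

test_that("region size accounting matches the printed totals", {
  roe <- example_b_regions("roe")
  acct <- region_size_accounting(as_region_calls(roe),
                                 example_b_deletions("roe"))
  expect_equal(acct$total_bp, 1979679)
  expect_equal(round(acct$total_minus_deletions_bp / 1e6, 2), 1.42)
  brocket <- region_size_accounting(as_region_calls(
    example_b_regions("brocket")))
  expect_equal(brocket$total_bp, 9311710)
  empty <- region_size_accounting(
    data.frame(chrom = character(), start = numeric(), end = numeric()))
  expect_equal(c(empty$total_bp, empty$total_minus_deletions_bp), c(0, 0))
})

test_that("short low-PD runs outside regions surface as visual candidates", {
  pos <- data.frame(chrom = "chrC",
                    start = c(seq(0, 2e6, by = 4e4),
                              seq(2.5e6, 2.512e6, by = 2e3),
                              seq(3e6, 5e6, by = 4e4)))
  pos$end <- pos$start + 200
  pos$read_count <- 1
  pd <- compute_pd(pos)
  cand <- candidate_regions(pd, regions = NULL, pd_cutoff = 10000,
                            min_run = 4)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 2.5e6)
  expect_equal(cand$label, "candidate (visual)")
  # suppressed when a called region already covers it
  none <- candidate_regions(pd, data.frame(chrom = "chrC", start = 2.4e6,
                                           end = 2.6e6), 10000)
  expect_equal(nrow(none), 0)
})
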