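test_that("the moving average follows the truncated-window edge rule", {
  expect_equal(moving_average(c(0, 1, 0, 1, 0), 3),
               c(0.5, 1 / 3, 2 / 3, 1 / 3, 0.5))
  expect_equal(moving_average(rep(0.4, 10), 5), rep(0.4, 10))
  x <- runif(7)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(x, 11), rep(mean(x), 7))
  expect_error(moving_average(x, 4), "window")
})

test_that("a flat methylome gives a flat profile", {
  sim <- small_sim()
  calls <- dplyr::mutate(truth_as_calls(sim), level = 0.5)
  prof <- metagene_profile(calls, sim$ann$genes)
  filled <- prof[prof$n > 0, ]
  expect_true(all(abs(filled$mean_level - 0.5) < 1e-12))
  expect_equal(nrow(prof), 80L)
})

test_that("profile bin counts conserve the assigned sites", {
  sim <- small_sim()
  calls <- truth_as_calls(sim)
  prof <- metagene_profile(calls, sim$ann$genes)
  # oracle: count sites within the -50%..150% frame of their nearest gene
  d <- interval_distance_oracle(
    calls, dplyr::rename(sim$ann$genes, start = txStart, end = txEnd))
  g <- sim$ann$genes
  in_frame <- vapply(seq_len(nrow(calls)), function(i) {
    on <- which(g$chrom == calls$chrom[i])
    any(calls$pos[i] >= g$txStart[on] - 0.5 * (g$txEnd[on] - g$txStart[on]) &
          calls$pos[i] <= g$txEnd[on] + 0.5 * (g$txEnd[on] - g$txStart[on]) - 1)
  }, logical(1))
  # nearest-gene frame is a subset of any-gene frames; counts must not exceed
  expect_lte(sum(prof$n), sum(in_frame))
  expect_gt(sum(prof$n), 0.8 * sum(in_frame))
})

test_that("the TSS dip is recovered at the TSS bins", {
  sim <- small_sim()
  calls <- truth_as_calls(sim)
  prof <- metagene_profile(calls, sim$ann$genes)
  dip <- glance(prof)$dip_position
  expect_lt(abs(dip), 0.2)
})

test_that("minus-strand genes align with plus-strand genes after the flip", {
  # one gene per strand with identical geometry and a dip after the TSS
  genes <- tibble::tibble(
    name = c("gp", "gm"), chrom = c("chrP", "chrM"), strand = c("+", "-"),
    txStart = 20000L, txEnd = 24000L,
    exon_starts = list(20000L, 20000L), exon_ends = list(24000L, 24000L)
  )
  pos <- seq(10000L, 34000L, by = 50L)
  mk_calls <- function(chrom, strand) {
    rel <- if (strand == "+") (pos - 20000) / 4000 else (24000 - 1 - pos) / 4000
    tibble::tibble(sample = "S0h", site_id = seq_along(pos), chrom = chrom,
                   pos = pos, u = 0L, m = 0L, depth = 100L,
                   level = ifelse(rel >= 0 & rel < 0.25, 0.1, 0.8))
  }
  pp <- metagene_profile(mk_calls("chrP", "+"), genes[1, ], smooth_window = 1)
  pm <- metagene_profile(mk_calls("chrM", "-"), genes[2, ], smooth_window = 1)
  expect_equal(pp$mean_level, pm$mean_level, tolerance = 1e-12)
})

test_that("equal expression still splits genes into near-equal tertiles", {
  expr <- tibble::tibble(gene = sprintf("g%02d", 1:10), expression = 5)
  tert <- expression_tertiles(expr)
  sizes <- table(tert$tertile)
  expect_lte(max(sizes) - min(sizes), 1)
  # deterministic: ordering by (expression, gene) sends first names low
  expect_equal(tert$tertile[tert$gene == "g01"], 1)
  expect_equal(tert$tertile[tert$gene == "g10"], 3)
})

test_that("boundary expression ties fall into the lower tertile", {
  expr <- tibble::tibble(gene = c("a", "b", "c", "d", "e", "f"),
                         expression = c(1, 2, 2, 2, 5, 6))
  tert <- expression_tertiles(expr)
  expect_equal(tert$tertile[tert$gene == "c"], 2)  # tie at the 1|2 boundary
  expect_equal(tert$tertile[tert$gene == "b"], 1)
})

test_that("expression-coupled truth recovers the tertile body contrast", {
  sim <- small_sim()
  truth <- generate_methylome(sim$genome, sim$ann, sim$cfg,
                              scenario = "expression_coupled")
  calls <- dplyr::mutate(truth[truth$sample == "S0h", ],
                         u = 0L, m = 0L, depth = 100L)
  tp <- expression_tertile_profiles(calls, sim$ann$genes, sim$ann$expression)
  ct <- tp$contrast
  diff_body <- ct$body2_mean[ct$tertile == 3] - ct$body2_mean[ct$tertile == 1]
  expect_lt(abs(diff_body - 0.2), 0.05)
  # TSS ordering is reversed relative to the body ordering
  expect_lt(ct$tss_mean[ct$tertile == 3], ct$tss_mean[ct$tertile == 1])
})

test_that("genes without expression are excluded and counted", {
  sim <- small_sim()
  calls <- truth_as_calls(sim)
  expr <- sim$ann$expression[-(1:2), ]
  tp <- expression_tertile_profiles(calls, sim$ann$genes, expr)
  expect_equal(tp$n_genes_missing_expression, 2L)
})

test_that("histone peak strata recover the planted contrasts", {
  sim <- small_sim()
  calls <- truth_as_calls(sim)
  ov <- peak_overlap_summary(calls, sim$ann$peaks)
  active <- ov[ov$mark == sim$cfg$marks[1], ]
  repress <- ov[ov$mark == sim$cfg$marks[2], ]
  expect_lt(active$mean_level[active$stratum == "within"],
            active$mean_level[active$stratum == "without"])
  expect_gt(repress$mean_level[repress$stratum == "within"],
            repress$mean_level[repress$stratum == "without"])
  expect_equal(sum(ov$n[ov$mark == sim$cfg$marks[1]]), nrow(calls))
})

test_that("an empty peak track yields a within count of zero", {
  sim <- small_sim()
  calls <- truth_as_calls(sim)
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), mark = character())
  empty <- dplyr::bind_rows(empty,
                            tibble::tibble(chrom = "chrZZ", start = 0L,
                                           end = 10L, mark = "H3K9ac"))
  ov <- peak_overlap_summary(calls, empty)
  expect_equal(ov$n[ov$stratum == "within"], 0L)
  expect_equal(ov$mean_level[ov$stratum == "without"], mean(calls$level))
})

test_that("short-RNA proximity classes use inclusive boundaries", {
  srna <- tibble::tibble(chrom = "chr1", start = 5000L, end = 5200L)
  calls <- tibble::tibble(sample = "S0h", site_id = 1:4, chrom = "chr1",
                          pos = c(5100L, 5199L + 2000L, 5199L + 2001L, 900L),
                          u = 0L, m = 0L, depth = 50L, level = 0.5)
  ps <- shortrna_proximity_summary(calls, srna, flank = 2000)
  expect_equal(ps$n[ps$class == "within"], 1L)
  expect_equal(ps$n[ps$class == "near"], 1L)   # exactly 2000 bp counts as near
  expect_equal(ps$n[ps$class == "without"], 2L)  # 2001 bp is already outside
  expect_equal(sum(ps$fraction), 1)
})

test_that("no short-RNA loci means every site is 'without'", {
  sim <- small_sim()
  calls <- truth_as_calls(sim)
  none <- tibble::tibble(chrom = character(), start = integer(),
                         end = integer())
  ps <- shortrna_proximity_summary(calls, none)
  expect_equal(ps$fraction[ps$class == "without"], 1)
  expect_equal(sum(ps$n[ps$class != "without"]), 0L)
})

test_that("short-RNA neighbourhoods are hypomethylated in the truth", {
  sim <- small_sim()
  calls <- truth_as_calls(sim)
  ps <- shortrna_proximity_summary(calls, sim$ann$shortrna)
  m <- setNames(ps$mean_level, ps$class)
  expect_lt(m["within"], m["near"])
  expect_lt(m["near"], m["without"])
})
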