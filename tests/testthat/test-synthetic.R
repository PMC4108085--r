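test_that("identical config and seed reproduce identical outputs", {
  cfg <- simulation_config(seed = 7, n_chroms = 2, chrom_length = 50000)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nchar(g1$genome), setNames(c(50000L, 50000L), c("chr1", "chr2")))

  t1 <- generate_methylome(g1$genome, g1$annotations, cfg)
  t2 <- generate_methylome(g2$genome, g2$annotations, cfg)
  expect_identical(t1, t2)

  c1 <- simulate_counts(t1, cfg)
  c2 <- simulate_counts(t2, cfg)
  expect_identical(c1, c2)
})

test_that("CCGG density inside CGIs is at least 3x the background", {
  sim <- small_sim()
  inside <- interval_distance_oracle(sim$sites, sim$ann$cgi) == 0
  cgi_bp <- sum(sim$ann$cgi$end - sim$ann$cgi$start)
  bg_bp <- sum(nchar(sim$genome)) - cgi_bp
  ratio <- (sum(inside) / cgi_bp) / (sum(!inside) / bg_bp)
  expect_gte(ratio, 3)
})

test_that("a CGI-free genome still supports the downstream pipeline", {
  cfg <- simulation_config(seed = 5, n_chroms = 1, chrom_length = 30000,
                           cgi_count = 0)
  gen <- generate_genome(cfg)
  expect_equal(nrow(gen$annotations$cgi), 0L)
  truth <- generate_methylome(gen$genome, gen$annotations, cfg)
  sc <- simulate_counts(truth, cfg)
  sites <- find_ccgg_sites(gen$genome)
  calls <- normalize_and_call(sc$counts, sc$spike_ins, sites)
  expect_gt(nrow(calls), 0)
  ctx <- classify_cgi_context(sites, gen$annotations$cgi)
  expect_true(all(ctx$cgi_context == "open_sea"))
})

test_that("annotations use valid half-open coordinates and positive expression", {
  sim <- small_sim()
  for (iv in sim$ann[c("cgi", "peaks", "shortrna")]) {
    expect_true(all(iv$start >= 0 & iv$start < iv$end))
  }
  expect_true(all(sim$ann$expression$expression > 0))
  expect_true(all(sim$ann$genes$strand %in% c("+", "-")))
  expect_setequal(unique(sim$ann$peaks$mark), sim$cfg$marks)
})

test_that("the null methylome is identical across all five samples", {
  sim <- small_sim()
  wide <- tidyr::pivot_wider(sim$truth[, c("sample", "site_id", "level")],
                             names_from = "sample", values_from = "level")
  for (s in setdiff(sim$cfg$samples, "S0h")) {
    expect_equal(max(abs(wide[[s]] - wide$S0h)), 0)
  }
  expect_true(all(sim$truth$level >= 0 & sim$truth$level <= 1))
})

test_that("CGI sites are hypomethylated relative to the rest", {
  sim <- small_sim()
  s0 <- sim$truth[sim$truth$sample == "S0h", ]
  inside <- interval_distance_oracle(sim$sites, sim$ann$cgi) == 0
  expect_lt(mean(s0$level[inside]), 0.15)
  expect_lt(mean(s0$level[inside]), mean(s0$level[!inside]))
})

test_that("expression-coupled truth separates tertiles by the offset", {
  sim <- small_sim()
  cfg <- sim$cfg
  truth <- generate_methylome(sim$genome, sim$ann, cfg,
                              scenario = "expression_coupled")
  s0 <- truth[truth$sample == "S0h", ]
  tert <- expression_tertiles(sim$ann$expression)
  # oracle: strand-aware latter-body membership recomputed from scratch
  genes <- sim$ann$genes
  means <- vapply(c(1, 3), function(t) {
    g <- genes[genes$name %in% tert$gene[tert$tertile == t], ]
    sel <- rep(FALSE, nrow(s0))
    for (i in seq_len(nrow(g))) {
      L <- g$txEnd[i] - g$txStart[i]
      rel <- if (g$strand[i] == "+") {
        (s0$pos - g$txStart[i]) / L
      } else {
        (g$txEnd[i] - 1 - s0$pos) / L
      }
      sel <- sel | (s0$chrom == g$chrom[i] & rel >= 0.5 & rel < 1)
    }
    mean(s0$level[sel])
  }, numeric(1))
  expect_lt(abs((means[2] - means[1]) - 0.2), 0.03)
})

test_that("unknown scenarios are rejected", {
  sim <- small_sim()
  expect_error(generate_methylome(sim$genome, sim$ann, sim$cfg,
                                  scenario = "bogus"), "scenario")
})

test_that("plant_dmrs shifts treated samples and clips at the boundaries", {
  sites <- tibble::tibble(site_id = 1:8, chrom = "chr1",
                          pos = c(10L, 50L, 90L, 130L, 410L, 450L, 490L, 530L))
  truth <- tidyr::expand_grid(sample = c("S0h", "S4h", "S12h"), sites) |>
    dplyr::mutate(level = 0.2)
  pl <- plant_dmrs(truth, n_dmrs = 1, delta = 0.4, width_bp = 200, seed = 1)
  shifted <- pl$truth
  in_dmr <- shifted$pos >= pl$dmrs$start & shifted$pos < pl$dmrs$end &
    shifted$chrom == pl$dmrs$chrom
  expect_equal(unique(shifted$level[in_dmr & shifted$sample != "S0h"]), 0.6)
  expect_equal(unique(shifted$level[shifted$sample == "S0h"]), 0.2)
  expect_gte(sum(sites$pos >= pl$dmrs$start & sites$pos < pl$dmrs$end), 4)

  # clipping (opt-in placement on clipping regions)
  truth$level <- 0.5
  pl2 <- plant_dmrs(truth, n_dmrs = 1, delta = 0.9, width_bp = 200, seed = 1,
                    allow_clipping = TRUE)
  tr <- pl2$truth[pl2$truth$sample != "S0h", ]
  in2 <- tr$pos >= pl2$dmrs$start & tr$pos < pl2$dmrs$end
  expect_equal(unique(tr$level[in2]), 1.0)

  # without allow_clipping the same request is unplaceable
  expect_error(plant_dmrs(truth, n_dmrs = 1, delta = 0.9, width_bp = 200,
                          seed = 1), "eligible")
})

test_that("planted regions are disjoint and each holds >= 4 sites", {
  sim <- small_sim()
  pl <- plant_dmrs(sim$truth, n_dmrs = 10, delta = 0.4, seed = 3)
  d <- pl$dmrs
  expect_equal(nrow(d), 10)
  ov <- FALSE
  for (i in seq_len(nrow(d) - 1)) {
    same <- d$chrom == d$chrom[i]
    same[i] <- FALSE
    ov <- ov || any(same & d$start < d$end[i] & d$start[i] < d$end)
  }
  expect_false(ov)
  for (i in seq_len(nrow(d))) {
    n <- sum(sim$sites$chrom == d$chrom[i] &
               sim$sites$pos >= d$start[i] & sim$sites$pos < d$end[i])
    expect_gte(n, 4)
  }
})

test_that("count simulation respects the digestion model at the endpoints", {
  cfg <- simulation_config(seed = 9, mean_depth = 50)
  truth0 <- tibble::tibble(sample = "S0h", site_id = 1:500, chrom = "chr1",
                           pos = seq_len(500) * 40L, level = 0)
  sc0 <- simulate_counts(truth0, cfg)
  expect_true(all(sc0$counts$m == 0))

  truth1 <- dplyr::mutate(truth0, level = 1)
  sc1 <- simulate_counts(truth1, cfg)
  expect_true(all(sc1$counts$u == 0))
})

test_that("at p = 0.5 with equal efficiencies the count ratio is centred", {
  cfg <- simulation_config(seed = 13, mean_depth = 100)
  truth <- tibble::tibble(sample = "S0h", site_id = 1:2000, chrom = "chr1",
                          pos = seq_len(2000) * 40L, level = 0.5)
  sc <- simulate_counts(truth, cfg)
  frac <- with(sc$counts[sc$counts$u + sc$counts$m > 0, ], m / (m + u))
  expect_lt(abs(mean(frac) - 0.5), 0.01)
})

test_that("error-free reads use only library tags and conserve counts", {
  cfg <- simulation_config(seed = 17, n_chroms = 1, chrom_length = 20000,
                           mean_depth = 5, spike_in_mean = 30,
                           samples = c("S0h", "S4h"))
  gen <- generate_genome(cfg)
  sites <- find_ccgg_sites(gen$genome)
  lib <- add_standard_tags(build_tag_library(gen$genome, sites), seed = 2)
  truth <- generate_methylome(gen$genome, gen$annotations, cfg)
  sc <- simulate_counts(truth, cfg)
  itab <- make_index_table(cfg$samples)
  rd <- simulate_reads(sc, lib, itab, seq_error_rate = 0, seed = 5)

  tags <- substr(rd$reads$seq, 7, 24)
  expect_true(all(tags %in% c(lib$tags$tag, lib$standards$tag)))

  # conservation: emissions equal counts plus spike-ins minus drops
  total_in <- sum(sc$counts$u) + sum(sc$counts$m) + sum(sc$spike_ins$count)
  expect_equal(sum(rd$ledger$emitted), nrow(rd$reads))
  expect_equal(sum(rd$ledger$emitted) + sum(rd$ledger$dropped), total_in)
})

test_that("single-site counts emit exactly that library's reads", {
  g <- c(chr1 = paste0(random_dna(30, seed = 21), "CCGG",
                       random_dna(30, seed = 22)))
  sites <- find_ccgg_sites(g)
  lib <- build_tag_library(g, sites)
  counts <- list(
    counts = tibble::tibble(sample = "S0h", site_id = sites$site_id,
                            u = 3L, m = 0L),
    spike_ins = tibble::tibble(sample = "S0h",
                               library = c("hpaii", "inverse"),
                               count = c(0L, 0L))
  )
  itab <- make_index_table("S0h")
  rd <- simulate_reads(counts, lib, itab, seq_error_rate = 0, seed = 1)
  expect_equal(nrow(rd$reads), 3L)
  idx <- itab$index[itab$library == "hpaii"]
  expect_true(all(substr(rd$reads$seq, 1, 6) == idx))
})
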