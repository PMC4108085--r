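# A tiny deterministic library for matcher unit tests.
toy_library <- function() {
  g <- c(chr1 = paste0(random_dna(40, seed = 31), "CCGG",
                       random_dna(60, seed = 32), "CCGG",
                       random_dna(40, seed = 33)))
  sites <- find_ccgg_sites(g)
  lib <- add_standard_tags(build_tag_library(g, sites), n_per_library = 2,
                           seed = 4)
  list(genome = g, sites = sites, lib = lib)
}

flip_base <- function(tag, pos) {
  b <- substr(tag, pos, pos)
  substr(tag, pos, pos) <- setdiff(c("A", "C", "G", "T"), b)[1]
  tag
}

test_that("demultiplexing is exact-match and conserves reads", {
  itab <- make_index_table(c("S0h", "S4h"))
  idx <- itab$index[itab$sample == "S0h" & itab$library == "hpaii"]
  reads <- tibble::tibble(id = sprintf("r%03d", 1:101),
                          seq = c(rep(paste0(idx, strrep("A", 18)), 100),
                                  paste0(flip_base(idx, 1), strrep("A", 18))))
  st <- demultiplex(reads, itab)
  expect_equal(nrow(st), 100L)
  expect_equal(unique(st$sample), "S0h")
  expect_equal(unique(st$library), "hpaii")
  expect_equal(attr(st, "unassigned"), 1L)
  expect_equal(nrow(st) + attr(st, "unassigned"), attr(st, "total"))
})

test_that("ragged or duplicated index tables are rejected", {
  bad <- tibble::tibble(index = c("AAA", "CCCC"),
                        sample = c("a", "b"), library = "hpaii")
  expect_error(demultiplex(tibble::tibble(id = "r", seq = "AAAA"), bad),
               "ragged")
  dup <- tibble::tibble(index = c("AAAA", "AAAA"),
                        sample = c("a", "b"), library = "hpaii")
  expect_error(demultiplex(tibble::tibble(id = "r", seq = "AAAA"), dup),
               "unique")
})

test_that("exact tags match their site; distant tags are rejected", {
  tl <- toy_library()
  tag <- tl$lib$tags$tag[1]
  hit <- match_tag(tag, tl$lib)
  expect_equal(hit$status, "site")
  expect_equal(hit$site_id, tl$lib$tags$site_id[1])
  expect_equal(hit$mismatches, 0L)

  # two substitutions beyond max_mismatch = 1
  far <- flip_base(flip_base(tag, 5), 9)
  miss <- match_tag(far, tl$lib, max_mismatch = 1)
  expect_equal(miss$status, "no_hit")
  # but accepted when the tolerance is raised to 2 (unique best hit)
  hit2 <- match_tag(far, tl$lib, max_mismatch = 2)
  expect_equal(hit2$status, "site")
  expect_equal(hit2$mismatches, 2L)
})

test_that("equidistant hits at the best tier are ambiguous", {
  # two library tags at Hamming distance 2; the midpoint pattern is at
  # distance 1 from both
  base <- paste0("CGG", random_dna(15, seed = 41))
  t2 <- flip_base(flip_base(base, 7), 12)
  lib <- structure(list(
    tags = tibble::tibble(tag = c(base, t2), site_id = c(1L, 2L),
                          side = "fwd"),
    ambiguous = character(),
    standards = tibble::tibble(tag = character(), library = character()),
    tag_length = 18L
  ), class = "mscc_tag_library")
  mid <- flip_base(base, 7)
  res <- match_tag(mid, lib)
  expect_equal(res$status, "ambiguous")
})

test_that("a unique exact hit wins even when 1-mismatch hits exist", {
  base <- paste0("CGG", random_dna(15, seed = 43))
  neigh <- flip_base(base, 10)
  lib <- structure(list(
    tags = tibble::tibble(tag = c(base, neigh), site_id = c(1L, 2L),
                          side = "fwd"),
    ambiguous = character(),
    standards = tibble::tibble(tag = character(), library = character()),
    tag_length = 18L
  ), class = "mscc_tag_library")
  res <- match_tag(base, lib)
  expect_equal(res$status, "site")
  expect_equal(res$site_id, 1L)
})

test_that("non-ACGT bases count as mismatches at their position", {
  tl <- toy_library()
  tag <- tl$lib$tags$tag[1]
  n_tag <- tag
  substr(n_tag, 4, 4) <- "N"
  hit <- match_tag(n_tag, tl$lib, max_mismatch = 1)
  expect_equal(hit$status, "site")
  expect_equal(hit$mismatches, 1L)
  n2 <- flip_base(n_tag, 9)
  expect_equal(match_tag(n2, tl$lib, max_mismatch = 1)$status, "no_hit")
})

test_that("counting partitions every stream and routes standards", {
  tl <- toy_library()
  std <- tl$lib$standards
  streams <- tibble::tibble(
    sample = "S0h", library = "hpaii",
    tag = c(tl$lib$tags$tag[1], std$tag[std$library == "hpaii"][1],
            strrep("T", 18))
  )
  res <- count_tags(streams, tl$lib)
  expect_equal(sum(res$counts$u), 1L)
  expect_equal(sum(res$counts$m), 0L)
  expect_equal(res$spike_ins$count[res$spike_ins$sample == "S0h" &
                                     res$spike_ins$library == "hpaii"], 1L)
  rep_row <- res$report[res$report$library == "hpaii", ]
  expect_equal(rep_row$mapped + rep_row$no_hit + rep_row$ambiguous,
               rep_row$total)
  expect_equal(rep_row$total, 3L)
})

test_that("a standards-only stream yields zero site counts", {
  tl <- toy_library()
  std <- tl$lib$standards$tag[tl$lib$standards$library == "inverse"]
  streams <- tibble::tibble(sample = "S0h", library = "inverse",
                            tag = rep(std, 5)[1:10])
  res <- count_tags(streams, tl$lib)
  expect_equal(sum(res$counts$u) + sum(res$counts$m), 0L)
  expect_equal(sum(res$spike_ins$count), 10L)
})

test_that("error-free round trip reproduces the simulated counts exactly", {
  cfg <- simulation_config(seed = 23, n_chroms = 1, chrom_length = 20000,
                           mean_depth = 8, spike_in_mean = 40,
                           samples = c("S0h", "S4h"))
  gen <- generate_genome(cfg)
  sites <- find_ccgg_sites(gen$genome)
  lib <- add_standard_tags(build_tag_library(gen$genome, sites), seed = 6)
  truth <- generate_methylome(gen$genome, gen$annotations, cfg)
  sc <- simulate_counts(truth, cfg)
  itab <- make_index_table(cfg$samples)
  rd <- simulate_reads(sc, lib, itab, seq_error_rate = 0, seed = 7)
  st <- demultiplex(rd$reads, itab)
  expect_equal(attr(st, "unassigned"), 0L)

  # stream totals equal the emission ledger
  totals <- dplyr::count(st, sample, library)
  led <- dplyr::inner_join(totals, rd$ledger, by = c("sample", "library"))
  expect_equal(led$n, led$emitted)

  res <- count_tags(st, lib)
  joined <- dplyr::inner_join(sc$counts, res$counts,
                              by = c("sample", "site_id"),
                              suffix = c("_in", "_out"))
  # sites with no usable tag never emit reads; all others match exactly
  tagged <- joined$site_id %in% lib$tags$site_id
  expect_true(all(joined$u_in[tagged] == joined$u_out[tagged]))
  expect_true(all(joined$m_in[tagged] == joined$m_out[tagged]))
  sp <- dplyr::inner_join(sc$spike_ins, res$spike_ins,
                          by = c("sample", "library"),
                          suffix = c("_in", "_out"))
  expect_equal(sp$count_in, sp$count_out)
})

test_that("raising max_mismatch never decreases the mapped count", {
  cfg <- simulation_config(seed = 29, n_chroms = 1, chrom_length = 15000,
                           mean_depth = 4, spike_in_mean = 20,
                           samples = "S0h", seq_error_rate = 0.03)
  gen <- generate_genome(cfg)
  sites <- find_ccgg_sites(gen$genome)
  lib <- add_standard_tags(build_tag_library(gen$genome, sites), seed = 8)
  truth <- generate_methylome(gen$genome, gen$annotations, cfg)
  sc <- simulate_counts(truth, cfg)
  itab <- make_index_table(cfg$samples)
  rd <- simulate_reads(sc, lib, itab, seq_error_rate = 0.03, seed = 9)
  st <- demultiplex(rd$reads, itab)
  mapped <- vapply(0:2, function(mm) {
    sum(count_tags(st, lib, max_mismatch = mm)$report$mapped)
  }, numeric(1))
  expect_true(all(diff(mapped) >= 0))
})

test_that("the exact-match fraction tracks (1 - p)^18", {
  p <- 0.01
  cfg <- simulation_config(seed = 37, n_chroms = 1, chrom_length = 25000,
                           mean_depth = 10, spike_in_mean = 20,
                           samples = "S0h", seq_error_rate = p)
  gen <- generate_genome(cfg)
  sites <- find_ccgg_sites(gen$genome)
  lib <- add_standard_tags(build_tag_library(gen$genome, sites), seed = 10)
  truth <- generate_methylome(gen$genome, gen$annotations, cfg)
  sc <- simulate_counts(truth, cfg)
  itab <- make_index_table(cfg$samples)
  rd <- simulate_reads(sc, lib, itab, seq_error_rate = p, seed = 11)
  tags <- substr(rd$reads$seq, 7, 24)
  exact <- mean(tags %in% c(lib$tags$tag, lib$standards$tag))
  expect_lt(abs(exact - (1 - p)^18), 0.02)
})
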