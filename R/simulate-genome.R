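# Synthetic genomes and annotations. The toy genome reproduces the
# statistical structure the downstream analyses assume -- CCGG-enriched
# CpG islands, genes with strand/exon structure, histone peak tracks and
# short-RNA loci -- at a desk scale. CCGG sites are intentionally denser
# than in a mammalian genome so that a few hundred kb already yields
# >1000 analysis windows with >=4 sites, the regime the window-based DMR
# machinery is designed for.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic MSCC experiment.
#' The defaults define the emulated study: five timepoint samples
#' (S0h--S96h), ~50x mean site coverage, unbiased library efficiencies
#' and abundant spike-in standards.
#'
#' @param seed Integer seed; identical config + seed reproduces identical
#'   output byte for byte.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp (>= 1000).
#' @param cgi_count Number of CpG islands across the genome; by default
#'   one per ~12.5 kb.
#' @param gene_count Number of genes across the genome; by default one
#'   per ~10 kb.
#' @param mean_depth Mean sequencing depth per CCGG site (reads).
#' @param hpaii_efficiency,inverse_efficiency Library sampling
#'   efficiencies in (0, 1]; values < 1 under-sample that library and are
#'   what spike-in normalization corrects.
#' @param spike_in_mean Mean spike-in standard read count per library.
#' @param seq_error_rate Per-base substitution error probability.
#' @param samples Ordered sample labels; the first is the baseline.
#' @param marks Histone mark names: first is treated as an active
#'   (methylation-depleted) mark, second as repressive.
#' @return A validated list of class `mscc_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 3L,
                              chrom_length = 100000L,
                              cgi_count = NULL,
                              gene_count = NULL,
                              mean_depth = 50,
                              hpaii_efficiency = 1,
                              inverse_efficiency = 1,
                              spike_in_mean = 10000,
                              seq_error_rate = 0.001,
                              samples = c("S0h", "S4h", "S12h", "S24h", "S96h"),
                              marks = c("H3K9ac", "H3K27me3")) {
  genome_len <- as.numeric(n_chroms) * as.numeric(chrom_length)
  cgi_count <- cgi_count %||% max(2L, round(genome_len / 12500))
  gene_count <- gene_count %||% max(2L, round(genome_len / 10000))
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length), cgi_count = as.integer(cgi_count),
    gene_count = as.integer(gene_count), mean_depth = mean_depth,
    hpaii_efficiency = hpaii_efficiency, inverse_efficiency = inverse_efficiency,
    spike_in_mean = spike_in_mean, seq_error_rate = seq_error_rate,
    samples = samples, marks = marks
  )
  stopifnot(
    cfg$n_chroms >= 1, cfg$chrom_length >= 1000,
    cfg$cgi_count >= 0, cfg$gene_count >= 0, cfg$mean_depth >= 0,
    cfg$hpaii_efficiency > 0, cfg$hpaii_efficiency <= 1,
    cfg$inverse_efficiency > 0, cfg$inverse_efficiency <= 1,
    cfg$spike_in_mean >= 0, cfg$seq_error_rate >= 0, cfg$seq_error_rate < 1,
    length(cfg$samples) >= 1, !anyDuplicated(cfg$samples)
  )
  structure(cfg, class = "mscc_config")
}

BASES <- c("A", "C", "G", "T")
BG_PROBS <- c(0.30, 0.20, 0.20, 0.30)   # AT-rich background
CGI_PROBS <- c(0.15, 0.35, 0.35, 0.15)  # GC-rich islands
BG_CCGG_SPACING <- 45L                  # mean bp between planted background CCGGs
CGI_CCGG_SPACING <- 12L                 # mean bp between planted CGI CCGGs

#' Generate a toy genome with annotations
#'
#' Builds `n_chroms` random chromosomes and plants, in order: CpG islands
#' (GC-rich, CCGG density >= 3x background), genome-wide background CCGG
#' sites, genes with strand and exon structure plus a positive expression
#' value each, one histone peak track per configured mark, and short-RNA
#' loci. All annotation coordinates are 0-based half-open.
#'
#' @param config An [simulation_config()] object.
#' @return List with `genome` (named character vector) and `annotations`
#'   (list of tibbles: `genes`, `cgi`, `peaks` (with `mark` column),
#'   `shortrna`, `expression`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "mscc_config"))
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  chrom_lengths <- setNames(rep(config$chrom_length, config$n_chroms), chroms)
  genome_len <- sum(chrom_lengths)

  seqs <- lapply(chrom_lengths, function(L) {
    sample(BASES, L, replace = TRUE, prob = BG_PROBS)
  })

  # feature sizes/pads shrink on very small chromosomes so toy configs place
  cl <- config$chrom_length
  cgi_pad_bp <- min(2400L, max(600L, cl %/% 10L))
  cgi <- place_intervals(chrom_lengths, config$cgi_count, 600L, 1200L,
                         pad = cgi_pad_bp)
  for (i in seq_len(nrow(cgi))) {
    s <- cgi$start[i]; e <- cgi$end[i]; ch <- cgi$chrom[i]
    seqs[[ch]][(s + 1L):e] <- sample(BASES, e - s, replace = TRUE, prob = CGI_PROBS)
    p <- s
    while (p <= e - 4L) {
      seqs[[ch]][(p + 1L):(p + 4L)] <- c("C", "C", "G", "G")
      p <- p + 4L + sample.int(2L * (CGI_CCGG_SPACING - 4L), 1L)
    }
  }

  cgi_pad <- if (nrow(cgi)) {
    tibble(chrom = cgi$chrom, start = pmax(cgi$start - 4L, 0L), end = cgi$end + 4L)
  } else {
    cgi
  }
  for (ch in chroms) {
    L <- chrom_lengths[[ch]]
    n_est <- ceiling(L / BG_CCGG_SPACING) + 50L
    pos <- cumsum(4L + rpois(n_est, BG_CCGG_SPACING - 4L))
    pos <- pos[pos <= L - 4L]
    if (nrow(cgi_pad)) {
      pos <- pos[!in_intervals(rep(ch, length(pos)), pos, cgi_pad)]
    }
    for (p in pos) seqs[[ch]][(p + 1L):(p + 4L)] <- c("C", "C", "G", "G")
  }

  gene_w_min <- min(2000L, max(800L, cl %/% 10L))
  gene_w_max <- max(gene_w_min + 500L, min(5000L, cl %/% 4L))
  gene_iv <- place_intervals(chrom_lengths, config$gene_count, gene_w_min,
                             gene_w_max, pad = 500L)
  genes <- make_gene_models(gene_iv)
  expression <- tibble(
    gene = genes$name,
    expression = round(2 ^ rnorm(nrow(genes), mean = 6, sd = 2), 3)
  )

  n_peaks_per_mark <- max(1L, round(genome_len / 30000))
  peak_w_max <- max(1200L, min(3000L, cl %/% 8L))
  peak_iv <- place_intervals(chrom_lengths, n_peaks_per_mark * length(config$marks),
                             800L, peak_w_max, pad = 1000L, existing = cgi)
  peak_iv$mark <- rep(config$marks, length.out = nrow(peak_iv))
  peak_iv <- peak_iv |> arrange(.data$mark, .data$chrom, .data$start)

  n_srna <- max(2L, round(genome_len / 30000))
  srna_pad <- min(2200L, max(400L, cl %/% 16L))
  shortrna <- place_intervals(chrom_lengths, n_srna, 100L, 300L, pad = srna_pad,
                              existing = bind_rows(cgi, peak_iv[, 1:3]))

  list(
    genome = vapply(seqs, paste, character(1), collapse = ""),
    annotations = list(
      genes = genes,
      cgi = cgi,
      peaks = peak_iv,
      shortrna = shortrna,
      expression = expression
    )
  )
}

# Carve each placed gene interval into 2-4 exons separated by introns.
make_gene_models <- function(gene_iv) {
  n <- nrow(gene_iv)
  if (n == 0) {
    return(tibble(name = character(), chrom = character(), strand = character(),
                  txStart = integer(), txEnd = integer(),
                  exon_starts = list(), exon_ends = list()))
  }
  exon_starts <- vector("list", n)
  exon_ends <- vector("list", n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  for (i in seq_len(n)) {
    L <- gene_iv$end[i] - gene_iv$start[i]
    k <- sample(2:4, 1L)
    w <- sample(150:400, k, replace = TRUE)
    gap_total <- L - sum(w)
    props <- runif(k - 1L)
    gaps <- floor(props / sum(props) * gap_total)
    gaps[k - 1L] <- gap_total - sum(gaps[-(k - 1L)])
    starts <- gene_iv$start[i] + cumsum(c(0L, head(w, -1L) + gaps))
    exon_starts[[i]] <- as.integer(starts)
    exon_ends[[i]] <- as.integer(starts + w)
  }
  validate_genes(tibble(
    name = sprintf("gene%03d", seq_len(n)),
    chrom = gene_iv$chrom, strand = strand,
    txStart = gene_iv$start, txEnd = gene_iv$end,
    exon_starts = exon_starts, exon_ends = exon_ends
  ))
}

# Strand-aware TSS position (0-based) of each gene.
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$txStart, genes$txEnd - 1L)
}
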