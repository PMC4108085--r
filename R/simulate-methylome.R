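# Ground-truth methylomes. Background site levels follow a bimodal Beta
# mixture (mammalian methylomes are bimodal); CpG islands are strongly
# hypomethylated, shores intermediate, TSS-proximal sites dipped, active
# histone peaks depleted and repressive peaks enriched, short-RNA loci
# and their neighbourhoods hypomethylated. Under every scenario the truth
# is identical across samples until DMRs are planted explicitly.

#' Generate a ground-truth methylome
#'
#' Draws one true methylation level per CCGG site and replicates it across
#' all configured samples. Scenarios: `"null"` (and `"planted_dmr"`, which
#' is the null until [plant_dmrs()] shifts it) and `"expression_coupled"`,
#' where latter-gene-body levels rise with the gene's expression tertile
#' and the TSS dip deepens with expression.
#'
#' @param genome Named character vector of sequences.
#' @param annotations Annotation list from [generate_genome()].
#' @param config An [simulation_config()].
#' @param scenario One of `"null"`, `"planted_dmr"`, `"expression_coupled"`.
#' @param seed Integer seed (defaults to `config$seed + 1`).
#' @param tss_dip Multiplicative TSS dip applied within +-1 kb of a TSS.
#' @param expr_offset Latter-body mean-level offset between top and bottom
#'   expression tertiles under `"expression_coupled"`.
#' @param shore_width Shore width in bp around CpG islands.
#' @return Tibble (`sample`, `site_id`, `chrom`, `pos`, `level`).
#' @export
generate_methylome <- function(genome, annotations, config,
                               scenario = c("null", "planted_dmr",
                                            "expression_coupled"),
                               seed = config$seed + 1L,
                               tss_dip = 0.2, expr_offset = 0.2,
                               shore_width = 2000L) {
  scenario <- tryCatch(match.arg(scenario),
                       error = function(e) abort(paste0(
                         "unknown scenario; use null, planted_dmr or expression_coupled")))
  set.seed(seed)
  sites <- find_ccgg_sites(genome)
  n <- nrow(sites)
  ann <- annotations

  hi <- runif(n) < 0.7
  level <- ifelse(hi, rbeta(n, 8, 2), rbeta(n, 2, 8))

  cgi_d <- interval_distance(sites$chrom, sites$pos, merge_intervals(ann$cgi))
  level[cgi_d == 0] <- rbeta(sum(cgi_d == 0), 1, 12)
  shore <- cgi_d > 0 & cgi_d <= shore_width
  level[shore] <- level[shore] * 0.5

  # strand-aware TSS proximity; under expression coupling the dip deepens
  # with expression (highly expressed genes have the least TSS methylation)
  tss <- tibble(chrom = ann$genes$chrom, pos = gene_tss(ann$genes),
                gene = ann$genes$name)
  near_tss <- rep(NA_character_, n)
  for (i in seq_len(nrow(tss))) {
    hit <- sites$chrom == tss$chrom[i] & abs(sites$pos - tss$pos[i]) <= 1000L
    near_tss[hit] <- tss$gene[i]
  }
  if (scenario == "expression_coupled") {
    tert <- expression_tertiles(ann$expression)
    dipf <- c(`1` = 0.5, `2` = 0.25, `3` = 0.1)  # tertile 3 = highest expression
    gt <- setNames(tert$tertile, tert$gene)
    sel <- !is.na(near_tss)
    level[sel] <- level[sel] * dipf[as.character(gt[near_tss[sel]])]
  } else {
    level[!is.na(near_tss)] <- level[!is.na(near_tss)] * tss_dip
  }

  marks <- intersect(config$marks, unique(ann$peaks$mark))
  if (length(marks) >= 1) {
    act <- in_intervals(sites$chrom, sites$pos,
                        ann$peaks[ann$peaks$mark == marks[1], ])
    level[act] <- level[act] * 0.3
  }
  if (length(marks) >= 2) {
    rep_ <- in_intervals(sites$chrom, sites$pos,
                         ann$peaks[ann$peaks$mark == marks[2], ])
    level[rep_] <- pmin(level[rep_] + 0.2, 1)
  }

  srna_d <- interval_distance(sites$chrom, sites$pos, merge_intervals(ann$shortrna))
  level[srna_d == 0] <- level[srna_d == 0] * 0.25
  near_srna <- srna_d > 0 & srna_d <= 2000
  level[near_srna] <- level[near_srna] * 0.45

  if (scenario == "expression_coupled") {
    rel <- gene_relative_position(sites, ann$genes)
    body2 <- !is.na(rel$rel) & rel$inside & rel$rel >= 0.5
    tert <- expression_tertiles(ann$expression)
    gt <- setNames(tert$tertile, tert$gene)
    t_site <- gt[rel$gene[body2]]
    mu <- 0.45 + expr_offset * (t_site - 2) / 2
    level[body2] <- pmin(pmax(rnorm(sum(body2), mu, 0.05), 0.02), 0.98)
  }

  level <- pmin(pmax(level, 0), 1)
  expand_grid(sample = config$samples, sites) |>
    mutate(level = rep(level, times = length(config$samples))) |>
    arrange(.data$sample, .data$site_id)
}

#' Plant differential methylation into a truth methylome
#'
#' Selects `n_dmrs` disjoint `width_bp` windows that each contain at least
#' `min_sites` CCGG sites and shifts every treated sample's levels by
#' `delta` (clipped to \[0, 1\]) inside them; the baseline sample is left
#' untouched. By default only windows where no member site clips are
#' eligible, so the planted effect size equals the nominal `delta`;
#' set `allow_clipping = TRUE` to plant anywhere.
#'
#' @param truth Methylome tibble from [generate_methylome()].
#' @param n_dmrs Number of regions to plant.
#' @param delta Signed level shift.
#' @param width_bp Region width (default matches the 200-bp analysis window).
#' @param seed Integer seed.
#' @param baseline Untreated sample label.
#' @param min_sites Minimum CCGG sites per planted region.
#' @param allow_clipping Permit regions where `level + delta` clips.
#' @return List with `truth` (shifted tibble) and `dmrs` (tibble `chrom`,
#'   `start`, `end`, `delta`, `n_sites`, `samples`).
#' @export
plant_dmrs <- function(truth, n_dmrs, delta, width_bp = 200L, seed = 1L,
                       baseline = "S0h", min_sites = 4L,
                       allow_clipping = FALSE) {
  stopifnot(abs(delta) <= 1, baseline %in% truth$sample)
  set.seed(seed)
  base <- truth |> filter(.data$sample == baseline)
  cand <- base |>
    mutate(win = .data$pos %/% width_bp) |>
    group_by(.data$chrom, .data$win) |>
    summarise(n_sites = n(),
              clip_free = all(.data$level + delta >= 0 & .data$level + delta <= 1),
              .groups = "drop") |>
    filter(.data$n_sites >= min_sites)
  if (!allow_clipping) cand <- filter(cand, .data$clip_free)
  if (nrow(cand) < n_dmrs) {
    abort(paste0("cannot place ", n_dmrs, " non-overlapping DMRs with >=",
                 min_sites, " sites", if (!allow_clipping) " and no clipping",
                 ": only ", nrow(cand), " eligible windows"))
  }
  pick <- cand[sample.int(nrow(cand), n_dmrs), ]
  dmrs <- tibble(
    chrom = pick$chrom,
    start = as.integer(pick$win * width_bp),
    end = as.integer((pick$win + 1) * width_bp),
    delta = delta, n_sites = pick$n_sites,
    samples = paste(setdiff(unique(truth$sample), baseline), collapse = ",")
  ) |> arrange(.data$chrom, .data$start)
  inside <- in_intervals(truth$chrom, truth$pos, dmrs[, c("chrom", "start", "end")])
  shift <- inside & truth$sample != baseline
  truth$level[shift] <- pmin(pmax(truth$level[shift] + delta, 0), 1)
  list(truth = truth, dmrs = dmrs)
}

#' Simulate dual-library site counts
#'
#' Per (sample, site): total depth ~ Poisson(`mean_depth`); the
#' methylated-library (inverse) count is Binomial(depth, q) with
#' q = p e_I / (p e_I + (1 - p) e_H), where p is the true level and
#' e_H, e_I the HpaII/inverse library efficiencies; the HpaII count is the
#' remainder. Spike-in standard counts are Poisson(`spike_in_mean` x e_L)
#' per sample and library, so biased efficiencies leave their trace in the
#' standards exactly as in the genomic reads.
#'
#' @param truth Methylome tibble (`sample`, `site_id`, `level`).
#' @param config An [simulation_config()].
#' @param seed Integer seed (defaults to `config$seed + 2`).
#' @return List with `counts` (`sample`, `site_id`, `u`, `m`) and
#'   `spike_ins` (`sample`, `library`, `count`).
#' @export
simulate_counts <- function(truth, config, seed = config$seed + 2L) {
  set.seed(seed)
  eH <- config$hpaii_efficiency
  eI <- config$inverse_efficiency
  n <- nrow(truth)
  depth <- rpois(n, config$mean_depth)
  p <- truth$level
  q <- ifelse(p * eI + (1 - p) * eH > 0,
              p * eI / (p * eI + (1 - p) * eH), 0)
  m <- rbinom(n, depth, q)
  counts <- tibble(sample = truth$sample, site_id = truth$site_id,
                   u = depth - m, m = m)
  spike <- expand_grid(sample = unique(truth$sample),
                       library = c("hpaii", "inverse")) |>
    mutate(count = rpois(n(), config$spike_in_mean *
                           ifelse(.data$library == "hpaii", eH, eI)))
  list(counts = counts, spike_ins = spike)
}
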