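# End-to-end orchestration: simulate (optional) -> digest -> map ->
# quantify -> annotate -> differential -> profiles, driven by a single
# validated config, with a checksummed run manifest for reproducibility.

PIPELINE_CONFIG_KEYS <- list(
  top = c("seed", "simulate", "analysis", "inputs"),
  simulate = c("enabled", "scenario", "read_level", "n_dmrs", "dmr_delta",
               "n_chroms", "chrom_length", "cgi_count", "gene_count",
               "mean_depth", "hpaii_efficiency", "inverse_efficiency",
               "spike_in_mean", "seq_error_rate", "samples", "marks"),
  analysis = c("min_depth", "window_width", "min_sites", "delta_cutoff",
               "q_cutoff", "shore_width", "tss_halfwidth", "flank",
               "tag_length", "max_mismatch", "baseline", "scale_constant"),
  inputs = c("fastq", "genome", "genes", "cgi", "peaks", "shortrna",
             "expression", "index_table", "counts", "spike_ins")
)

#' Load and validate a pipeline configuration
#'
#' Reads a YAML pipeline config (or takes a list), fills defaults and
#' rejects unknown keys (typo safety). `simulate.scenario: null` in YAML
#' maps to the null scenario.
#'
#' @param config Path to a YAML file or a config list.
#' @return Validated config list of class `mscc_pipeline_config`.
#' @export
load_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra) > 0) {
      abort(paste0("unknown config key(s) in ", where, ": ",
                   paste(extra, collapse = ", ")))
    }
  }
  check_keys(config, PIPELINE_CONFIG_KEYS$top, "top level")
  check_keys(config$simulate %||% list(), PIPELINE_CONFIG_KEYS$simulate, "simulate")
  check_keys(config$analysis %||% list(), PIPELINE_CONFIG_KEYS$analysis, "analysis")
  check_keys(config$inputs %||% list(), PIPELINE_CONFIG_KEYS$inputs, "inputs")

  sim_defaults <- list(enabled = TRUE, scenario = "null", read_level = FALSE,
                       n_dmrs = 0L, dmr_delta = 0)
  ana_defaults <- list(min_depth = 30L, window_width = 200L, min_sites = 4L,
                       delta_cutoff = 0.25, q_cutoff = 0.05,
                       shore_width = 2000L, tss_halfwidth = 1000L,
                       flank = 2000L, tag_length = 18L, max_mismatch = 1L,
                       baseline = NULL, scale_constant = 1e6)
  sim <- utils::modifyList(sim_defaults, config$simulate %||% list())
  if (is.null(sim$scenario)) sim$scenario <- "null"
  ana <- utils::modifyList(ana_defaults, config$analysis %||% list())
  cfg_fields <- intersect(names(sim), names(formals(simulation_config)))
  out <- list(seed = as.integer(config$seed %||% 1L),
              simulate = sim, analysis = ana,
              inputs = config$inputs %||% list(),
              sim_config_fields = cfg_fields)
  structure(out, class = "mscc_pipeline_config")
}

#' Run the MSCC pipeline end to end
#'
#' Executes simulate (optional) -> digest -> map (when reads are
#' available) -> quantify -> annotate -> differential -> profiles and
#' writes every stage's tables under `outdir`. If a previous run in
#' `outdir` used an identical config and seed and all its outputs are
#' intact (checksums match), the run is skipped and the previous manifest
#' returned. A failing stage aborts with the stage named; files the
#' failing stage had already written are renamed with a `.partial`
#' suffix.
#'
#' @param config Path to a YAML config or a config list
#'   (see [load_pipeline_config()]).
#' @param outdir Output directory (created if needed).
#' @param seed Optional seed override.
#' @param force Re-run even when outputs are current.
#' @return The run manifest: tibble (`stage`, `file`, `rows`, `md5`) with
#'   attributes `seed` and `config_hash`.
#' @export
run_mscc <- function(config, outdir, seed = NULL, force = FALSE) {
  cfg <- load_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  snapshot <- file.path(outdir, "config_snapshot.yaml")
  cfg_hash <- config_hash(cfg)

  manifest_path <- file.path(outdir, "manifest.tsv")
  if (!force && file.exists(manifest_path)) {
    old <- suppressMessages(read_tsv(manifest_path, show_col_types = FALSE,
                                     progress = FALSE))
    old_hash <- attr_from_snapshot(snapshot)
    paths <- file.path(outdir, old$file)
    if (identical(old_hash, cfg_hash) && all(file.exists(paths)) &&
        all(unname(tools::md5sum(paths)) == old$md5)) {
      out <- as_tibble(old)
      attr(out, "seed") <- cfg$seed
      attr(out, "config_hash") <- cfg_hash
      return(out)
    }
  }

  state <- new.env(parent = emptyenv())
  state$manifest <- list()
  state$outdir <- outdir
  state$stage_files <- character()

  emit <- function(name, obj, writer = write_tsv) {
    path <- file.path(state$outdir, name)
    state$stage_files <- c(state$stage_files, path)
    if (identical(writer, write_tsv)) {
      write_tsv(obj, path, progress = FALSE)
      rows <- nrow(obj)
    } else {
      writer(obj, path)
      rows <- length(obj)
    }
    state$manifest[[name]] <- tibble(stage = state$stage, file = name,
                                     rows = rows, md5 = unname(tools::md5sum(path)))
    path
  }
  run_stage <- function(name, fun) {
    state$stage <- name
    state$stage_files <- character()
    tryCatch(fun(), error = function(e) {
      for (f in state$stage_files) {
        if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      }
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  sim <- cfg$simulate
  ana <- cfg$analysis
  inp <- cfg$inputs
  data <- new.env(parent = emptyenv())

  if (isTRUE(sim$enabled)) {
    run_stage("simulate", function() {
      args <- sim[intersect(names(sim), cfg$sim_config_fields)]
      args$seed <- cfg$seed
      scfg <- do.call(simulation_config, args)
      gen <- generate_genome(scfg)
      truth <- generate_methylome(gen$genome, gen$annotations, scfg,
                                  scenario = if (sim$scenario == "expression_coupled")
                                    "expression_coupled" else "null")
      dmrs <- NULL
      if (sim$scenario == "planted_dmr" && sim$n_dmrs > 0) {
        pl <- plant_dmrs(truth, sim$n_dmrs, sim$dmr_delta,
                         width_bp = ana$window_width, seed = cfg$seed + 3L,
                         baseline = scfg$samples[1], min_sites = ana$min_sites)
        truth <- pl$truth
        dmrs <- pl$dmrs
      }
      counts <- simulate_counts(truth, scfg, seed = cfg$seed + 4L)
      emit("genome.fasta", gen$genome, write_genome)
      emit("genes.tsv", gen$annotations$genes, function(o, p) write_genes(o, p))
      emit("cgi.bed", gen$annotations$cgi, function(o, p) write_bed(o, p))
      emit("peaks.bed",
           gen$annotations$peaks |> mutate(name = .data$mark) |>
             select("chrom", "start", "end", "name"),
           function(o, p) write_bed(o, p))
      emit("shortrna.bed", gen$annotations$shortrna, function(o, p) write_bed(o, p))
      emit("expression.tsv", gen$annotations$expression)
      emit("truth.tsv.gz", truth |> mutate(level = signif(.data$level, 6)))
      if (!is.null(dmrs)) emit("dmr_truth.tsv", dmrs)
      emit("sim_counts.tsv.gz", counts$counts)
      emit("sim_spike_ins.tsv", counts$spike_ins)
      data$scfg <- scfg
      data$samples <- scfg$samples
      if (isTRUE(sim$read_level)) {
        sites <- find_ccgg_sites(gen$genome)
        lib <- build_tag_library(gen$genome, sites, ana$tag_length)
        lib <- add_standard_tags(lib, seed = cfg$seed + 5L)
        itab <- make_index_table(scfg$samples)
        rd <- simulate_reads(counts, lib, itab, scfg$seq_error_rate,
                             seed = cfg$seed + 6L)
        emit("index_table.tsv", itab)
        emit("reads.fastq.gz", rd$reads, function(o, p) write_mscc_fastq(o, p))
        emit("read_ledger.tsv", rd$ledger)
        data$standards <- lib$standards
      }
      invisible(NULL)
    })
  }

  path_of <- function(name, input_key) {
    p <- file.path(outdir, name)
    if (file.exists(p)) p else inp[[input_key]] %||%
      abort(paste0("no ", input_key, " available: not simulated and not in inputs"))
  }

  run_stage("digest", function() {
    genome <- read_genome(path_of("genome.fasta", "genome"))
    sites <- find_ccgg_sites(genome)
    lib <- build_tag_library(genome, sites, ana$tag_length)
    if (!is.null(data$standards)) lib$standards <- data$standards
    emit("sites.tsv", sites)
    emit("tag_library.tsv", lib$tags)
    emit("ambiguous_tags.tsv", tibble(tag = lib$ambiguous))
    data$genome <- genome
    data$sites <- sites
    data$lib <- lib
    invisible(NULL)
  })

  run_stage("map", function() {
    fastq <- if (file.exists(file.path(outdir, "reads.fastq.gz"))) {
      file.path(outdir, "reads.fastq.gz")
    } else {
      inp$fastq
    }
    if (!is.null(fastq)) {
      reads <- read_mscc_fastq(fastq)
      itab_path <- path_of("index_table.tsv", "index_table")
      itab <- read_tsv(itab_path, show_col_types = FALSE, progress = FALSE)
      streams <- demultiplex(reads, itab)
      res <- count_tags(streams, data$lib, ana$max_mismatch)
      emit("counts.tsv.gz", res$counts)
      emit("spike_ins.tsv", res$spike_ins)
      emit("mapping_report.tsv", res$report)
      data$counts <- res$counts
      data$spike_ins <- res$spike_ins
    } else if (file.exists(file.path(outdir, "sim_counts.tsv.gz"))) {
      data$counts <- read_tsv(file.path(outdir, "sim_counts.tsv.gz"),
                              show_col_types = FALSE, progress = FALSE)
      data$spike_ins <- read_tsv(file.path(outdir, "sim_spike_ins.tsv"),
                                 show_col_types = FALSE, progress = FALSE)
    } else {
      data$counts <- read_tsv(inp$counts %||%
                                abort("no reads and no counts available"),
                              show_col_types = FALSE, progress = FALSE)
      data$spike_ins <- read_tsv(inp$spike_ins %||%
                                   abort("counts without spike_ins"),
                                 show_col_types = FALSE, progress = FALSE)
    }
    invisible(NULL)
  })

  run_stage("quantify", function() {
    calls <- normalize_and_call(data$counts, data$spike_ins, data$sites,
                                min_depth = ana$min_depth,
                                scale_constant = ana$scale_constant)
    emit("calls.tsv.gz", calls |> mutate(level = signif(.data$level, 6)))
    chrom <- chromosome_summary(calls, data$sites)
    emit("chromosome_summary.tsv", as_tibble(chrom))
    data$calls <- calls
    invisible(NULL)
  })

  ann <- new.env(parent = emptyenv())
  run_stage("annotate", function() {
    genes <- read_genes(path_of("genes.tsv", "genes"))
    cgi <- read_bed(path_of("cgi.bed", "cgi"))
    gene_ctx <- classify_gene_context(data$sites, genes, ana$tss_halfwidth,
                                      ana$flank)
    cgi_ctx <- classify_cgi_context(data$sites, cgi, ana$shore_width)
    annotation <- left_join(gene_ctx, cgi_ctx, by = "site_id")
    emit("site_annotation.tsv", annotation)
    emit("cgi_stratum_means.tsv",
         stratum_means(data$calls, cgi_ctx, "cgi_context"))
    emit("gene_stratum_means.tsv",
         stratum_means(data$calls, gene_ctx, "gene_context"))
    ann$genes <- genes
    ann$cgi <- cgi
    invisible(NULL)
  })

  base_sample <- ana$baseline %||% unique(data$counts$sample)[1]

  run_stage("differential", function() {
    units <- bind_rows(make_windows(data$genome, ana$window_width),
                       cgi_units(ann$cgi))
    dmr <- compare_all_units(units, data$calls, baseline = base_sample,
                             delta_cutoff = ana$delta_cutoff,
                             q_cutoff = ana$q_cutoff,
                             min_sites = ana$min_sites)
    emit("unit_comparisons.tsv",
         dmr$comparisons |> mutate(across(c("mean_a", "mean_b", "delta", "p", "q"),
                                          ~ signif(.x, 6))))
    emit("dmr_calls.tsv", dmr$calls)
    sc <- site_level_consistency(data$calls, baseline = base_sample,
                                 delta_cutoff = ana$delta_cutoff)
    emit("site_consistency.tsv",
         tibble(n_eligible = sc$n_eligible, n_flagged = sc$n_flagged,
                fraction = sc$fraction, n_excluded = sc$n_excluded))
    invisible(NULL)
  })

  run_stage("profiles", function() {
    base_calls <- data$calls |> filter(.data$sample == base_sample)
    prof <- metagene_profile(base_calls, ann$genes)
    emit("metagene.tsv", as_tibble(prof))
    expr_path <- path_of("expression.tsv", "expression")
    expr <- read_tsv(expr_path, show_col_types = FALSE, progress = FALSE)
    tp <- expression_tertile_profiles(base_calls, ann$genes, expr,
                                      ana$tss_halfwidth)
    emit("tertile_profiles.tsv", tp$profiles)
    emit("tertile_contrast.tsv", tp$contrast)
    peaks_bed <- read_bed(path_of("peaks.bed", "peaks"))
    if ("name" %in% names(peaks_bed)) peaks_bed$mark <- peaks_bed$name
    emit("peak_overlap.tsv", peak_overlap_summary(base_calls, peaks_bed))
    srna <- read_bed(path_of("shortrna.bed", "shortrna"))
    emit("shortrna_proximity.tsv",
         shortrna_proximity_summary(base_calls, srna, ana$flank))
    invisible(NULL)
  })

  manifest <- list_rbind(unname(state$manifest))
  write_tsv(manifest, manifest_path, progress = FALSE)
  yaml::write_yaml(list(config_hash = cfg_hash, seed = cfg$seed,
                        version = as.character(utils::packageVersion("msccr")),
                        config = unclass(cfg)),
                   snapshot)
  attr(manifest, "seed") <- cfg$seed
  attr(manifest, "config_hash") <- cfg_hash
  manifest
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

attr_from_snapshot <- function(snapshot) {
  if (!file.exists(snapshot)) return(NA_character_)
  (yaml::read_yaml(snapshot)$config_hash) %||% NA_character_
}

#' Generate a bundled fixture set
#'
#' Runs the pipeline under a named preset and leaves all stage outputs
#' (genome, annotations, truth, optionally reads, and summary tables) in
#' `dir`.
#'
#' Presets: `tiny` (one small chromosome, read-level simulation,
#' seconds to run), `null_emt` (five samples from one methylome, no true
#' differences), `planted_dmr` (20 planted DMRs, delta +0.4),
#' `expression_coupled` (gene-body methylation coupled to expression
#' tertile).
#'
#' @param preset Preset name.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return The run manifest, invisibly.
#' @export
make_fixtures <- function(preset = c("tiny", "null_emt", "planted_dmr",
                                     "expression_coupled"),
                          dir = tempfile("fixtures_"), seed = 1L) {
  preset <- tryCatch(match.arg(preset), error = function(e) {
    abort(paste0("unknown preset; available: tiny, null_emt, planted_dmr, ",
                 "expression_coupled"))
  })
  cfg <- switch(preset,
    tiny = list(seed = seed,
                simulate = list(enabled = TRUE, scenario = "null",
                                read_level = TRUE, n_chroms = 1L,
                                chrom_length = 12000L, cgi_count = 2L,
                                gene_count = 3L, mean_depth = 5,
                                spike_in_mean = 50, seq_error_rate = 0.001),
                analysis = list(min_depth = 3L)),
    null_emt = list(seed = seed,
                    simulate = list(enabled = TRUE, scenario = "null",
                                    n_chroms = 3L, chrom_length = 100000L,
                                    mean_depth = 50)),
    planted_dmr = list(seed = seed,
                       simulate = list(enabled = TRUE, scenario = "planted_dmr",
                                       n_dmrs = 20L, dmr_delta = 0.4,
                                       n_chroms = 3L, chrom_length = 100000L,
                                       mean_depth = 50)),
    expression_coupled = list(seed = seed,
                              simulate = list(enabled = TRUE,
                                              scenario = "expression_coupled",
                                              n_chroms = 3L,
                                              chrom_length = 100000L,
                                              mean_depth = 50))
  )
  invisible(run_mscc(cfg, dir))
}
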