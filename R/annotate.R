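# Genomic context of quantified sites: gene-feature class and CGI/shore
# class. One label per axis per site, resolved by a fixed precedence so
# multi-gene overlaps are deterministic.

GENE_CONTEXTS <- c("tss_region", "exon", "intron", "upstream", "downstream",
                   "intergenic")

#' Classify sites by gene context
#'
#' Labels every site with one of `tss_region`, `exon`, `intron`,
#' `upstream`, `downstream`, `intergenic`. When a site hits several genes
#' the label with the highest precedence (the order above) wins.
#' `tss_region` is +-`tss_halfwidth` bp of the strand-aware TSS;
#' `upstream`/`downstream` extend `flank` bp beyond the transcript,
#' strand-aware.
#'
#' @param sites Tibble (`site_id`, `chrom`, `pos`).
#' @param genes Gene tibble (see [read_genes()]).
#' @param tss_halfwidth Half-width of the TSS window in bp.
#' @param flank Upstream/downstream flank width in bp.
#' @return Tibble (`site_id`, `gene_context`, `nearest_gene`,
#'   `distance` to the nearest transcript, 0 if inside).
#' @export
classify_gene_context <- function(sites, genes, tss_halfwidth = 1000L,
                                  flank = 2000L) {
  validate_genes(genes)
  n <- nrow(sites)
  rank <- rep(length(GENE_CONTEXTS), n)  # intergenic
  nearest <- rep(NA_character_, n)
  nearest_d <- rep(Inf, n)
  tss <- gene_tss(genes)
  for (g in seq_len(nrow(genes))) {
    on <- which(sites$chrom == genes$chrom[g])
    if (length(on) == 0) next
    p <- sites$pos[on]
    t0 <- genes$txStart[g]; t1 <- genes$txEnd[g]
    d <- pmax(t0 - p, p - (t1 - 1L), 0L)
    upd <- d < nearest_d[on]
    nearest[on[upd]] <- genes$name[g]
    nearest_d[on[upd]] <- d[upd]

    lab <- rep(NA_integer_, length(on))
    inside <- p >= t0 & p < t1
    in_exon <- rep(FALSE, length(on))
    es <- genes$exon_starts[[g]]; ee <- genes$exon_ends[[g]]
    for (k in seq_along(es)) in_exon <- in_exon | (p >= es[k] & p < ee[k])
    before <- p < t0; after <- p >= t1
    if (genes$strand[g] == "+") {
      up <- before & p >= t0 - flank
      down <- after & p < t1 + flank
    } else {
      up <- after & p < t1 + flank
      down <- before & p >= t0 - flank
    }
    lab[down] <- 5L
    lab[up] <- 4L
    lab[inside & !in_exon] <- 3L
    lab[inside & in_exon] <- 2L
    lab[abs(p - tss[g]) <= tss_halfwidth] <- 1L
    hit <- !is.na(lab)
    rank[on[hit]] <- pmin(rank[on[hit]], lab[hit])
  }
  tibble(site_id = sites$site_id,
         gene_context = factor(GENE_CONTEXTS[rank], levels = GENE_CONTEXTS),
         nearest_gene = nearest,
         distance = ifelse(is.finite(nearest_d), nearest_d, NA_real_))
}

#' Classify sites by CGI context
#'
#' `cgi` if the site lies inside a (merged) CGI interval, `shore` if its
#' distance to the nearest CGI base is between 1 and `shore_width` bp
#' (boundary inclusive), else `open_sea`.
#'
#' @param sites Tibble (`site_id`, `chrom`, `pos`).
#' @param cgi CGI interval tibble (`chrom`, `start`, `end`).
#' @param shore_width Shore width in bp.
#' @return Tibble (`site_id`, `cgi_context`).
#' @export
classify_cgi_context <- function(sites, cgi, shore_width = 2000L) {
  d <- interval_distance(sites$chrom, sites$pos, merge_intervals(cgi))
  ctx <- ifelse(d == 0, "cgi", ifelse(d <= shore_width, "shore", "open_sea"))
  tibble(site_id = sites$site_id,
         cgi_context = factor(ctx, levels = c("cgi", "shore", "open_sea")))
}

#' Mean methylation per annotation class
#'
#' Unweighted mean call level and site count per class of the given
#' annotation axis. Classes with no quantified site are reported with an
#' `NA` mean and count 0.
#'
#' @param calls Call tibble (`site_id`, `level`).
#' @param annotation Annotation tibble containing `site_id` and the class
#'   column.
#' @param class_col Name of the class column (e.g. `"cgi_context"`).
#' @return Tibble (`class`, `n`, `mean_level`).
#' @export
stratum_means <- function(calls, annotation, class_col = "cgi_context") {
  stopifnot(class_col %in% names(annotation))
  joined <- inner_join(calls, annotation[, c("site_id", class_col)],
                       by = "site_id")
  lv <- joined[[class_col]]
  levels_all <- if (is.factor(annotation[[class_col]])) {
    levels(annotation[[class_col]])
  } else {
    sort(unique(annotation[[class_col]]))
  }
  tibble(class = levels_all) |>
    left_join(
      joined |> group_by(class = as.character(.data[[class_col]])) |>
        summarise(n = n(), mean_level = mean(.data$level), .groups = "drop"),
      by = "class"
    ) |>
    mutate(n = ifelse(is.na(.data$n), 0L, as.integer(.data$n)))
}
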