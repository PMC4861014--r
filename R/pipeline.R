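#' Build a resolved pipeline configuration
#'
#' Collects every stage parameter with the analysis defaults (200-bp bins,
#' 10-count bin filter, dual chi-square alpha 0.01, 200/100-bp profile
#' windows, correlation threshold 0.7, adjusted-p 0.05) plus input paths
#' or simulation settings. The resolved configuration is written alongside
#' every run so a run can be reproduced from its record.
#'
#' @param out_dir Output directory for the run.
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param simulate Generate synthetic inputs instead of reading paths.
#' @param inputs Named list of input paths (used when `simulate = FALSE`):
#'   methylome_wt1/wt2/sulf1/sulf2, srna_counts, srna_design,
#'   expression_matrix, expression_de, expression_annotation, qpcr.
#' @param bin_size,min_total,alpha Methylome stage parameters.
#' @param window,step Profile stage parameters.
#' @param r_threshold,min_effect,padj Expression stage parameters.
#' @param boundary S-locus boundary (bp) for the candidate filter.
#' @param srna_min_total Normalization subset threshold.
#' @param srna_mode Poisson test mode (`"literal"` or `"offset"`).
#' @param regions Named list of region-test intervals, each
#'   `list(chrom=, start=, end=)` (0-based half-open); defaults to the
#'   planted regions in simulate mode.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = "paramut_run", seed = 1L, simulate = TRUE,
                       inputs = list(), bin_size = 200, min_total = 10,
                       alpha = 0.01, window = 200, step = 100,
                       r_threshold = 0.7, min_effect = 0.5, padj = 0.05,
                       boundary = 3.5e7, srna_min_total = 10,
                       srna_mode = "literal", regions = NULL) {
  stopifnot(bin_size > 0, min_total >= 0, alpha > 0, alpha < 1,
            window >= step, step > 0, padj > 0, padj <= 1,
            srna_mode %in% c("literal", "offset"))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs, bin_size = bin_size,
                 min_total = min_total, alpha = alpha, window = window,
                 step = step, r_threshold = r_threshold,
                 min_effect = min_effect, padj = padj, boundary = boundary,
                 srna_min_total = srna_min_total, srna_mode = srna_mode,
                 regions = regions),
            class = "run_config")
}

# deterministic sub-seed, kept inside the 32-bit integer range
.derive_seed <- function(seed, k) as.integer((seed * 1009 + k) %% 2147483647)

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.need_input <- function(config, key) {
  path <- config$inputs[[key]]
  if (is.null(path) || !file.exists(path))
    stop("missing input '", key, "' (path: ",
         if (is.null(path)) "<unset>" else path, ")")
  path
}

#' Default simulated methylome for the pipeline
#'
#' One 200-kb chromosome "2" carrying two adjacent planted regions shaped
#' like the promoter DMRs: a 727-bp region hypermethylated in sulf in all
#' contexts (wt CG 24%, CHG 4%, CHH 0.7%; sulf CG 73%, CHG 62%, CHH 4%)
#' and, directly upstream, a 400-bp repeat-like region hypomethylated in
#' sulf in CHG and CHH (wt CG 96%, CHG 93%, CHH 27%; sulf CG 95%, CHG 78%,
#' CHH 4%), at about 5x depth.
#'
#' @param seed Integer seed.
#' @param chrom_length Chromosome length in bp.
#' @param mean_depth Expected calls per cytosine.
#' @return A [methylome_sim_spec()].
#' @export
default_methylome_spec <- function(seed = 1L, chrom_length = 2e5,
                                   mean_depth = 5) {
  dmr1 <- planted_region(1e5, 1e5 + 727, list(
    CG = c(wt = 0.24, sulf = 0.73),
    CHG = c(wt = 0.04, sulf = 0.62),
    CHH = c(wt = 0.007, sulf = 0.04)))
  dmr2 <- planted_region(1e5 - 600, 1e5 - 200, list(
    CG = c(wt = 0.96, sulf = 0.95),
    CHG = c(wt = 0.93, sulf = 0.78),
    CHH = c(wt = 0.27, sulf = 0.04)))
  methylome_sim_spec(chrom_name = "2", chrom_length = chrom_length,
                     planted_regions = list(dmr1, dmr2),
                     mean_depth = mean_depth, seed = seed)
}

#' Run the full pipeline
#'
#' Executes (optionally) simulation, then DMR calling, region tests,
#' sliding-window profiles, the sRNA TMM + Poisson stage, expression
#' clustering and candidate triage, and the qPCR assays, writing one or
#' more TSV summaries per stage plus a resolved-config YAML and a run log
#' into `config$out_dir`. Any stage failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  wtsv <- function(df, name) utils::write.table(
    df, out(name), sep = "\t", quote = FALSE, row.names = FALSE)
  results <- list()
  seed <- config$seed

  # resolved configuration record
  cfg_record <- unclass(config)
  cfg_record$package_version <- as.character(utils::packageVersion("paramut"))
  cfg_record$r_version <- R.version.string
  yaml::write_yaml(cfg_record, out("resolved_config.yaml"))

  if (config$simulate) {
    .stage("simulate", {
      mspec <- default_methylome_spec(seed = .derive_seed(seed, 1))
      reports <- list(
        wt1 = simulate_cytosine_report(mspec, "wt", .derive_seed(seed, 11)),
        wt2 = simulate_cytosine_report(mspec, "wt", .derive_seed(seed, 12)),
        sulf1 = simulate_cytosine_report(mspec, "sulf", .derive_seed(seed, 13)),
        sulf2 = simulate_cytosine_report(mspec, "sulf", .derive_seed(seed, 14)))
      for (nm in names(reports))
        write_cytosine_report(reports[[nm]], out(paste0("methylome_", nm, ".cx.tsv")))
      write_planted_regions_bed(mspec, out("planted_regions.bed"))

      sspec <- srna_sim_spec(seed = .derive_seed(seed, 2))
      srna <- simulate_srna_counts(sspec)
      write_count_matrix(srna$counts, out("srna_counts.tsv"))
      wtsv(data.frame(library = colnames(srna$counts),
                      genotype = as.character(srna$genotype)),
           "srna_design.tsv")
      wtsv(srna$truth, "srna_truth.tsv")

      espec <- expression_sim_spec(seed = .derive_seed(seed, 3))
      expr <- simulate_expression(espec)
      write_count_matrix(round(expr$matrix, 6), out("expression_log2.tsv"),
                         id_name = "gene")
      wtsv(expr$de, "expression_de.tsv")
      wtsv(expr$annotation, "expression_annotation.tsv")

      cq <- simulate_qpcr_cq(seed = .derive_seed(seed, 4))
      wtsv(cq, "qpcr_cq.tsv")

      results$simulate <- list(spec = mspec, reports = reports,
                                srna = srna, expr = expr, cq = cq)
    })
    mspec <- results$simulate$spec
    reports <- results$simulate$reports
    srna_counts <- results$simulate$srna$counts
    srna_genotype <- results$simulate$srna$genotype
    expr_mat <- results$simulate$expr$matrix
    expr_genotype <- results$simulate$expr$genotype
    de <- results$simulate$expr$de
    ann <- results$simulate$expr$annotation
    cq <- results$simulate$cq
    boundary <- results$simulate$expr$s_locus_boundary
    regions <- config$regions
    if (is.null(regions))
      regions <- stats::setNames(
        lapply(mspec$planted_regions, function(r)
          list(chrom = mspec$chrom_name, start = r$start, end = r$end)),
        paste0("planted_", seq_along(mspec$planted_regions)))
  } else {
    reports <- .stage("read-inputs", lapply(
      c(wt1 = "methylome_wt1", wt2 = "methylome_wt2",
        sulf1 = "methylome_sulf1", sulf2 = "methylome_sulf2"),
      function(k) read_cytosine_report(.need_input(config, k))))
    srna_counts <- .stage("read-inputs",
                          read_count_matrix(.need_input(config, "srna_counts")))
    design <- .stage("read-inputs", utils::read.table(
      .need_input(config, "srna_design"), sep = "\t", header = TRUE,
      stringsAsFactors = FALSE))
    srna_genotype <- factor(design$genotype[match(colnames(srna_counts),
                                                  design$library)],
                            levels = c("wt", "sulf/+", "sulf"))
    expr_mat <- .stage("read-inputs", read_count_matrix(
      .need_input(config, "expression_matrix")))
    expr_genotype <- NULL
    if (!is.null(config$inputs$expression_design)) {
      ed <- utils::read.table(config$inputs$expression_design, sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
      expr_genotype <- factor(ed$genotype[match(colnames(expr_mat), ed$sample)],
                              levels = c("wt", "sulf/+", "sulf"))
    }
    de <- .stage("read-inputs", utils::read.table(
      .need_input(config, "expression_de"), sep = "\t", header = TRUE,
      stringsAsFactors = FALSE))
    ann <- .stage("read-inputs", utils::read.table(
      .need_input(config, "expression_annotation"), sep = "\t", header = TRUE,
      stringsAsFactors = FALSE))
    cq <- .stage("read-inputs", read_cq_table(.need_input(config, "qpcr")))
    boundary <- config$boundary
    regions <- config$regions
  }

  .stage("dmr-call", {
    bins <- lapply(reports, bin_counts, bin_size = config$bin_size)
    calls <- call_dmrs(bins$wt1, bins$sulf1, bins$wt2, bins$sulf2,
                       alpha = config$alpha, min_total = config$min_total)
    wtsv(calls, "dmr_bins.tsv")
    write_dmr_bed(calls, out("dmrs.bed"))
    wtsv(classify_dmrs(calls), "dmr_summary.tsv")
    results$dmr <- calls
  })

  if (!is.null(regions) && length(regions)) .stage("region-test", {
    rows <- list()
    genotype <- c(wt1 = "wt", wt2 = "wt", sulf1 = "sulf", sulf2 = "sulf")
    for (rn in names(regions)) {
      r <- regions[[rn]]
      for (ctx in c("CG", "CHG", "CHH")) {
        agg <- vapply(names(genotype), function(s) {
          rec <- reports[[s]]
          keep <- rec$context == ctx & rec$chrom == r$chrom &
            (rec$pos - 1L) >= r$start & (rec$pos - 1L) < r$end
          c(sum(rec$meth[keep]), sum(rec$unmeth[keep]))
        }, numeric(2))
        if (sum(agg) == 0) next
        tst <- region_glm_test(agg[1, ], agg[2, ], genotype,
                               region = rn, context = ctx)
        rows[[length(rows) + 1L]] <- data.frame(
          region = rn, chrom = r$chrom, start = r$start, end = r$end,
          context = ctx, t(tst$levels), p_value = tst$p_value,
          stringsAsFactors = FALSE)
      }
    }
    rt <- do.call(rbind, rows)
    wtsv(rt, "region_tests.tsv")
    results$region_tests <- rt
  })

  .stage("profile", {
    pool <- function(samples) do.call(rbind, reports[samples])
    prof <- rbind(cbind(genotype = "wt",
                        sliding_window_profile(pool(c("wt1", "wt2")),
                                               config$window, config$step)),
                  cbind(genotype = "sulf",
                        sliding_window_profile(pool(c("sulf1", "sulf2")),
                                               config$window, config$step)))
    wtsv(prof, "profiles.tsv")
    results$profile <- prof
  })

  .stage("srna-test", {
    st <- srna_test_all(srna_counts, srna_genotype,
                        min_total = config$srna_min_total,
                        mode = config$srna_mode)
    wtsv(data.frame(library = names(st$norm$factors),
                    tmm_factor = unname(st$norm$factors),
                    effective_size = unname(st$norm$effective_sizes)),
         "srna_factors.tsv")
    wtsv(st$tests, "srna_tests.tsv")
    results$srna <- st
  })

  .stage("cluster-expression", {
    de_genes <- de$gene[de$padj < config$padj]
    de_genes <- intersect(de_genes, rownames(expr_mat))
    if (length(de_genes) >= 2) {
      cl <- correlation_cluster(expr_mat[de_genes, , drop = FALSE],
                                r_threshold = config$r_threshold)
      wtsv(cl, "expression_clusters.tsv")
      if (!is.null(expr_genotype)) {
        cat_tab <- assign_categories(expr_mat[de_genes, , drop = FALSE], cl,
                                     expr_genotype,
                                     min_effect = config$min_effect)
        cl$category <- cat_tab$category[match(cl$cluster, cat_tab$cluster)]
        wtsv(cat_tab, "expression_categories.tsv")
        wtsv(cl, "expression_clusters.tsv")
        results$categories <- cat_tab
      }
      results$clusters <- cl
    }
  })

  .stage("candidates", {
    cand <- positional_candidate_filter(de, ann, boundary = boundary,
                                        padj_max = config$padj)
    wtsv(cand, "candidates.tsv")
    results$candidates <- cand
  })

  .stage("assays", {
    per_sample <- lapply(split(cq, cq$sample), function(d) {
      data.frame(sample = d$sample[1],
                 genotype = if ("genotype" %in% names(d)) d$genotype[1] else NA,
                 rel_expr = qpcr_relative_expression(
                   d$cq[d$target == "target"],
                   d$cq[d$target == "TIP41"],
                   d$cq[d$target == "EXPRESSED"]),
                 stringsAsFactors = FALSE)
    })
    abund <- do.call(rbind, per_sample)
    rownames(abund) <- NULL
    wtsv(abund, "qpcr_expression.tsv")
    results$qpcr <- abund
    if (all(c("wt", "sulf") %in% abund$genotype)) {
      ft <- fold_change_ttest(abund$rel_expr[abund$genotype == "wt"],
                              abund$rel_expr[abund$genotype == "sulf"])
      wtsv(data.frame(comparison = "wt_vs_sulf", fold = ft$fold,
                      p_value = ft$p_value), "qpcr_fold.tsv")
      results$qpcr_fold <- ft
    }
  })

  # run log (deterministic: no timestamps, so same-seed runs are identical)
  writeLines(c(
    paste0("paramut ", utils::packageVersion("paramut"), " on ",
           R.version.string),
    paste0("seed: ", config$seed),
    paste0("parameters: bin_size=", config$bin_size,
           " min_total=", config$min_total, " alpha=", config$alpha,
           " window=", config$window, " step=", config$step,
           " r_threshold=", config$r_threshold, " padj=", config$padj,
           " boundary=", config$boundary),
    paste0("stages: ", paste(names(results), collapse = ", "))),
    out("run_log.txt"))
  invisible(results)
}
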