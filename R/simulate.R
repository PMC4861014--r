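#' Place cytosine sites along a synthetic chromosome
#'
#' Sites arise from a homogeneous Bernoulli process per context and strand:
#' each strand carries an expected `context_density/2` sites per bp for each
#' context, and a position holds at most one context per strand.
#'
#' @param spec A [methylome_sim_spec()].
#' @return A data.frame with columns `pos` (1-based), `strand` (`+`/`-`)
#'   and `context`, sorted by position then strand. Zero length or zero
#'   density gives zero rows.
#' @export
simulate_cytosine_sites <- function(spec) {
  stopifnot(inherits(spec, "methylome_sim_spec"))
  L <- spec$chrom_length
  empty <- data.frame(pos = integer(), strand = character(),
                      context = character(), stringsAsFactors = FALSE)
  if (L == 0L || sum(spec$context_density) == 0) return(empty)
  set.seed(spec$seed)
  ctx <- c("CG", "CHG", "CHH")
  per_strand <- function(strand) {
    n_ctx <- vapply(ctx, function(k)
      stats::rbinom(1L, L, spec$context_density[[k]] / 2), integer(1))
    ntot <- sum(n_ctx)
    if (ntot == 0L) return(empty)
    pos <- sample.int(L, ntot)         # distinct positions on this strand
    data.frame(pos = pos, strand = strand,
               context = rep(ctx, n_ctx), stringsAsFactors = FALSE)
  }
  out <- rbind(per_strand("+"), per_strand("-"))
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a per-cytosine methylation call report for one genotype
#'
#' Site placement is controlled by `spec$seed` so that every genotype and
#' replicate shares the same genome; count sampling is controlled by `seed`.
#' Per site, the number of calls is Poisson(`mean_depth`) and the number of
#' methylated calls is beta-binomial with mean equal to the site's
#' methylation probability (planted level inside a planted region for this
#' genotype, background otherwise) and dispersion `overdispersion`;
#' dispersion 0 degenerates to plain binomial sampling.
#'
#' @param spec A [methylome_sim_spec()].
#' @param genotype `"wt"` or `"sulf"` (any label present in the planted
#'   regions' level tables is accepted).
#' @param seed Integer seed for depth and methylation sampling; defaults to
#'   `spec$seed` so a bare call is reproducible.
#' @return A data.frame of cytosine records: `chrom`, `pos` (1-based),
#'   `strand`, `meth`, `unmeth`, `context`. One row per simulated site.
#' @export
simulate_cytosine_report <- function(spec, genotype = "wt", seed = spec$seed) {
  stopifnot(inherits(spec, "methylome_sim_spec"), length(genotype) == 1L)
  sites <- simulate_cytosine_sites(spec)
  n <- nrow(sites)
  level <- unname(spec$background_level[sites$context])
  for (r in spec$planted_regions) {
    for (ctx in names(r$levels)) {
      p <- r$levels[[ctx]]
      if (!genotype %in% names(p))
        stop("planted region defines no level for genotype '", genotype,
             "' in context ", ctx)
      hit <- sites$context == ctx &
        (sites$pos - 1L) >= r$start & (sites$pos - 1L) < r$end
      level[hit] <- p[[genotype]]
    }
  }
  set.seed(seed)
  total <- stats::rpois(n, spec$mean_depth)
  rho <- spec$overdispersion
  if (n == 0L) {
    meth <- integer(0)
  } else if (rho == 0) {
    meth <- stats::rbinom(n, total, level)
  } else {
    # mean/dispersion parameterization: a = p(1-rho)/rho, b = (1-p)(1-rho)/rho
    p <- level
    fixed <- p <= 0 | p >= 1          # rbeta degenerates at the boundary
    pdraw <- p
    if (any(!fixed)) {
      a <- p[!fixed] * (1 - rho) / rho
      b <- (1 - p[!fixed]) * (1 - rho) / rho
      pdraw[!fixed] <- stats::rbeta(sum(!fixed), a, b)
    }
    meth <- stats::rbinom(n, total, pdraw)
  }
  data.frame(chrom = rep(spec$chrom_name, n), pos = sites$pos,
             strand = sites$strand, meth = meth, unmeth = total - meth,
             context = sites$context, stringsAsFactors = FALSE)
}

#' Simulate a small RNA locus count matrix with genotype structure
#'
#' Counts are independent Poisson with mean
#' `library_size * baseline_mean * fold(locus, genotype)`.
#'
#' @param spec An [srna_sim_spec()].
#' @return A list with `counts` (locus x library integer matrix),
#'   `genotype` (factor over libraries with levels wt, sulf/+, sulf), and
#'   `truth` (data.frame of the planted per-genotype folds for every locus).
#' @export
simulate_srna_counts <- function(spec) {
  stopifnot(inherits(spec, "srna_sim_spec"))
  set.seed(spec$seed)
  loci <- sprintf("locus_%04d", seq_len(spec$n_loci))
  libs <- names(spec$library_sizes)
  fold <- matrix(1, nrow = spec$n_loci, ncol = 3,
                 dimnames = list(loci, c("wt", "sulf/+", "sulf")))
  for (nm in names(spec$effect_loci)) {
    if (!nm %in% loci) stop("effect locus '", nm, "' not in the locus set")
    f <- spec$effect_loci[[nm]]
    fold[nm, names(f)] <- f
  }
  mu <- fold[, spec$genotype_design, drop = FALSE] *
    rep(spec$library_sizes, each = spec$n_loci) * spec$baseline_mean
  counts <- matrix(stats::rpois(length(mu), mu), nrow = spec$n_loci,
                   dimnames = list(loci, libs))
  truth <- data.frame(locus = loci, fold_wt = fold[, "wt"],
                      fold_het = fold[, "sulf/+"], fold_sulf = fold[, "sulf"],
                      row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts,
       genotype = factor(spec$genotype_design[libs],
                         levels = c("wt", "sulf/+", "sulf")),
       truth = truth)
}

#' Simulate an expression class structure with annotation and DE table
#'
#' Emits the log2 library-normalized, per-gene median-centered matrix the
#' clustering step consumes, a differential-expression table (log2
#' fold-change wt over sulf, with Welch-t Benjamini-Hochberg adjusted
#' p-values computed from the simulated matrix), a positional annotation,
#' and the planted class labels. Genes are scattered uniformly over the
#' planned chromosomes; class I/II genes (down in sulf) are enriched on
#' chromosome 2 so that the positional filter has candidates to find.
#'
#' @param spec An [expression_sim_spec()].
#' @return A list with `matrix` (gene x sample), `genotype` (factor over
#'   samples), `de` (gene, log2fc, padj), `annotation` (gene, chrom, start,
#'   end, strand; 0-based half-open), `s_locus_boundary`, and `truth`
#'   (planted class per gene).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  set.seed(spec$seed)
  genes <- sprintf("gene_%04d", seq_len(spec$n_genes))
  cls <- spec$class_assignment
  if (is.null(cls)) {
    # proportions of the four observed class sizes (467/524/339/893)
    cls <- sample(c("I", "II", "III", "IV"), spec$n_genes, replace = TRUE,
                  prob = c(0.21, 0.236, 0.152, 0.402))
  }
  genotype <- factor(rep(names(spec$n_samples), spec$n_samples),
                     levels = c("wt", "sulf/+", "sulf"))
  samples <- paste0(sub("sulf/\\+", "het", as.character(genotype)),
                    stats::ave(seq_along(genotype), genotype, FUN = seq_along))
  pattern <- t(vapply(cls, function(cl)
    spec$class_effects[[cl]][as.character(genotype)],
    numeric(length(genotype))))
  mat <- pattern + matrix(stats::rnorm(length(pattern), 0, spec$noise_sd),
                          nrow = spec$n_genes)
  dimnames(mat) <- list(genes, samples)
  mat <- mat - apply(mat, 1, stats::median)

  wt_cols <- genotype == "wt"; sulf_cols <- genotype == "sulf"
  log2fc <- rowMeans(mat[, wt_cols, drop = FALSE]) -
    rowMeans(mat[, sulf_cols, drop = FALSE])
  pvals <- apply(mat, 1, function(x) {
    p <- tryCatch(stats::t.test(x[wt_cols], x[sulf_cols])$p.value,
                  error = function(e) 1)
    if (is.na(p)) 1 else p
  })
  de <- data.frame(gene = genes, log2fc = unname(log2fc),
                   padj = stats::p.adjust(pvals, "BH"),
                   stringsAsFactors = FALSE)

  plan <- spec$annotation_plan
  # bias "down in sulf" classes toward chromosome 2 below the S-locus boundary
  chrom <- sample(plan$chroms, spec$n_genes, replace = TRUE)
  down <- cls %in% c("I", "II")
  chrom[down & stats::runif(spec$n_genes) < 0.5] <- "2"
  start <- floor(stats::runif(spec$n_genes, 0, plan$chrom_length - 5e3))
  ann <- data.frame(gene = genes, chrom = chrom, start = start,
                    end = start + floor(stats::runif(spec$n_genes, 1e3, 5e3)),
                    strand = sample(c("+", "-"), spec$n_genes, replace = TRUE),
                    stringsAsFactors = FALSE)
  list(matrix = mat, genotype = genotype, de = de, annotation = ann,
       s_locus_boundary = plan$s_locus_boundary,
       truth = stats::setNames(cls, genes))
}

#' Simulate a qPCR Cq table for expression of a target across genotypes
#'
#' Cq values fall by one cycle per doubling of template at efficiency 2;
#' the target's Cq shifts by `log2(fold)` relative to wild type while two
#' housekeeping targets stay flat. Technical replicates get Gaussian Cq
#' noise.
#'
#' @param fold Named numeric: genotype -> expression fold relative to wt
#'   (default the 26-fold sulf reduction scale with an intermediate het).
#' @param n_biological Biological replicates per genotype.
#' @param n_technical Technical replicates per measurement.
#' @param base_cq Target Cq in wild type; housekeepers sit at 20 and 22.
#' @param cq_sd Technical Cq standard deviation, cycles.
#' @param seed Integer seed.
#' @return A data.frame: sample, genotype, target, replicate, cq.
#' @export
simulate_qpcr_cq <- function(fold = c(wt = 1, "sulf/+" = 0.5, sulf = 1 / 26),
                             n_biological = 5, n_technical = 3,
                             base_cq = 24, cq_sd = 0.1, seed = 1L) {
  stopifnot(all(fold > 0), n_biological >= 1, n_technical >= 1, cq_sd >= 0)
  set.seed(seed)
  rows <- list()
  hk_cq <- c(TIP41 = 20, EXPRESSED = 22)
  for (g in names(fold)) {
    for (b in seq_len(n_biological)) {
      sample_id <- paste0(sub("sulf/\\+", "het", g), "_", b)
      bio_shift <- stats::rnorm(1, 0, cq_sd)   # shared library-amount shift
      for (target in c("target", names(hk_cq))) {
        mu <- if (target == "target") base_cq - log2(fold[[g]]) else hk_cq[[target]]
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sample_id, genotype = g, target = target,
          replicate = seq_len(n_technical),
          cq = mu + bio_shift + stats::rnorm(n_technical, 0, cq_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cytosine report in the Bismark CX dialect
#'
#' Tab-separated, no header: chrom, 1-based position, strand, methylated
#' count, unmethylated count, context, trinucleotide ("NNN" here, since the
#' simulator does not track sequence).
#'
#' @param records Cytosine record data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  out <- data.frame(records$chrom, records$pos, records$strand,
                    records$meth, records$unmeth, records$context, "NNN")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a count matrix as TSV with an id column
#' @param counts Matrix with row and column names.
#' @param path Output path.
#' @param id_name Header for the id column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, id_name = "locus") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write planted regions as a BED file (0-based half-open)
#' @param spec A [methylome_sim_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_planted_regions_bed <- function(spec, path) {
  stopifnot(inherits(spec, "methylome_sim_spec"))
  lines <- vapply(seq_along(spec$planted_regions), function(i) {
    r <- spec$planted_regions[[i]]
    paste(spec$chrom_name, r$start, r$end, paste0("planted_", i), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
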