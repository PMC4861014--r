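#' Library-normalize, log-transform and median-center an expression matrix
#'
#' Counts are scaled to counts-per-million against the supplied library
#' sizes, log2(x + 1) transformed, and each gene's median across samples is
#' subtracted, matching the representation the correlation clustering
#' consumes.
#'
#' @param counts Gene x sample count matrix (non-negative).
#' @param lib_sizes Library sizes; defaults to column sums.
#' @return Gene x sample matrix of log2, median-centered values.
#' @export
prepare_matrix <- function(counts, lib_sizes = colSums(counts)) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  cpm <- sweep(counts, 2, lib_sizes, `/`) * 1e6
  lg <- log2(cpm + 1)
  lg - apply(lg, 1, stats::median)
}

#' Hierarchical correlation clustering of expression profiles
#'
#' Genes are clustered by average-linkage hierarchical clustering with
#' distance 1 - Pearson correlation across samples, and the tree is cut
#' where the merge correlation drops below `r_threshold`. Genes without
#' variance across samples have no defined correlation and are assigned to
#' singleton clusters flagged `flat`. Input order does not matter: genes
#' are processed in lexicographic id order.
#'
#' @param mat Gene x sample matrix (rownames are gene ids), typically the
#'   differentially expressed subset of [prepare_matrix()] output.
#' @param r_threshold Correlation threshold for cutting the tree
#'   (default 0.7); `-1` yields a single cluster.
#' @return A data.frame: gene, cluster (integer), flat (logical), in
#'   lexicographic gene order.
#' @export
correlation_cluster <- function(mat, r_threshold = 0.7) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), nrow(mat) >= 2)
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  sds <- apply(mat, 1, stats::sd)
  flat <- sds < 1e-12 | is.na(sds)
  genes <- rownames(mat)
  cluster <- integer(length(genes))
  ok <- which(!flat)
  if (length(ok) >= 2) {
    d <- stats::as.dist(1 - stats::cor(t(mat[ok, , drop = FALSE])))
    hc <- stats::hclust(d, method = "average")
    cluster[ok] <- stats::cutree(hc, h = 1 - r_threshold)
  } else if (length(ok) == 1) {
    cluster[ok] <- 1L
  }
  next_id <- max(cluster, 0L)
  for (i in which(flat)) {                # each flat gene its own cluster
    next_id <- next_id + 1L
    cluster[i] <- next_id
  }
  data.frame(gene = genes, cluster = cluster, flat = flat,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Categorize clusters by their genotype response pattern
#'
#' Each cluster's mean profile is summarized as genotype means, and the
#' sign pattern of (sulf - wt) and (sulf/+ - wt) assigns the category:
#' I down in sulf and sulf/+, II down in sulf only, III up in both,
#' IV up in sulf only. Differences smaller than `min_effect` (log2) count
#' as unchanged; any other pattern is `"other"`.
#'
#' @param mat Gene x sample matrix used for clustering.
#' @param clusters Output of [correlation_cluster()].
#' @param genotype Factor over samples with levels wt, sulf/+, sulf (all
#'   three must be present).
#' @param min_effect Minimum absolute log2 difference (default 0.5).
#' @return A data.frame: cluster, n_genes, d_het, d_sulf, category.
#' @export
assign_categories <- function(mat, clusters, genotype, min_effect = 0.5) {
  genotype <- as.factor(genotype)
  need <- c("wt", "sulf/+", "sulf")
  if (!all(need %in% levels(droplevels(genotype))))
    stop("genotype must contain wt, sulf/+ and sulf samples")
  stopifnot(ncol(mat) == length(genotype))
  sgn <- function(x) ifelse(abs(x) < min_effect, 0, sign(x))
  res <- lapply(sort(unique(clusters$cluster)), function(cl) {
    g <- clusters$gene[clusters$cluster == cl]
    prof <- colMeans(mat[g, , drop = FALSE])
    gm <- tapply(prof, genotype, mean)
    d_sulf <- gm[["sulf"]] - gm[["wt"]]
    d_het <- gm[["sulf/+"]] - gm[["wt"]]
    pat <- paste0(sgn(d_het), ",", sgn(d_sulf))
    category <- switch(pat,
                       "-1,-1" = "I", "0,-1" = "II",
                       "1,1" = "III", "0,1" = "IV",
                       "other")
    data.frame(cluster = cl, n_genes = length(g), d_het = d_het,
               d_sulf = d_sulf, category = category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Positional candidate filter for the paramutated locus
#'
#' Keeps differentially expressed genes that are down-regulated in sulf
#' (log2 fold-change wt/sulf > 0) at adjusted p below `padj_max` and that
#' lie on the stated chromosome with gene end at or before the S-locus
#' boundary (the paramutated locus must map upstream of it). Candidates
#' are returned strongest repression first.
#'
#' @param de DE table data.frame: gene, log2fc (wt over sulf), padj.
#' @param annotation Annotation data.frame: gene, chrom, start, end
#'   (0-based half-open).
#' @param boundary S-locus coordinate in bp (inclusive).
#' @param chrom Chromosome to restrict to (default "2").
#' @param padj_max Adjusted-p threshold (default 0.05).
#' @return The filtered, annotated DE table ordered by descending log2fc.
#'   Genes missing from the annotation are dropped with a warning.
#' @export
positional_candidate_filter <- function(de, annotation, boundary,
                                        chrom = "2", padj_max = 0.05) {
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(de)),
            all(c("gene", "chrom", "start", "end") %in% names(annotation)),
            length(boundary) == 1, boundary >= 0)
  missing <- setdiff(de$gene, annotation$gene)
  if (length(missing))
    warning(length(missing), " DE genes missing from the annotation ",
            "were excluded")
  m <- merge(de, annotation, by = "gene")
  keep <- m$padj < padj_max & m$log2fc > 0 &
    m$chrom == chrom & m$end <= boundary
  out <- m[keep, , drop = FALSE]
  out <- out[order(-out$log2fc, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on whose co-membership the two partitions agree.
#'
#' @param a,b Cluster label vectors over the same items.
#' @return Rand index in [0, 1].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_a - sum_b) / total
}
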