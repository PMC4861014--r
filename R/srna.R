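#' Loci used for between-library normalization
#'
#' The scaling factors are estimated on the loci detected in every library
#' (count > 0 everywhere) whose total count across libraries is at least
#' `min_total`.
#'
#' @param counts Locus x library count matrix with rownames.
#' @param min_total Minimum row total (default 10).
#' @return Character vector of locus names; empty with a warning when no
#'   locus qualifies.
#' @export
normalization_subset <- function(counts, min_total = 10) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  keep <- rowSums(counts > 0) == ncol(counts) & rowSums(counts) >= min_total
  if (!any(keep))
    warning("no locus passes the normalization filter; ",
            "factors fall back to library size only")
  rownames(counts)[keep]
}

# Trimmed mean of M-values between one observation library and the
# reference, with inverse-variance (delta-method binomial) weights.
.tmm_pair <- function(obs, ref, nO, nR, logratio_trim, sum_trim, weighted) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
    (rank(absE) >= loS & rank(absE) <= hiS)
  f <- if (weighted) {
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(logR[keep], na.rm = TRUE)
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Computes per-library TMM factors from the normalization subset: the
#' reference library is the one whose 75th count-rate percentile is closest
#' to the mean across libraries; each library's factor is the precision-
#' weighted trimmed mean of log2 rate ratios against the reference (30%
#' two-sided trim on M-values, 5% on average log expression), and factors
#' are rescaled to geometric mean 1.
#'
#' @param counts Locus x library count matrix.
#' @param subset Locus names to estimate from; defaults to
#'   [normalization_subset()]. An empty subset yields factors of 1.
#' @param lib_sizes Library sizes; defaults to column sums of `counts`.
#' @param logratio_trim Two-sided trim fraction on M-values (default 0.30).
#' @param sum_trim Two-sided trim fraction on A-values (default 0.05).
#' @param weighted Use inverse-variance precision weights (default TRUE).
#' @return A list of class `tmm_norm`: `factors` (geometric mean 1),
#'   `effective_sizes` (`lib_sizes * factors`), `lib_sizes`, `subset`,
#'   `ref` (reference library name).
#' @export
tmm_factors <- function(counts, subset = NULL, lib_sizes = colSums(counts),
                        logratio_trim = 0.30, sum_trim = 0.05,
                        weighted = TRUE) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1, all(lib_sizes > 0))
  libs <- colnames(counts)
  if (is.null(subset)) subset <- normalization_subset(counts)
  f <- rep(1, ncol(counts))
  ref <- NA_character_
  if (ncol(counts) >= 2 && length(subset) > 0) {
    x <- counts[subset, , drop = FALSE]
    q75 <- vapply(seq_len(ncol(x)),
                  function(j) stats::quantile(x[, j], 0.75) / lib_sizes[j],
                  numeric(1))
    ref_i <- if (stats::median(q75) < 1e-20) {
      which.max(colSums(sqrt(x)))
    } else {
      which.min(abs(q75 - mean(q75)))
    }
    ref <- libs[ref_i]
    f <- vapply(seq_len(ncol(x)), function(j)
      .tmm_pair(x[, j], x[, ref_i], lib_sizes[j], lib_sizes[ref_i],
                logratio_trim, sum_trim, weighted), numeric(1))
    f <- f / exp(mean(log(f)))
  }
  names(f) <- libs
  structure(list(factors = f,
                 effective_sizes = stats::setNames(lib_sizes * f, libs),
                 lib_sizes = stats::setNames(lib_sizes, libs),
                 subset = subset, ref = ref),
            class = "tmm_norm")
}

#' @export
print.tmm_norm <- function(x, ...) {
  cat("TMM normalization on", length(x$subset), "loci (reference:",
      x$ref, ")\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Rescale counts to a common effective library size
#'
#' Normalized count = raw count * mean(effective size) / effective size of
#' the library, where effective size = library size * TMM factor.
#'
#' @param counts Locus x library count matrix.
#' @param norm A `tmm_norm` object from [tmm_factors()].
#' @return Matrix of non-negative normalized counts (reals).
#' @export
normalize_counts <- function(counts, norm) {
  stopifnot(inherits(norm, "tmm_norm"),
            identical(colnames(counts), names(norm$effective_sizes)))
  eff <- norm$effective_sizes
  sweep(counts, 2, mean(eff) / eff, `*`)
}

#' Poisson regression test of locus abundance on genotype
#'
#' Fits a Poisson log-linear model of counts on the genotype factor and
#' tests it against the intercept-only model with a likelihood-ratio test
#' on (levels - 1) degrees of freedom. In `"literal"` mode the normalized
#' counts are rounded to the nearest integer and modelled directly; in
#' `"offset"` mode raw counts are modelled with log effective library
#' sizes as offsets (the statistically preferred variant).
#'
#' @param y Counts for one locus (normalized in literal mode, raw in
#'   offset mode).
#' @param genotype Factor (or coercible) over libraries; at least two
#'   levels, each with at least one library.
#' @param mode `"literal"` (default) or `"offset"`.
#' @param effective_sizes Required in offset mode.
#' @return A list: deviance (LRT statistic), df, p_value, group_means,
#'   all_zero flag.
#' @export
poisson_genotype_test <- function(y, genotype, mode = c("literal", "offset"),
                                  effective_sizes = NULL) {
  mode <- match.arg(mode)
  genotype <- droplevels(as.factor(genotype))
  stopifnot(length(y) == length(genotype))
  if (nlevels(genotype) < 2) stop("need at least two genotype levels")
  if (any(tabulate(genotype) < 1)) stop("empty genotype level")
  if (any(y < 0)) stop("counts must be non-negative")
  group_means <- tapply(y, genotype, mean)
  if (all(y == 0))
    return(list(deviance = 0, df = nlevels(genotype) - 1, p_value = 1,
                group_means = group_means, all_zero = TRUE))
  if (mode == "literal") {
    yy <- round(y)
    fit <- stats::glm(yy ~ genotype, family = stats::poisson)
  } else {
    if (is.null(effective_sizes))
      stop("offset mode requires effective_sizes")
    yy <- round(y)
    fit <- stats::glm(yy ~ genotype + offset(log(effective_sizes)),
                      family = stats::poisson)
  }
  dev <- fit$null.deviance - fit$deviance
  df <- fit$df.null - fit$df.residual
  list(deviance = dev, df = df,
       p_value = stats::pchisq(dev, df = df, lower.tail = FALSE),
       group_means = group_means, all_zero = FALSE)
}

#' TMM-normalize a count matrix and test every locus on genotype
#'
#' Convenience wrapper chaining [normalization_subset()], [tmm_factors()],
#' [normalize_counts()] and [poisson_genotype_test()].
#'
#' @param counts Locus x library count matrix.
#' @param genotype Factor over libraries.
#' @param min_total Normalization subset threshold (default 10).
#' @param mode Test mode, see [poisson_genotype_test()].
#' @return A list: `norm` (the `tmm_norm`), `normalized` (matrix), and
#'   `tests` (data.frame: locus, deviance, df, p_value).
#' @export
srna_test_all <- function(counts, genotype, min_total = 10,
                          mode = c("literal", "offset")) {
  mode <- match.arg(mode)
  norm <- tmm_factors(counts, normalization_subset(counts, min_total))
  normalized <- normalize_counts(counts, norm)
  res <- lapply(rownames(counts), function(lo) {
    y <- if (mode == "literal") normalized[lo, ] else counts[lo, ]
    r <- poisson_genotype_test(y, genotype, mode = mode,
                               effective_sizes = norm$effective_sizes)
    data.frame(locus = lo, deviance = r$deviance, df = r$df,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  list(norm = norm, normalized = normalized, tests = do.call(rbind, res))
}

#' Read a TSV count matrix written by [write_count_matrix()]
#' @param path Path to the TSV (first column ids, header of sample names).
#' @return Integer matrix with rownames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
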