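#' Read a Bismark-style cytosine report
#'
#' Expects tab-separated columns chrom, position (1-based), strand (+/-),
#' methylated count, unmethylated count, context (CG/CHG/CHH), and an
#' optional trinucleotide column. Malformed lines raise an error naming the
#' first offending line.
#'
#' @param path Path to the report (uncompressed TSV, no header).
#' @return A cytosine record data.frame: chrom, pos, strand, meth, unmeth,
#'   context.
#' @export
read_cytosine_report <- function(path) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), meth = integer(),
                      unmeth = integer(), context = character(),
                      stringsAsFactors = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0L) return(empty)
  bad <- which(!nf %in% c(6L, 7L))
  if (length(bad))
    stop("line ", bad[1], ": expected 6 or 7 tab-separated columns, found ",
         nf[bad[1]])
  df <- utils::read.table(path, sep = "\t", quote = "",
                          col.names = c("chrom", "pos", "strand", "meth",
                                        "unmeth", "context", "tri")[seq_len(max(nf))],
                          colClasses = c("character", "integer", "character",
                                         "integer", "integer",
                                         "character", "character")[seq_len(max(nf))],
                          fill = FALSE, stringsAsFactors = FALSE)
  check <- function(ok, what) {
    if (any(!ok)) stop("line ", which(!ok)[1], ": ", what)
  }
  check(!is.na(df$pos) & df$pos >= 1, "position must be a positive integer")
  check(df$strand %in% c("+", "-"), "strand must be + or -")
  check(!is.na(df$meth) & df$meth >= 0, "negative or missing methylated count")
  check(!is.na(df$unmeth) & df$unmeth >= 0,
        "negative or missing unmethylated count")
  check(df$context %in% c("CG", "CHG", "CHH"),
        "context must be CG, CHG or CHH")
  df[c("chrom", "pos", "strand", "meth", "unmeth", "context")]
}

#' Pool cytosine calls into contiguous context-separated bins
#'
#' Counts from both strands are summed into contiguous `bin_size`-bp bins,
#' kept separate per context. A cytosine at 1-based position `pos` falls in
#' bin `floor((pos - 1) / bin_size)`, so bins are 0-based half-open.
#'
#' @param records Cytosine record data.frame (see
#'   [read_cytosine_report()]).
#' @param bin_size Bin width in bp (default 200).
#' @return A data.frame: chrom, start, end, context, meth, total, sorted by
#'   chrom, start, context. Only bins containing at least one record appear.
#' @export
bin_counts <- function(records, bin_size = 200) {
  if (bin_size <= 0) stop("bin_size must be positive")
  if (nrow(records) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      meth = integer(), total = integer(),
                      stringsAsFactors = FALSE))
  start <- ((records$pos - 1L) %/% bin_size) * bin_size
  key <- paste(records$chrom, start, records$context, sep = "\r")
  meth <- rowsum(records$meth, key)
  total <- rowsum(records$meth + records$unmeth, key)
  parts <- strsplit(rownames(meth), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    start = as.integer(vapply(parts, `[`, "", 2L)),
                    context = vapply(parts, `[`, "", 3L),
                    meth = as.integer(meth[, 1]),
                    total = as.integer(total[, 1]),
                    stringsAsFactors = FALSE)
  out$end <- out$start + as.integer(bin_size)
  out <- out[order(out$chrom, out$start, out$context),
             c("chrom", "start", "end", "context", "meth", "total")]
  rownames(out) <- NULL
  out
}

#' Match per-sample bins into one multi-sample table
#'
#' Inner-joins the per-sample bin tables on (chrom, start, end, context);
#' bins absent from any sample are dropped and their count is reported via
#' a message.
#'
#' @param bin_list Named list of [bin_counts()] outputs.
#' @return A data.frame with chrom, start, end, context and, per sample
#'   `s`, columns `meth.s` and `total.s`.
#' @export
merge_bins <- function(bin_list) {
  stopifnot(is.list(bin_list), length(bin_list) >= 1,
            !is.null(names(bin_list)))
  keys <- c("chrom", "start", "end", "context")
  wide <- NULL
  for (nm in names(bin_list)) {
    b <- bin_list[[nm]]
    names(b)[names(b) == "meth"] <- paste0("meth.", nm)
    names(b)[names(b) == "total"] <- paste0("total.", nm)
    wide <- if (is.null(wide)) b else merge(wide, b, by = keys)
  }
  dropped <- max(vapply(bin_list, nrow, 0L)) - nrow(wide)
  if (dropped > 0)
    message(dropped, " bins present in only some samples were skipped")
  wide <- wide[order(wide$chrom, wide$start, wide$context), , drop = FALSE]
  rownames(wide) <- NULL
  wide
}

#' Exclude low-count bins
#'
#' In `"each"` mode (default) a bin is retained only if every sample's
#' total is at least `min_total`, which guarantees populated 2x2 tables for
#' both replicate chi-square tests. `"pooled"` mode applies the threshold
#' to the summed total across samples instead.
#'
#' @param bins Multi-sample bin table from [merge_bins()].
#' @param min_total Minimum total count (default 10).
#' @param mode `"each"` or `"pooled"`.
#' @return The retained rows of `bins`.
#' @export
filter_bins <- function(bins, min_total = 10, mode = c("each", "pooled")) {
  mode <- match.arg(mode)
  tot <- as.matrix(bins[, grep("^total\\.", names(bins)), drop = FALSE])
  keep <- if (mode == "each") {
    apply(tot >= min_total, 1, all)
  } else {
    rowSums(tot) >= min_total
  }
  out <- bins[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test on a 2x2 methylation table
#'
#' Compares methylated/unmethylated counts of two samples with the Pearson
#' chi-square statistic on 1 degree of freedom, no continuity correction.
#' A table with an empty row or column margin is uninformative and returns
#' statistic 0, p-value 1. All arguments are vectorized.
#'
#' @param meth_a,unmeth_a Counts for sample a.
#' @param meth_b,unmeth_b Counts for sample b.
#' @return A list with numeric vectors `statistic` and `p_value`.
#' @export
chisq_2x2 <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  if (any(c(meth_a, unmeth_a, meth_b, unmeth_b) < 0))
    stop("counts must be non-negative")
  a <- as.numeric(meth_a); b <- as.numeric(unmeth_a)
  c_ <- as.numeric(meth_b); d <- as.numeric(unmeth_b)
  n <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stat <- ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Call differentially methylated bins with the dual chi-square rule
#'
#' For each (chrom, bin, context) present with sufficient counts in all
#' four samples, tests wt1 vs sulf1 and wt2 vs sulf2 with [chisq_2x2()].
#' A bin is a DMR when the maximum of the two p-values is below `alpha`.
#' The reported difference is the mean over replicate pairs of
#' (wt level - sulf level) in percentage points, so negative values mean
#' hypermethylation in sulf. Direction is `hyper_in_sulf` or
#' `hypo_in_sulf` only when both replicate pairs agree in sign, else
#' `discordant`.
#'
#' @param bins_wt1,bins_sulf1,bins_wt2,bins_sulf2 Per-sample
#'   [bin_counts()] outputs.
#' @param alpha DMR threshold on the maximum p-value (default 0.01).
#' @param min_total Bin count filter passed to [filter_bins()].
#' @param filter_mode Filter scope, see [filter_bins()].
#' @return A data.frame over all tested bins: chrom, start, end, context,
#'   per-sample levels (percent), p_pair1, p_pair2, max_p, diff, direction,
#'   is_dmr.
#' @export
call_dmrs <- function(bins_wt1, bins_sulf1, bins_wt2, bins_sulf2,
                      alpha = 0.01, min_total = 10,
                      filter_mode = c("each", "pooled")) {
  wide <- merge_bins(list(wt1 = bins_wt1, sulf1 = bins_sulf1,
                          wt2 = bins_wt2, sulf2 = bins_sulf2))
  wide <- filter_bins(wide, min_total = min_total,
                      mode = match.arg(filter_mode))
  lev <- function(s) 100 * wide[[paste0("meth.", s)]] / wide[[paste0("total.", s)]]
  l_wt1 <- lev("wt1"); l_sulf1 <- lev("sulf1")
  l_wt2 <- lev("wt2"); l_sulf2 <- lev("sulf2")
  t1 <- chisq_2x2(wide$meth.wt1, wide$total.wt1 - wide$meth.wt1,
                  wide$meth.sulf1, wide$total.sulf1 - wide$meth.sulf1)
  t2 <- chisq_2x2(wide$meth.wt2, wide$total.wt2 - wide$meth.wt2,
                  wide$meth.sulf2, wide$total.sulf2 - wide$meth.sulf2)
  d1 <- l_wt1 - l_sulf1
  d2 <- l_wt2 - l_sulf2
  diff <- (d1 + d2) / 2
  concordant <- sign(d1) == sign(d2) & sign(d1) != 0
  direction <- ifelse(!concordant, "discordant",
                      ifelse(diff < 0, "hyper_in_sulf", "hypo_in_sulf"))
  max_p <- pmax(t1$p_value, t2$p_value)
  out <- data.frame(wide[c("chrom", "start", "end", "context")],
                    level.wt1 = l_wt1, level.sulf1 = l_sulf1,
                    level.wt2 = l_wt2, level.sulf2 = l_sulf2,
                    p_pair1 = t1$p_value, p_pair2 = t2$p_value,
                    max_p = max_p, diff = diff, direction = direction,
                    is_dmr = max_p < alpha, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Weighted methylation level of a region
#'
#' The weighted level is 100 * sum(methylated) / sum(total calls) over the
#' cytosines of one context inside the region. A region with zero coverage
#' has no defined level and returns `NA` (never 0).
#'
#' @param records Cytosine record data.frame.
#' @param start,end Region as a 0-based half-open interval.
#' @param context Context to score (CG, CHG or CHH).
#' @param chrom Optional chromosome filter.
#' @return Percentage in [0, 100], or `NA_real_` when there is no coverage.
#' @export
weighted_level <- function(records, start, end, context, chrom = NULL) {
  stopifnot(end > start, context %in% c("CG", "CHG", "CHH"))
  keep <- records$context == context &
    (records$pos - 1L) >= start & (records$pos - 1L) < end
  if (!is.null(chrom)) keep <- keep & records$chrom == chrom
  denom <- sum(records$meth[keep] + records$unmeth[keep])
  if (denom == 0) return(NA_real_)
  100 * sum(records$meth[keep]) / denom
}

#' Sliding-window weighted methylation profile
#'
#' Windows of `window` bp advance in steps of `step` bp starting at 0; each
#' window's value is the weighted methylation level of its context.
#' Windows without coverage are emitted with level `NA`.
#'
#' @param records Cytosine record data.frame (single chromosome).
#' @param window Window width in bp (default 200).
#' @param step Step in bp (default 100); must not exceed `window`.
#' @return A data.frame: chrom, start, end, context, meth, total, level.
#' @export
sliding_window_profile <- function(records, window = 200, step = 100) {
  stopifnot(window >= step, step > 0)
  if (nrow(records) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      meth = integer(), total = integer(),
                      level = numeric(), stringsAsFactors = FALSE))
  if (length(unique(records$chrom)) > 1L)
    stop("profile expects records from a single chromosome")
  pos0 <- records$pos - 1L                        # 0-based
  last_start <- (max(pos0) %/% step) * step       # last window covering data
  n_win <- last_start %/% step + 1L
  acc_m <- numeric(n_win); acc_t <- numeric(n_win)
  max_span <- ceiling(window / step)              # windows covering one bp
  per_ctx <- function(ctx) {
    sel <- records$context == ctx
    m <- numeric(n_win); tt <- numeric(n_win)
    if (any(sel)) {
      p <- pos0[sel]; me <- records$meth[sel]
      to <- me + records$unmeth[sel]
      for (j in seq_len(max_span) - 1L) {
        k <- p %/% step - j                       # candidate window index
        ok <- k >= 0L & (k * step + window) > p
        if (any(ok)) {
          add_m <- rowsum(me[ok], k[ok])
          add_t <- rowsum(to[ok], k[ok])
          idx <- as.integer(rownames(add_m)) + 1L
          m[idx] <- m[idx] + add_m[, 1]
          tt[idx] <- tt[idx] + add_t[, 1]
        }
      }
    }
    starts <- as.integer((seq_len(n_win) - 1L) * step)
    data.frame(chrom = records$chrom[1], start = starts,
               end = starts + as.integer(window), context = ctx,
               meth = as.integer(m), total = as.integer(tt),
               level = ifelse(tt > 0, 100 * m / tt, NA_real_),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c("CG", "CHG", "CHH"), per_ctx))
  rownames(out) <- NULL
  out
}

#' Region-level binomial regression test of methylation on genotype
#'
#' Fits a binomial (logistic) regression of the aggregated methylated /
#' unmethylated counts on genotype, one observation per sample, and tests
#' the genotype factor with a likelihood-ratio test against the
#' intercept-only model.
#'
#' @param meth,unmeth Per-sample aggregated counts for the region.
#' @param genotype Factor (or coercible) with at least two levels.
#' @param region Optional label carried into the result.
#' @param context Optional context label carried into the result.
#' @return A list of class `region_test`: region, context, levels (percent
#'   per sample; `NA` for uncovered samples), deviance (LRT statistic), df,
#'   p_value.
#' @export
region_glm_test <- function(meth, unmeth, genotype, region = NULL,
                            context = NULL) {
  stopifnot(length(meth) == length(unmeth),
            length(meth) == length(genotype))
  genotype <- droplevels(as.factor(genotype))
  if (nlevels(genotype) < 2) stop("need at least two genotype levels")
  total <- meth + unmeth
  if (all(total == 0)) stop("all samples have zero coverage in the region")
  fit <- stats::glm(cbind(meth, unmeth) ~ genotype, family = stats::binomial)
  dev <- fit$null.deviance - fit$deviance
  df <- fit$df.null - fit$df.residual
  structure(list(
    region = region, context = context,
    levels = ifelse(total > 0, 100 * meth / total, NA_real_),
    deviance = dev, df = df,
    p_value = stats::pchisq(dev, df = df, lower.tail = FALSE)
  ), class = "region_test")
}

#' @export
print.region_test <- function(x, ...) {
  cat("Region binomial regression test",
      if (!is.null(x$region)) paste0(" [", x$region, "]"),
      if (!is.null(x$context)) paste0(" context ", x$context), "\n", sep = "")
  cat("  per-sample levels (%):",
      paste(formatC(x$levels, digits = 3, format = "fg"), collapse = ", "), "\n")
  cat("  LRT deviance ", formatC(x$deviance, digits = 4, format = "fg"),
      " on ", x$df, " df, p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Tally DMR calls by context and direction
#'
#' @param calls Output of [call_dmrs()].
#' @return A data.frame with one row per context: counts of hyper_in_sulf,
#'   hypo_in_sulf and discordant DMRs, plus bins tested.
#' @export
classify_dmrs <- function(calls) {
  ctx <- c("CG", "CHG", "CHH")
  dmr <- calls[calls$is_dmr, , drop = FALSE]
  tally <- function(k, dir) sum(dmr$context == k & dmr$direction == dir)
  data.frame(context = ctx,
             hyper_in_sulf = vapply(ctx, tally, 0, dir = "hyper_in_sulf"),
             hypo_in_sulf = vapply(ctx, tally, 0, dir = "hypo_in_sulf"),
             discordant = vapply(ctx, tally, 0, dir = "discordant"),
             tested = vapply(ctx, function(k) sum(calls$context == k), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write DMR calls as a BED6 file
#'
#' Emits one line per called DMR with 0-based half-open coordinates,
#' name `context:direction`, score `-10 log10(max_p)` capped at 1000, and
#' strand ".".
#'
#' @param calls Output of [call_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(calls, path) {
  dmr <- calls[calls$is_dmr, , drop = FALSE]
  if (nrow(dmr) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- pmin(1000, round(-10 * log10(pmax(dmr$max_p, 1e-300))))
  df <- data.frame(dmr$chrom, dmr$start, dmr$end,
                   paste0(dmr$context, ":", dmr$direction), score, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
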