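#' McrBC-qPCR methylation proportion
#'
#' McrBC cuts methylated DNA, so template surviving digestion is the
#' unmethylated fraction. The surviving fraction is estimated from the Cq
#' shift between digested and undigested aliquots,
#' R = efficiency^(Cq_undigested - Cq_digested), and the methylation
#' proportion is 100 * (1 - R), clamped to [0, 100]. A digested sample
#' with no amplification (infinite Cq) gives 100% methylation; an
#' undigested sample that fails to amplify is an assay failure and yields
#' `NA` with a warning. Vectorized.
#'
#' @param cq_digested Cq of the McrBC-digested aliquot (`Inf` or `NA` for
#'   no amplification).
#' @param cq_undigested Cq of the undigested aliquot.
#' @param efficiency Amplification efficiency per cycle, in (1, 2]
#'   (default 2, perfect doubling).
#' @return Methylation proportion(s) in percent.
#' @export
mcrbc_methylation_proportion <- function(cq_digested, cq_undigested,
                                         efficiency = 2) {
  stopifnot(efficiency > 1, efficiency <= 2)
  cq_digested[is.na(cq_digested)] <- Inf
  cq_undigested[is.na(cq_undigested)] <- Inf
  if (any(cq_digested <= 0) || any(cq_undigested <= 0))
    stop("Cq values must be positive")
  bad <- is.infinite(cq_undigested)
  surviving <- efficiency^(cq_undigested - cq_digested)
  surviving[is.nan(surviving)] <- 1      # both infinite: no information
  prop <- 100 * (1 - pmin(surviving, 1))
  if (any(bad)) {
    warning("undigested sample(s) failed to amplify; returning NA")
    prop[bad] <- NA_real_
  }
  prop
}

#' Housekeeping-normalized relative expression from qPCR Cq values
#'
#' Technical replicates are averaged on the Cq scale; the target's
#' abundance efficiency^(-Cq) is divided by the geometric mean of the two
#' housekeeping abundances. Adding a constant to every Cq leaves the
#' result unchanged.
#'
#' @param cq_target Cq replicates of the target assay.
#' @param cq_hk1,cq_hk2 Cq replicates of the two housekeeping assays.
#' @param efficiency Amplification efficiency per cycle, in (1, 2].
#' @return Relative abundance (dimensionless).
#' @export
qpcr_relative_expression <- function(cq_target, cq_hk1, cq_hk2,
                                     efficiency = 2) {
  stopifnot(efficiency > 1, efficiency <= 2)
  for (x in list(cq_target, cq_hk1, cq_hk2)) {
    if (length(x) == 0 || all(is.na(x)))
      stop("each assay needs at least one finite Cq replicate ",
           "(missing housekeeper?)")
  }
  mt <- mean(cq_target, na.rm = TRUE)
  m1 <- mean(cq_hk1, na.rm = TRUE)
  m2 <- mean(cq_hk2, na.rm = TRUE)
  # efficiency^(-mt) / sqrt(eff^(-m1) * eff^(-m2)), on the log scale
  efficiency^(-(mt - (m1 + m2) / 2))
}

#' Fold change and Welch t-test between two groups of abundances
#'
#' The fold change is the ratio of arithmetic means; the test is a
#' two-tailed Welch t-test on log2 abundances (a raw-scale p-value is also
#' reported for comparison).
#'
#' @param group_a,group_b Positive abundances, at least two values each.
#' @return A list: fold (mean a / mean b), p_value (log2-scale Welch),
#'   p_value_raw (untransformed-scale Welch), statistic, df.
#' @export
fold_change_ttest <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (any(c(group_a, group_b) <= 0))
    stop("abundances must be positive (log2 fold testing)")
  fold <- mean(group_a) / mean(group_b)
  la <- log2(group_a); lb <- log2(group_b)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
    # degenerate: no within-group variance; equal means -> no evidence
    equal <- isTRUE(all.equal(mean(la), mean(lb)))
    return(list(fold = fold, p_value = if (equal) 1 else 0,
                p_value_raw = if (equal) 1 else 0,
                statistic = if (equal) 0 else Inf, df = NA_real_))
  }
  tt <- stats::t.test(la, lb)
  tr <- stats::t.test(group_a, group_b)
  list(fold = fold, p_value = tt$p.value, p_value_raw = tr$p.value,
       statistic = unname(tt$statistic), df = unname(tt$parameter))
}

#' Read a qPCR Cq table
#'
#' TSV with header columns sample, target, replicate, cq (extra columns
#' are kept); "NA" in cq means no amplification and is read as `Inf`.
#'
#' @param path Path to the TSV.
#' @return A data.frame with `cq` numeric (`Inf` for no amplification).
#' @export
read_cq_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "target", "replicate", "cq")
  if (!all(need %in% names(df)))
    stop("Cq table must have columns: ", paste(need, collapse = ", "))
  df$cq <- suppressWarnings(as.numeric(df$cq))
  df$cq[is.na(df$cq)] <- Inf
  if (any(df$cq[is.finite(df$cq)] <= 0)) stop("Cq values must be positive")
  df
}
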