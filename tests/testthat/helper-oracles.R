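# Independently coded oracles used to cross-check the implementation.

# Pearson chi-square by explicit expected-count summation over all 4 cells
chisq_oracle <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  obs <- matrix(c(meth_a, unmeth_a, meth_b, unmeth_b), nrow = 2, byrow = TRUE)
  n <- sum(obs)
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0))
    return(list(statistic = 0, p_value = 1))
  stat <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(obs[i, ]) * sum(obs[, j]) / n
    stat <- stat + (obs[i, j] - e)^2 / e
  }
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# Poisson LRT deviance from the closed-form group-mean MLE:
# 2 * sum(y * log(y / fitted)), with group means (alternative) and the
# grand mean (null) as fitted values; y log y terms vanish at y = 0.
poisson_lrt_oracle <- function(y, genotype) {
  genotype <- as.factor(genotype)
  ll <- function(mu) sum(ifelse(y > 0, y * log(mu), 0) - mu)
  mu1 <- ave(y, genotype)               # group-mean fits
  mu0 <- rep(mean(y), length(y))        # grand-mean fit
  2 * (ll(mu1) - ll(mu0))
}

# convenience builder for cytosine record tables
make_records <- function(pos, meth, unmeth, context = "CG", strand = "+",
                         chrom = "2") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             meth = as.integer(meth), unmeth = as.integer(unmeth),
             context = context, stringsAsFactors = FALSE)
}

# builder for multi-sample bin tables in call_dmrs input form
make_bins <- function(start, context, meth, total, chrom = "2",
                      bin_size = 200) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + bin_size), context = context,
             meth = as.integer(meth), total = as.integer(total),
             stringsAsFactors = FALSE)
}
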