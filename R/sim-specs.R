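#' Simulation specification for a synthetic bisulfite methylome
#'
#' Describes a single synthetic chromosome: where cytosines sit (a
#' homogeneous Bernoulli process per context and strand), the background
#' methylation probability per context, planted regions whose methylation
#' probability depends on genotype, and the sequencing depth model
#' (Poisson calls per cytosine, beta-binomial methylated counts).
#'
#' @param chrom_name Chromosome name used in emitted records.
#' @param chrom_length Chromosome length in bp.
#' @param context_density Named numeric, expected cytosines per bp (summed
#'   over both strands) for contexts CG, CHG and CHH. Defaults reflect a
#'   plant genome of roughly 34% GC.
#' @param background_level Named numeric in [0,1]: methylation probability
#'   per context outside planted regions (both genotypes).
#' @param planted_regions List of regions built with [planted_region()].
#' @param mean_depth Expected number of calls per cytosine (the study design
#'   this emulates sequenced to about 5x).
#' @param overdispersion Beta-binomial dispersion rho in [0,1); 0 gives
#'   plain binomial sampling.
#' @param seed Integer seed controlling site placement (and, by default,
#'   count sampling).
#' @return An object of class `methylome_sim_spec`.
#' @seealso [simulate_cytosine_sites()], [simulate_cytosine_report()]
#' @export
methylome_sim_spec <- function(chrom_name = "2",
                               chrom_length = 2e5,
                               context_density = c(CG = 0.06, CHG = 0.05, CHH = 0.23),
                               background_level = c(CG = 0.30, CHG = 0.10, CHH = 0.05),
                               planted_regions = list(),
                               mean_depth = 5,
                               overdispersion = 0,
                               seed = 1L) {
  ctx <- c("CG", "CHG", "CHH")
  context_density <- .complete_context(context_density, 0)
  background_level <- .complete_context(background_level, 0)
  stopifnot(
    length(chrom_name) == 1L, chrom_length >= 0,
    all(context_density >= 0), sum(context_density) / 2 <= 1,
    all(background_level >= 0 & background_level <= 1),
    mean_depth >= 0,
    overdispersion >= 0, overdispersion < 1
  )
  for (r in planted_regions) {
    if (!inherits(r, "planted_region"))
      stop("planted_regions must be built with planted_region()")
    if (r$start < 0 || r$end > chrom_length || r$start >= r$end)
      stop("planted region [", r$start, ",", r$end,
           ") outside chromosome of length ", chrom_length)
  }
  structure(list(
    chrom_name = chrom_name, chrom_length = as.integer(chrom_length),
    context_density = context_density[ctx],
    background_level = background_level[ctx],
    planted_regions = planted_regions,
    mean_depth = mean_depth, overdispersion = overdispersion,
    seed = as.integer(seed)
  ), class = "methylome_sim_spec")
}

.complete_context <- function(x, fill) {
  ctx <- c("CG", "CHG", "CHH")
  if (is.null(names(x))) {
    stopifnot(length(x) == 3L)
    names(x) <- ctx
  }
  out <- stats::setNames(rep(fill, 3L), ctx)
  out[names(x)] <- x
  out
}

#' Define a planted differentially methylated region
#'
#' @param start,end 0-based half-open interval on the simulated chromosome.
#' @param levels Named list, context -> named numeric of per-genotype
#'   methylation probabilities, e.g.
#'   `list(CG = c(wt = 0.24, sulf = 0.73))`. Contexts absent from the list
#'   keep the background level.
#' @return An object of class `planted_region`.
#' @export
planted_region <- function(start, end, levels) {
  stopifnot(start >= 0, end > start, is.list(levels))
  for (ctx in names(levels)) {
    if (!ctx %in% c("CG", "CHG", "CHH")) stop("unknown context: ", ctx)
    p <- levels[[ctx]]
    if (is.null(names(p)) || any(p < 0 | p > 1))
      stop("levels must be named per-genotype probabilities in [0,1]")
  }
  structure(list(start = as.integer(start), end = as.integer(end),
                 levels = levels), class = "planted_region")
}

#' Simulation specification for small RNA locus counts
#'
#' Counts are Poisson with mean
#' `library_size * baseline_mean * fold(locus, genotype)`. The default
#' design mirrors the study layout: two libraries for each of the wild
#' type, heterozygous `sulf/+`, and fully paramutated `sulf` genotypes,
#' with a handful of loci whose 23-24-nt siRNA abundance rises (RdDM gain,
#' as at the promoter-proximal DMR) or falls with paramutation dose.
#'
#' @param n_loci Number of simulated loci.
#' @param library_sizes Named positive scale factors, one per library.
#' @param genotype_design Named character, library -> genotype in
#'   `c("wt", "sulf/+", "sulf")`.
#' @param baseline_mean Expected counts per locus at scale factor 1.
#' @param effect_loci Named list, locus index (as character) or name ->
#'   named fold-change vector over the three genotypes.
#' @param seed Integer seed.
#' @return An object of class `srna_sim_spec`.
#' @export
srna_sim_spec <- function(n_loci = 500,
                          library_sizes = c(wt1 = 1, wt2 = 1, het1 = 1,
                                            het2 = 1, sulf1 = 1, sulf2 = 1),
                          genotype_design = c(wt1 = "wt", wt2 = "wt",
                                              het1 = "sulf/+", het2 = "sulf/+",
                                              sulf1 = "sulf", sulf2 = "sulf"),
                          baseline_mean = 20,
                          effect_loci = default_srna_effects(n_loci),
                          seed = 1L) {
  stopifnot(
    n_loci >= 1, all(library_sizes > 0),
    identical(sort(names(library_sizes)), sort(names(genotype_design))),
    all(genotype_design %in% c("wt", "sulf/+", "sulf")),
    baseline_mean >= 0
  )
  for (f in effect_loci) {
    if (is.null(names(f)) || !all(names(f) %in% c("wt", "sulf/+", "sulf")) ||
        any(f < 0))
      stop("effect_loci entries must be non-negative folds named by genotype")
  }
  structure(list(
    n_loci = as.integer(n_loci),
    library_sizes = library_sizes,
    genotype_design = genotype_design[names(library_sizes)],
    baseline_mean = baseline_mean,
    effect_loci = effect_loci, seed = as.integer(seed)
  ), class = "srna_sim_spec")
}

#' Default planted siRNA effects: ten dose-responsive gains, ten losses
#' @param n_loci Number of loci in the matrix the effects apply to.
#' @return Named list of per-genotype fold-change vectors.
#' @export
default_srna_effects <- function(n_loci) {
  if (n_loci < 20) return(list())
  up <- lapply(1:10, function(i) c(wt = 1, "sulf/+" = 2, sulf = 4))
  dn <- lapply(11:20, function(i) c(wt = 1, "sulf/+" = 0.5, sulf = 0.25))
  stats::setNames(c(up, dn), sprintf("locus_%04d", 1:20))
}

#' Simulation specification for the expression class structure
#'
#' Emits an already library-normalized, log2, per-gene median-centered
#' matrix (upstream count modelling and differential-expression calling are
#' consumed, not simulated), together with a differential-expression table
#' and a positional gene annotation including a designated S-locus boundary
#' on chromosome 2. Class patterns over genotypes (wt, sulf/+, sulf):
#' I down in sulf and sulf/+; II down in sulf only; III up in both;
#' IV up in sulf only; "null" flat.
#'
#' @param n_genes Number of genes.
#' @param class_assignment Character vector over genes in
#'   `c("I","II","III","IV","null")`, or NULL to sample classes with
#'   proportions matching the four observed class sizes.
#' @param class_effects Named list, class -> log2 offsets over
#'   `c(wt, "sulf/+", sulf)`.
#' @param noise_sd Gaussian noise standard deviation on the log2 scale.
#' @param n_samples Named integer, genotype -> number of samples
#'   (default two wild types and three sulf / sulf-het pairs).
#' @param annotation_plan List with chromosome names, chromosome length,
#'   and the S-locus boundary coordinate on chromosome 2.
#' @param seed Integer seed.
#' @return An object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes = 400,
                                class_assignment = NULL,
                                class_effects = list(
                                  I = c(wt = 0, "sulf/+" = -1.5, sulf = -1.5),
                                  II = c(wt = 0, "sulf/+" = 0, sulf = -2),
                                  III = c(wt = 0, "sulf/+" = 1.5, sulf = 1.5),
                                  IV = c(wt = 0, "sulf/+" = 0, sulf = 2),
                                  null = c(wt = 0, "sulf/+" = 0, sulf = 0)),
                                noise_sd = 0.2,
                                n_samples = c(wt = 2, "sulf/+" = 3, sulf = 3),
                                annotation_plan = list(
                                  chroms = c("1", "2", "3"),
                                  chrom_length = 5e7,
                                  s_locus_boundary = 3.5e7),
                                seed = 1L) {
  classes <- c("I", "II", "III", "IV", "null")
  stopifnot(n_genes >= 1, noise_sd >= 0,
            all(names(n_samples) %in% c("wt", "sulf/+", "sulf")),
            all(n_samples >= 1))
  if (!is.null(class_assignment)) {
    stopifnot(length(class_assignment) == n_genes,
              all(class_assignment %in% classes))
  }
  for (cl in names(class_effects)) {
    p <- class_effects[[cl]]
    ok <- switch(cl,
      I = p["sulf"] < 0 && p[["sulf/+"]] < 0,
      II = p["sulf"] < 0 && p[["sulf/+"]] == 0,
      III = p["sulf"] > 0 && p[["sulf/+"]] > 0,
      IV = p["sulf"] > 0 && p[["sulf/+"]] == 0,
      null = all(p == 0),
      TRUE)
    if (!isTRUE(ok)) stop("class_effects[['", cl, "']] violates its sign pattern")
  }
  structure(list(
    n_genes = as.integer(n_genes), class_assignment = class_assignment,
    class_effects = class_effects, noise_sd = noise_sd,
    n_samples = n_samples, annotation_plan = annotation_plan,
    seed = as.integer(seed)
  ), class = "expression_sim_spec")
}
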