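#' Simulation settings for synthetic HRM plates
#'
#' Parameterizes the two-state duplex melting model used to generate
#' synthetic plates with known genotypes. Each duplex species melts along a
#' logistic transition centred at its Tm; a heterozygote's PCR product
#' re-anneals into four duplex combinations in roughly equal proportion
#' (two matched homoduplexes plus two mismatched heteroduplexes melting
#' \code{heteroduplex_shift} degrees earlier), which creates the
#' early-melting shoulder that HRM detects. On top of the mixture curve the
#' simulator adds per-curve amplitude jitter, a linear baseline drift and
#' i.i.d. Gaussian read noise, so that normalization has real work to do.
#'
#' @param tm_allele_ref Tm of the reference-allele homoduplex (degC).
#' @param delta_tm_alt Alt homoduplex Tm minus ref homoduplex Tm (degC).
#' @param heteroduplex_shift Tm depression of mismatched duplexes (degC,
#'   > 0).
#' @param width Logistic transition scale (degC, > 0).
#' @param t_start,t_end,t_step Temperature grid (degC). The defaults,
#'   70-90 degC in 0.1 degC steps, match a typical effective resolution of
#'   a continuous-ramp dissociation.
#' @param amplitude_mean,amplitude_cv Mean and coefficient of variation of
#'   the per-curve fluorescence amplitude.
#' @param baseline_slope Linear background fluorescence per degC.
#' @param noise_sd Standard deviation of additive Gaussian read noise, in
#'   fluorescence units (0.003 is 0.3\% of the unit amplitude).
#' @param n_per_genotype Integer counts of ref-homozygote, heterozygote and
#'   alt-homozygote samples; the default 9/9/9 gives a 27-sample plate the
#'   size of the cultivar panel.
#' @param ref_allele,alt_allele Allele letters used to label the truth.
#' @param seed Integer seed making [simulate_plate()] reproducible.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(tm_allele_ref = 78, delta_tm_alt = 0.5,
                              heteroduplex_shift = 1.0, width = 0.4,
                              t_start = 70, t_end = 90, t_step = 0.1,
                              amplitude_mean = 1, amplitude_cv = 0.05,
                              baseline_slope = 0.005, noise_sd = 0.003,
                              n_per_genotype = c(9, 9, 9),
                              ref_allele = "A", alt_allele = "G",
                              seed = 1L) {
  stopifnot(t_start < t_end, t_step > 0, width > 0,
            heteroduplex_shift > 0, noise_sd >= 0, amplitude_cv >= 0,
            length(n_per_genotype) == 3L, all(n_per_genotype >= 0))
  structure(
    list(tm_allele_ref = tm_allele_ref, delta_tm_alt = delta_tm_alt,
         heteroduplex_shift = heteroduplex_shift, width = width,
         t_start = t_start, t_end = t_end, t_step = t_step,
         amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
         baseline_slope = baseline_slope, noise_sd = noise_sd,
         n_per_genotype = as.integer(n_per_genotype),
         ref_allele = ref_allele, alt_allele = alt_allele,
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Duplex species of a genotype
#'
#' Homozygotes yield one homoduplex species; a heterozygote yields the four
#' equimolar duplex combinations of re-annealed PCR product: both
#' homoduplexes and both heteroduplexes, the latter destabilized by
#' \code{heteroduplex_shift}.
#'
#' @param genotype One of \code{"ref_hom"}, \code{"het"}, \code{"alt_hom"}
#'   (hyphenated forms accepted).
#' @param cfg A [simulation_config()].
#' @return A data frame with columns \code{tm}, \code{width},
#'   \code{weight}; weights sum to 1.
#' @export
genotype_species <- function(genotype, cfg) {
  g <- gsub("-", "_", genotype, fixed = TRUE)
  tm_ref <- cfg$tm_allele_ref
  tm_alt <- cfg$tm_allele_ref + cfg$delta_tm_alt
  sp <- switch(g,
    ref_hom = data.frame(tm = tm_ref, weight = 1),
    alt_hom = data.frame(tm = tm_alt, weight = 1),
    het = data.frame(
      tm = c(tm_ref, tm_alt,
             tm_ref - cfg$heteroduplex_shift,
             tm_alt - cfg$heteroduplex_shift),
      weight = rep(0.25, 4)),
    stop("unknown genotype token: '", genotype, "'", call. = FALSE))
  sp$width <- cfg$width
  sp[c("tm", "width", "weight")]
}

#' Simulate one melt curve
#'
#' Evaluates \code{F(T) = A * sum_i w_i * logistic((tm_i - T)/width_i) +
#' baseline_slope * (t_end - T) + noise} on the configured grid. The
#' amplitude \code{A} and the noise are drawn from R's current random
#' stream, so results are deterministic after \code{set.seed()}.
#'
#' @param species Data frame from [genotype_species()].
#' @param cfg A [simulation_config()].
#' @return Numeric vector of fluorescence values, one per grid point.
#' @export
melt_curve <- function(species, cfg) {
  if (!nrow(species)) stop("no duplex species given", call. = FALSE)
  tg <- seq(cfg$t_start, cfg$t_end, by = cfg$t_step)
  amp <- cfg$amplitude_mean * (1 + cfg$amplitude_cv * rnorm(1))
  f <- numeric(length(tg))
  for (i in seq_len(nrow(species)))
    f <- f + species$weight[i] /
      (1 + exp(-(species$tm[i] - tg) / species$width[i]))
  amp * f + cfg$baseline_slope * (cfg$t_end - tg) +
    rnorm(length(tg), sd = cfg$noise_sd)
}

#' Simulate an HRM plate with known genotypes
#'
#' @param cfg A [simulation_config()].
#' @return A list of class \code{simulated_plate} with \code{dataset} (a
#'   [melt_dataset]) and \code{truth}, a named character vector mapping
#'   each sample id to its true diploid genotype (e.g. \code{"A/G"}).
#' @examples
#' plate <- simulate_plate(simulation_config(n_per_genotype = c(2, 2, 2)))
#' plate$truth
#' @export
simulate_plate <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_per_genotype
  if (sum(n) < 1L) stop("plate needs at least one sample", call. = FALSE)
  set.seed(cfg$seed)
  genos <- c("ref_hom", "het", "alt_hom")
  truth_geno <- normalize_genotype(c(
    ref_hom = paste(cfg$ref_allele, cfg$ref_allele, sep = "/"),
    het = paste(cfg$ref_allele, cfg$alt_allele, sep = "/"),
    alt_hom = paste(cfg$alt_allele, cfg$alt_allele, sep = "/")))
  names(truth_geno) <- genos
  ids <- character(0); truth <- character(0)
  curves <- list()
  for (g in seq_along(genos)) {
    if (n[g] == 0L) next
    sp <- genotype_species(genos[g], cfg)
    for (j in seq_len(n[g])) {
      id <- sprintf("%s_%02d", genos[g], j)
      ids <- c(ids, id)
      truth[id] <- truth_geno[[genos[g]]]
      curves[[id]] <- melt_curve(sp, cfg)
    }
  }
  ds <- melt_dataset(seq(cfg$t_start, cfg$t_end, by = cfg$t_step),
                     do.call(cbind, curves), sample_ids = ids,
                     marker_id = "simulated")
  structure(list(dataset = ds, truth = truth, config = cfg),
            class = "simulated_plate")
}
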