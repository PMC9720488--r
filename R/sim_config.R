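#' Simulation configuration for a synthetic layer-hen batch
#'
#' Builds the parameter list that drives [simulate_batch()] and the
#' individual `simulate_*()` generators.  Defaults describe a single
#' purebred batch: 2,494 hens hatched in 3 weeks, ~500 maternal families
#' of ~5 full/half-sib hens, a lay curve peaking at 6.8 eggs/week at week
#' 29 of age and declining to 4.9 at week 92, natural-antibody (NAb)
#' titers with plate (146 levels) and age-at-sampling (112/123/124/138 d)
#' fixed effects, and a genotyped subset of 1,221 hens on ~5,000 SNPs
#' spread over macro-, micro- and Z-chromosomes.
#'
#' @param n_hens number of phenotyped hens in the batch.
#' @param family_size target number of hens per maternal family (dam).
#' @param n_sires number of sires; dams are nested within sires.
#' @param hatch_props proportions of hens in the 3 hatch weeks.
#' @param n_genotyped size of the genotyped subset (whole maternal
#'   families of `genotyped_per_family` hens are sampled until reached).
#' @param genotyped_per_family hens genotyped per selected family.
#' @param n_snps number of SNPs on the simulated array.
#' @param chromosomes chromosome labels; `"Z"` marks the sex chromosome.
#' @param chrom_weights relative share of SNPs per chromosome.
#' @param geno_missing_rate probability that a genotype call is missing.
#' @param maf_range range of founder allele frequencies (uniform draw).
#' @param nab per-isotype NAb model parameters: intercept `mu`, additive
#'   variance `sigma_a2`, residual variance `sigma_e2`, plate-effect
#'   variance `sigma_plate2`, and `age_effects` for the 4 sampling-age
#'   classes (112, 123, 124, 138 d).
#' @param n_plates number of ELISA plates (fixed effect levels).
#' @param n_rows number of barn rows (fixed effect levels).
#' @param egg egg-production model: anchor weeks/means of the batch lay
#'   curve, genetic variances of production level (`sigma2_level`, eggs^2)
#'   and persistency (`sigma2_pers`, squared slope multiplier), barn-row
#'   variance, disturbance process (Poisson `rate` per hen-week, depth
#'   uniform on [`depth_min`, `depth_max`], exponential recovery time
#'   constant `tau_weeks`), weekly culling `hazard`, first/last simulated
#'   week of age, and `allow_over7` to let free-running egg-collection
#'   intervals occasionally register >7 eggs in a week.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_hens = 2494,
                       family_size = 5,
                       n_sires = 125,
                       hatch_props = c(1, 1, 1) / 3,
                       n_genotyped = 1221,
                       genotyped_per_family = 5,
                       n_snps = 5000,
                       chromosomes = c(as.character(1:10), "Z"),
                       chrom_weights = c(20, 15, 12, 10, 8, 6, 5, 4, 3, 2, 7),
                       geno_missing_rate = 0,
                       maf_range = c(0.05, 0.5),
                       nab = list(
                         IgM = list(mu = 6.80, sigma_a2 = 0.5508,
                                    sigma_e2 = 0.8616, sigma_plate2 = 0.05,
                                    age_effects = c(0, 0.05, 0.05, 0.10)),
                         IgG = list(mu = 5.98, sigma_a2 = 0.3434,
                                    sigma_e2 = 1.3738, sigma_plate2 = 0.05,
                                    age_effects = c(0, 0.05, 0.05, 0.10))
                       ),
                       n_plates = 146,
                       n_rows = 12,
                       egg = list(
                         rise_start_week = 18,
                         peak_week = 29, peak_mean = 6.8,
                         end_week = 92, end_mean = 4.9,
                         sigma2_level = 0.09,
                         sigma2_pers = 0.0225,
                         cor_level_pers = 0,
                         sigma2_row = 0.0025,
                         disturbance = list(rate = 0.02, depth_min = 0.2,
                                            depth_max = 0.8, tau_weeks = 1.5),
                         hazard = 0.0024,
                         start_week = 19,
                         last_week = 93,
                         allow_over7 = FALSE
                       )) {
  cfg <- list(
    n_hens = as.integer(n_hens), family_size = as.integer(family_size),
    n_sires = as.integer(n_sires), hatch_props = hatch_props,
    n_genotyped = as.integer(n_genotyped),
    genotyped_per_family = as.integer(genotyped_per_family),
    n_snps = as.integer(n_snps), chromosomes = chromosomes,
    chrom_weights = chrom_weights, geno_missing_rate = geno_missing_rate,
    maf_range = maf_range, nab = nab, n_plates = as.integer(n_plates),
    n_rows = as.integer(n_rows), egg = egg
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_hens < 1L) stop("n_hens must be >= 1", call. = FALSE)
  if (cfg$family_size < 1L) stop("family_size must be >= 1", call. = FALSE)
  if (cfg$n_sires < 1L) stop("n_sires must be >= 1", call. = FALSE)
  if (length(cfg$hatch_props) != 3L || any(cfg$hatch_props < 0) ||
      abs(sum(cfg$hatch_props) - 1) > 1e-8)
    stop("hatch_props must be 3 non-negative proportions summing to 1",
         call. = FALSE)
  if (cfg$geno_missing_rate < 0 || cfg$geno_missing_rate > 1)
    stop("geno_missing_rate must be in [0,1]", call. = FALSE)
  for (iso in names(cfg$nab)) {
    p <- cfg$nab[[iso]]
    if (p$sigma_a2 < 0 || p$sigma_e2 < 0 || p$sigma_plate2 < 0)
      stop("NAb variances must be >= 0 (", iso, ")", call. = FALSE)
    if (length(p$age_effects) != 4L)
      stop("age_effects must have 4 levels (", iso, ")", call. = FALSE)
  }
  e <- cfg$egg
  if (e$peak_mean > 7)
    stop("peak_mean cannot exceed 7 eggs/week", call. = FALSE)
  if (e$sigma2_level < 0 || e$sigma2_pers < 0 || e$sigma2_row < 0)
    stop("egg genetic variances must be >= 0", call. = FALSE)
  d <- e$disturbance
  if (d$rate < 0) stop("disturbance rate must be >= 0", call. = FALSE)
  if (d$depth_min <= 0 || d$depth_max > 1 || d$depth_min > d$depth_max)
    stop("disturbance depths must satisfy 0 < depth_min <= depth_max <= 1",
         call. = FALSE)
  if (e$hazard < 0 || e$hazard > 1)
    stop("hazard must be in [0,1]", call. = FALSE)
  if (!(e$rise_start_week < e$peak_week && e$peak_week < e$end_week))
    stop("lay-curve weeks must satisfy rise_start < peak < end", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic layer-hen batch configuration\n")
  cat(sprintf("  hens: %d in 3 hatch weeks; ~%d maternal families (size %d), %d sires\n",
              x$n_hens, ceiling(x$n_hens / x$family_size), x$family_size,
              x$n_sires))
  cat(sprintf("  genotyped subset: %d hens, %d SNPs on %d chromosomes\n",
              x$n_genotyped, x$n_snps, length(x$chromosomes)))
  cat(sprintf("  lay curve: %.1f eggs/wk at wk %d -> %.1f at wk %d\n",
              x$egg$peak_mean, x$egg$peak_week, x$egg$end_mean,
              x$egg$end_week))
  invisible(x)
}
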