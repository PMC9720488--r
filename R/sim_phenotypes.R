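#' Simulate natural-antibody titers
#'
#' Generates KLH-binding NAb titers for the requested hens under the
#' fixed-effects-plus-animal model used downstream: titer = mu + plate
#' effect + age-at-sampling effect + additive genetic value + residual.
#' Hens are assigned to ELISA plates in sampling (pedigree) order, plate
#' effects draw from Normal(0, `sigma_plate2`).  The age-at-sampling class
#' follows the hatch week, as in a single-batch design where sampling day
#' is shared: hatch week 1 -> 112 d, week 2 -> 123 or 124 d, week 3 ->
#' 138 d; age class is therefore confounded with hatch week.
#'
#' @param ped pedigree (see [simulate_pedigree()]).
#' @param breeding_values named list of breeding-value vectors keyed by
#'   isotype (see [simulate_breeding_values()]), or a single vector used
#'   for all isotypes.
#' @param config a [sim_config()]; `config$nab` supplies per-isotype
#'   parameters, `config$n_plates` the plate count.
#' @param hens character vector of hen ids to phenotype; default all
#'   hens with a hatch week (the phenotyped generation).
#' @param isotypes which isotypes to simulate.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return data.frame `hen`, `isotype`, `titer`, `plate`, `age_class`,
#'   `hatch_week`.
#' @export
simulate_nab_phenotypes <- function(ped, breeding_values,
                                    config = sim_config(), hens = NULL,
                                    isotypes = names(config$nab),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(hens)) hens <- ped$animal[!is.na(ped$hatch_week)]
  hw <- ped$hatch_week[match(hens, ped$animal)]
  if (anyNA(hw))
    stop("all phenotyped hens must have a hatch week", call. = FALSE)
  n <- length(hens)
  # contiguous blocks in sampling order, sizes balanced across all plates
  plate <- ceiling(seq_len(n) * config$n_plates / n)
  # age class at blood sampling, confounded with hatch week
  age_levels <- c("112", "123", "124", "138")
  age_class <- character(n)
  age_class[hw == 1L] <- "112"
  age_class[hw == 2L] <- sample(c("123", "124"), sum(hw == 2L), replace = TRUE)
  age_class[hw == 3L] <- "138"

  out <- vector("list", length(isotypes))
  for (k in seq_along(isotypes)) {
    iso <- isotypes[k]
    par <- config$nab[[iso]]
    if (is.null(par)) stop("no NAb parameters for isotype ", iso,
                           call. = FALSE)
    bv <- if (is.list(breeding_values)) breeding_values[[iso]] else
      breeding_values
    if (is.null(bv)) stop("no breeding values for isotype ", iso,
                          call. = FALSE)
    a <- bv[hens]
    if (anyNA(a)) stop("breeding values missing for some hens",
                       call. = FALSE)
    plate_eff <- stats::rnorm(max(plate), 0, sqrt(par$sigma_plate2))
    titer <- par$mu + par$age_effects[match(age_class, age_levels)] +
      plate_eff[plate] + a + stats::rnorm(n, 0, sqrt(par$sigma_e2))
    out[[k]] <- data.frame(hen = hens, isotype = iso, titer = titer,
                           plate = plate, age_class = age_class,
                           hatch_week = hw, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
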