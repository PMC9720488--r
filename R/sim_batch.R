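# Whole-batch generator: pedigree, gene-dropped genotypes for the
# genotyped subset, NAb titers, and daily egg production, from one seed.

#' Select the genotyped subset of hens
#'
#' Mirrors a genotyping design where random maternal families are chosen
#' and a fixed number of random hens per family is genotyped, until the
#' target subset size is reached.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param config a [sim_config()] (`n_genotyped`, `genotyped_per_family`).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return character vector of hen ids.
#' @export
select_genotyped <- function(ped, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hens <- ped$animal[!is.na(ped$hatch_week)]
  dam <- ped$dam[match(hens, ped$animal)]
  fams <- split(hens, dam)
  fams <- fams[sample.int(length(fams))]
  chosen <- character(0)
  for (f in fams) {
    take <- sample(f, min(config$genotyped_per_family, length(f)))
    chosen <- c(chosen, take)
    if (length(chosen) >= config$n_genotyped) break
  }
  sort(utils::head(chosen, config$n_genotyped))
}

#' Simulate a complete synthetic batch
#'
#' Runs all generators with one seeded RNG stream: pedigree, SNP map,
#' gene-dropped genotypes, breeding values for NAb isotypes and for egg
#' production level/persistency (with configurable genetic correlation),
#' NAb titers for the genotyped subset, and the daily egg-laying /
#' collection process for every hen.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for the whole batch.
#' @param keep_full_panel also return genotypes of founders and
#'   non-genotyped hens (memory permitting).
#' @return list with `config`, `pedigree`, `snp_map`, `genotyped_ids`,
#'   `panel` (genotyped subset), optionally `panel_full`,
#'   `breeding_values` (list per trait), `nab`, `eggs` (see
#'   [simulate_egg_production()]).
#' @export
simulate_batch <- function(config = sim_config(), seed = 1,
                           keep_full_panel = FALSE) {
  validate_sim_config(config)
  set.seed(seed)
  ped <- simulate_pedigree(config)
  snp_map <- simulate_snp_map(config)
  panel_full <- simulate_genotypes(ped, snp_map, config)
  genotyped <- select_genotyped(ped, config)
  panel <- subset_panel(panel_full, genotyped)

  egg <- config$egg
  bv <- list()
  for (iso in names(config$nab))
    bv[[iso]] <- simulate_breeding_values(ped, config$nab[[iso]]$sigma_a2)
  bv$egg_level <- simulate_breeding_values(ped, egg$sigma2_level)
  pers_ind <- simulate_breeding_values(ped, egg$sigma2_pers)
  rho <- egg$cor_level_pers
  bv$egg_pers <- if (rho != 0 && egg$sigma2_level > 0) {
    rho * sqrt(egg$sigma2_pers / egg$sigma2_level) * bv$egg_level +
      sqrt(1 - rho^2) * pers_ind
  } else pers_ind

  nab <- simulate_nab_phenotypes(ped, bv, config, hens = genotyped)
  eggs <- simulate_egg_production(ped, bv$egg_level, bv$egg_pers, config)

  out <- list(config = config, pedigree = ped, snp_map = snp_map,
              genotyped_ids = genotyped, panel = panel,
              breeding_values = bv, nab = nab, eggs = eggs, seed = seed)
  if (keep_full_panel) out$panel_full <- panel_full
  out
}
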