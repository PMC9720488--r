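# End-to-end driver: simulate -> weekly production & resilience
# indicators -> SNP QC -> relationship matrices -> REML variance
# components per trait -> fixed-ratio mixed-model GWAS per trait.

pipeline_traits <- function() {
  c("IgM", "IgG",
    "ln_var_25-83", "skew_25-83", "r_auto_25-83",
    "ln_var_83-end", "skew_83-end", "r_auto_83-end")
}

# per-trait analysis table: response, fixed effects, animal id
trait_table <- function(trait, batch, indicators) {
  ped <- batch$pedigree
  if (trait %in% c("IgM", "IgG")) {
    nab <- batch$nab[batch$nab$isotype == trait, ]
    data.frame(animal = nab$hen, y = nab$titer,
               plate = factor(nab$plate), age_class = factor(nab$age_class),
               stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(trait, "_(?=[0-9])", perl = TRUE)[[1L]]
    col <- parts[1L]
    per <- parts[2L]
    ind <- indicators[indicators$period == per, ]
    hw <- ped$hatch_week[match(ind$hen, ped$animal)]
    row <- batch$eggs$rows$row[match(ind$hen, batch$eggs$rows$hen)]
    out <- data.frame(animal = ind$hen, y = ind[[col]],
                      hatch_week = factor(hw), row = factor(row),
                      stringsAsFactors = FALSE)
    out[!is.na(out$y), , drop = FALSE]
  }
}

trait_spec <- function(trait) {
  if (trait %in% c("IgM", "IgG"))
    model_spec("y", fixed = c("plate", "age_class"), animal = "animal")
  else
    model_spec("y", fixed = c("hatch_week", "row"), animal = "animal")
}

#' Run the full analysis pipeline on a synthetic batch
#'
#' Simulates a batch, computes weekly production, the batch mean curve
#' and resilience indicators, applies SNP QC, builds the pedigree A and
#' VanRaden G matrices, estimates variance components per trait with the
#' REML animal model, and runs the fixed-ratio mixed-model GWAS for each
#' trait on the genotyped subset.  Artifacts (CSV/TSV/JSON) are written
#' to `out_dir` when given.
#'
#' @param config a [sim_config()]; choose a small batch for interactive
#'   use.
#' @param seed integer seed for the simulated batch.
#' @param out_dir output directory (`NULL` = don't write files).
#' @param traits subset of `pipeline_traits()` to analyse.
#' @param gwas run the per-SNP association scan (the slow stage).
#' @return (invisibly) list with `batch`, `indicators`, `qc`, `A`, `G`,
#'   `varcomp` and `gwas` per trait, and a `summary` table.
#' @export
run_pipeline <- function(config = sim_config(n_hens = 500, n_snps = 1000,
                                             n_genotyped = 250,
                                             n_sires = 25, n_plates = 30),
                         seed = 1, out_dir = NULL,
                         traits = pipeline_traits(), gwas = TRUE) {
  t0 <- proc.time()[3]
  stage <- function(msg) message(sprintf("[%6.1fs] %s",
                                         proc.time()[3] - t0, msg))
  stage("simulating batch")
  batch <- simulate_batch(config, seed = seed)

  stage("weekly production and resilience indicators")
  weekly <- weekly_production(batch$eggs$log)
  curve <- batch_mean(weekly)
  indicators <- resilience_indicators(weekly, curve)
  fc <- attr(indicators, "filter_counts")
  stage(sprintf("  hens below %d eggs: %s", 20L,
                paste(names(fc), fc, sep = "=", collapse = ", ")))

  stage("SNP quality control")
  qc <- qc_pipeline(batch$panel)
  stage(sprintf("  retained %d / %d SNPs", qc$report$n_retained,
                qc$report$n_input_snps))

  stage("relationship matrices")
  A <- additive_relationship_matrix(batch$pedigree)
  G <- stabilize_grm(vanraden_grm(qc$panel))

  vc_list <- list()
  gw_list <- list()
  summary_rows <- list()
  for (tr in traits) {
    stage(sprintf("trait %s: variance components", tr))
    dat <- trait_table(tr, batch, indicators)
    spec <- trait_spec(tr)
    fit <- fit_animal_model(dat, spec, K = A)
    lrt <- lrt_additive_variance(fit)
    vc_list[[tr]] <- fit
    lam <- NA_real_
    nsug <- NA_integer_
    nsig <- NA_integer_
    if (gwas) {
      stage(sprintf("trait %s: GWAS (%d SNPs)", tr,
                    ncol(qc$panel$calls)))
      gw <- run_gwas(dat, spec, qc$panel, G, ratio = fit$ratio)
      gw_list[[tr]] <- gw
      lam <- gw$summary$lambda_gc
      nsug <- gw$summary$n_suggestive
      nsig <- gw$summary$n_significant
    }
    summary_rows[[tr]] <- data.frame(
      trait = tr, n = fit$n, sigma_a2 = fit$sigma_a2,
      sigma_e2 = fit$sigma_e2, h2 = fit$h2, se_h2 = fit$se_h2,
      lrt_p = lrt$p_value, lambda_gc = lam, n_suggestive = nsug,
      n_significant = nsig, stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pedigree(batch$pedigree, file.path(out_dir, "pedigree.csv"))
    write_genotypes(batch$panel, file.path(out_dir, "genotypes.tsv"),
                    file.path(out_dir, "snp_map.tsv"))
    write_egg_log(batch$eggs$log, file.path(out_dir, "egg_log.csv"))
    utils::write.csv(batch$nab, file.path(out_dir, "nab.csv"),
                     row.names = FALSE)
    utils::write.csv(indicators, file.path(out_dir, "indicators.csv"),
                     row.names = FALSE, na = "")
    jsonlite::write_json(
      list(seed = batch$seed,
           qc = qc$report[c("n_input_snps", "n_dropped_missingness",
                            "n_masked_rare", "n_masked_z_het",
                            "n_dropped_class_rule", "n_retained")],
           filter_counts = as.list(fc)),
      file.path(out_dir, "qc_report.json"), auto_unbox = TRUE)
    for (tr in names(vc_list)) {
      fit <- vc_list[[tr]]
      jsonlite::write_json(
        fit[c("sigma_a2", "sigma_e2", "h2", "se_h2", "ratio", "logL",
              "logL_reduced", "converged", "n")],
        file.path(out_dir, sprintf("varcomp_%s.json", gsub("/", "_", tr))),
        auto_unbox = TRUE, digits = NA)
      if (!is.null(gw_list[[tr]]))
        utils::write.table(
          gw_list[[tr]]$results,
          file.path(out_dir, sprintf("gwas_%s.tsv", gsub("/", "_", tr))),
          sep = "\t", row.names = FALSE, quote = FALSE)
    }
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  stage("done")
  invisible(list(batch = batch, indicators = indicators, qc = qc,
                 A = A, G = G, varcomp = vc_list, gwas = gw_list,
                 summary = summary))
}
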