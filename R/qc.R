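# SNP quality-control cascade: missingness filter, rare-genotype-class
# masking (with Z-heterozygote masking), and the underfilled-SNP discard
# rule, with a report whose arithmetic closes exactly.

geno_class_counts <- function(calls) {
  rbind(`0` = colSums(calls == 0L, na.rm = TRUE),
        `1` = colSums(calls == 1L, na.rm = TRUE),
        `2` = colSums(calls == 2L, na.rm = TRUE))
}

#' Drop SNPs with too many missing calls
#'
#' A SNP is discarded when its missing-call fraction strictly exceeds
#' `max_missing`.
#'
#' @param panel a [geno_panel()].
#' @param max_missing maximum tolerated missing fraction (default 10%).
#' @return list `panel` (filtered) and `dropped` (SNP ids).
#' @export
filter_missingness <- function(panel, max_missing = 0.10) {
  stopifnot(inherits(panel, "geno_panel"))
  if (ncol(panel$calls) == 0L)
    return(list(panel = panel, dropped = character(0)))
  frac <- colMeans(is.na(panel$calls))
  drop <- frac > max_missing
  list(panel = geno_panel(panel$calls[, !drop, drop = FALSE],
                          panel$map[!drop, , drop = FALSE]),
       dropped = colnames(panel$calls)[drop])
}

#' Mask rare genotype classes and Z heterozygotes
#'
#' For each SNP, every genotype class observed in fewer than `min_count`
#' individuals has all its calls set to missing.  On the Z chromosome,
#' heterozygous calls are additionally masked regardless of count: hens
#' carry a single Z allele, so a Z heterozygote is a genotyping artefact.
#'
#' @param panel a [geno_panel()].
#' @param min_count minimum class size (default 10).
#' @return list `panel` (masked calls), `n_masked_rare`,
#'   `n_masked_z_het` (masked-call counts).
#' @export
mask_rare_classes <- function(panel, min_count = 10) {
  stopifnot(inherits(panel, "geno_panel"))
  calls <- panel$calls
  n_z_het <- 0L
  if (any(panel$map$is_z) && ncol(calls)) {
    zc <- which(panel$map$is_z)
    het <- !is.na(calls[, zc, drop = FALSE]) &
      calls[, zc, drop = FALSE] == 1L
    n_z_het <- sum(het)
    tmp <- calls[, zc, drop = FALSE]
    tmp[het] <- NA_integer_
    calls[, zc] <- tmp
  }
  cc <- geno_class_counts(calls)
  n_rare <- 0L
  for (g in 0:2) {
    rare <- cc[as.character(g), ] > 0L & cc[as.character(g), ] < min_count
    if (any(rare)) {
      sub <- calls[, rare, drop = FALSE]
      hit <- !is.na(sub) & sub == g
      n_rare <- n_rare + sum(hit)
      sub[hit] <- NA_integer_
      calls[, rare] <- sub
    }
  }
  list(panel = geno_panel(calls, panel$map),
       n_masked_rare = n_rare, n_masked_z_het = n_z_het)
}

#' Discard SNPs with fewer than two analysable genotype classes
#'
#' After masking, a SNP is dropped when fewer than 2 of its genotype
#' classes have at least `min_count` individuals — it cannot support a
#' categorical SNP effect.  (For Z-linked SNPs, which have at most 2
#' classes in hens, the same criterion applies.)
#'
#' @param panel a [geno_panel()], already masked by [mask_rare_classes()].
#' @param min_count minimum class size (default 10).
#' @return list `panel` (filtered) and `dropped` (SNP ids).
#' @export
drop_underfilled_snps <- function(panel, min_count = 10) {
  stopifnot(inherits(panel, "geno_panel"))
  if (ncol(panel$calls) == 0L)
    return(list(panel = panel, dropped = character(0)))
  cc <- geno_class_counts(panel$calls)
  n_ok <- colSums(cc >= min_count)
  drop <- n_ok < 2L
  list(panel = geno_panel(panel$calls[, !drop, drop = FALSE],
                          panel$map[!drop, , drop = FALSE]),
       dropped = colnames(panel$calls)[drop])
}

#' Full SNP quality-control cascade
#'
#' Applies, in order: the missingness filter, rare-class and
#' Z-heterozygote masking, and the underfilled-SNP discard rule.  SNP
#' order is preserved and the pipeline is idempotent.
#'
#' @param panel a [geno_panel()].
#' @param max_missing maximum missing-call fraction per SNP.
#' @param min_count minimum genotype-class size.
#' @return list `panel` (the QC'd panel) and `report` (class
#'   `qc_report`): input/retained/dropped counts, masked-call counts, and
#'   per-SNP genotype-class counts before and after.
#' @export
qc_pipeline <- function(panel, max_missing = 0.10, min_count = 10) {
  stopifnot(inherits(panel, "geno_panel"))
  counts_before <- geno_class_counts(panel$calls)
  colnames(counts_before) <- colnames(panel$calls)

  s1 <- filter_missingness(panel, max_missing)
  s2 <- mask_rare_classes(s1$panel, min_count)
  s3 <- drop_underfilled_snps(s2$panel, min_count)

  counts_after <- geno_class_counts(s3$panel$calls)
  colnames(counts_after) <- colnames(s3$panel$calls)

  report <- structure(list(
    n_input_snps = ncol(panel$calls),
    n_dropped_missingness = length(s1$dropped),
    n_dropped_class_rule = length(s3$dropped),
    n_retained = ncol(s3$panel$calls),
    dropped_missingness = s1$dropped,
    dropped_class_rule = s3$dropped,
    n_masked_rare = s2$n_masked_rare,
    n_masked_z_het = s2$n_masked_z_het,
    class_counts_before = counts_before,
    class_counts_after = counts_after
  ), class = "qc_report")
  stopifnot(report$n_input_snps ==
              report$n_retained + report$n_dropped_missingness +
              report$n_dropped_class_rule)
  list(panel = s3$panel, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality control\n")
  cat(sprintf("  input SNPs:                %d\n", x$n_input_snps))
  cat(sprintf("  dropped, missingness:      %d\n", x$n_dropped_missingness))
  cat(sprintf("  masked calls (rare class): %d\n", x$n_masked_rare))
  cat(sprintf("  masked calls (Z het):      %d\n", x$n_masked_z_het))
  cat(sprintf("  dropped, <2 filled classes:%d\n", x$n_dropped_class_rule))
  cat(sprintf("  retained:                  %d\n", x$n_retained))
  invisible(x)
}
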