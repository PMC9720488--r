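# Single-SNP mixed-model association with a fixed variance ratio.  The
# phenotypic covariance (up to scale) V = ratio * G + I is whitened once
# through the spectral decomposition of G; each SNP then enters the
# rotated ordinary regression as a categorical factor (one level per
# genotype class, most frequent class as reference) and is tested with a
# conditional (incremental) F given all other fixed effects.

# whitened GLS incremental F-test for SNP indicator columns
# (shared by the batched fast path and the per-SNP missing-call path)
snp_ftest_core <- function(E, r, RSS0, n, p, counts_present) {
  q0 <- ncol(E)
  keep <- seq_len(q0)
  S <- crossprod(E)
  # drop near-aliased indicator columns (weakest residual signal first)
  while (length(keep) > 1L &&
         kappa(S[keep, keep, drop = FALSE]) > 1e10) {
    keep <- keep[-which.min(diag(S)[keep])]
  }
  E <- E[, keep, drop = FALSE]
  S <- crossprod(E)
  if (any(diag(S) < 1e-12 * n))
    return(NULL)
  cvec <- crossprod(E, r)
  beta <- tryCatch(solve(S, cvec), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  q <- ncol(E)
  SSexp <- drop(crossprod(cvec, beta))
  df_den <- n - p - q
  RSS1 <- max(RSS0 - SSexp, 0)
  Fstat <- (SSexp / q) / (RSS1 / df_den)
  list(beta = drop(beta), kept = keep, F = Fstat, df_num = q,
       df_den = df_den,
       p = stats::pf(Fstat, q, df_den, lower.tail = FALSE))
}

#' Mixed-model association test for a single SNP
#'
#' Generalised-least-squares fit of the trait model plus the SNP as a
#' categorical factor under V = ratio * G + I (up to scale), with the
#' variance ratio sigma_a2/sigma_e2 held fixed.  Individuals with a
#' missing call are excluded for this SNP.  The SNP factor is tested
#' with a conditional Wald F given all other fixed effects; the
#' reference genotype class is the most frequent one.
#'
#' @param data data.frame with response, fixed-effect and animal-id
#'   columns (see [model_spec()]).
#' @param spec a [model_spec()].
#' @param snp_calls named vector of 0/1/2/NA calls (names = animal ids).
#' @param G genomic relationship matrix covering the animals.
#' @param ratio fixed variance ratio sigma_a2/sigma_e2 (>= 0; 0 reduces
#'   the test to ordinary fixed-effects ANOVA).
#' @return one-row data.frame with class effects (vs reference), the
#'   conditional F, degrees of freedom and p-value.
#' @export
snp_association <- function(data, spec, snp_calls, G, ratio) {
  stopifnot(inherits(spec, "model_spec"))
  if (ratio < 0) stop("ratio must be >= 0", call. = FALSE)
  cols <- c(spec$response, spec$fixed, spec$animal)
  cc <- stats::complete.cases(data[cols])
  data <- data[cc, , drop = FALSE]
  ids <- as.character(data[[spec$animal]])
  g <- snp_calls[ids]
  use <- !is.na(g)
  if (length(unique(g[use])) < 2L)
    return(data.frame(n_used = sum(use), beta_g0 = NA_real_,
                      beta_g1 = NA_real_, beta_g2 = NA_real_,
                      F = NA_real_, df_num = NA_integer_,
                      df_den = NA_real_, p = NA_real_,
                      untestable = TRUE))
  data <- data[use, , drop = FALSE]
  ids <- ids[use]
  g <- g[use]
  n <- length(ids)

  y <- data[[spec$response]]
  X <- build_fixed_design(data, spec$fixed)$X
  V <- ratio * G[ids, ids] + diag(n)
  R <- chol(V)
  yw <- forwardsolve(t(R), y)
  Xw <- forwardsolve(t(R), X)
  qrX <- qr(Xw)
  p <- qrX$rank
  r <- stats::resid(stats::lm.fit(Xw, yw))
  RSS0 <- sum(r^2)

  counts <- c(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  present <- which(counts > 0L) - 1L
  ref <- present[which.max(counts[present + 1L])]
  non_ref <- setdiff(present, ref)
  Ind <- vapply(non_ref, function(k) as.numeric(g == k), numeric(n))
  Indw <- forwardsolve(t(R), Ind)
  E <- Indw - Xw %*% qr.coef(qrX, Indw)
  ft <- snp_ftest_core(E, r, RSS0, n, p, counts[non_ref + 1L])
  beta <- rep(NA_real_, 3)
  if (!is.null(ft)) beta[non_ref[ft$kept] + 1L] <- ft$beta
  data.frame(n_used = n,
             beta_g0 = beta[1], beta_g1 = beta[2], beta_g2 = beta[3],
             F = if (is.null(ft)) NA_real_ else ft$F,
             df_num = if (is.null(ft)) NA_integer_ else ft$df_num,
             df_den = if (is.null(ft)) NA_real_ else ft$df_den,
             p = if (is.null(ft)) NA_real_ else ft$p,
             untestable = is.null(ft))
}

#' Genome-wide single-SNP mixed-model association
#'
#' Runs the fixed-ratio mixed-model test of [snp_association()] for every
#' SNP in the panel, batching the whitening through one spectral
#' decomposition of G for SNPs with complete calls (SNPs with missing
#' calls fall back to an exact per-SNP subset fit).  Adds Storey
#' q-values, the genomic inflation factor, and FDR significance calls.
#'
#' @param data data.frame with response, fixed effects and animal ids.
#' @param spec a [model_spec()].
#' @param panel a QC'd [geno_panel()] covering (a superset of) the
#'   phenotyped animals.
#' @param G genomic relationship matrix (e.g. [vanraden_grm()], possibly
#'   [stabilize_grm()]d).
#' @param ratio fixed variance ratio, or a [fit_animal_model()] result
#'   whose whole-batch `ratio` is reused for every SNP.
#' @param fdr_suggestive,fdr_significant FDR thresholds for the
#'   suggestive and significant calls.
#' @return list with `results` (per-SNP data.frame, map order) and
#'   `summary` (`lambda_gc`, `n_snps_tested`, `n_suggestive`,
#'   `n_significant`, `ratio`).
#' @export
run_gwas <- function(data, spec, panel, G, ratio,
                     fdr_suggestive = 0.10, fdr_significant = 0.05) {
  stopifnot(inherits(panel, "geno_panel"), inherits(spec, "model_spec"))
  if (inherits(ratio, "varcomp_fit")) ratio <- ratio$ratio
  if (ratio < 0) stop("ratio must be >= 0", call. = FALSE)
  if (ncol(panel$calls) == 0L) stop("empty genotype panel", call. = FALSE)

  cols <- c(spec$response, spec$fixed, spec$animal)
  cc <- stats::complete.cases(data[cols])
  data <- data[cc, , drop = FALSE]
  ids <- intersect(as.character(data[[spec$animal]]), rownames(panel$calls))
  if (length(ids) < 3L)
    stop("too few animals with both phenotype and genotypes", call. = FALSE)
  data <- data[match(ids, as.character(data[[spec$animal]])), , drop = FALSE]
  calls <- panel$calls[ids, , drop = FALSE]
  m <- ncol(calls)
  n <- length(ids)

  y <- data[[spec$response]]
  X <- build_fixed_design(data, spec$fixed)$X

  eig <- kinship_eigen(G, ids)
  s <- 1 / sqrt(ratio * eig$values + 1)
  U <- eig$vectors
  yt <- s * drop(crossprod(U, y))
  Xt <- s * crossprod(U, X)
  qrX <- qr(Xt)
  p <- qrX$rank
  r <- stats::resid(stats::lm.fit(Xt, yt))
  RSS0 <- sum(r^2)

  n0 <- colSums(calls == 0L, na.rm = TRUE)
  n1 <- colSums(calls == 1L, na.rm = TRUE)
  n2 <- colSums(calls == 2L, na.rm = TRUE)
  any_na <- colSums(is.na(calls)) > 0L

  # batched whitened + residualised class indicators (complete SNPs)
  storage.mode(calls) <- "double"
  resid_ind <- function(Ind) {
    It <- s * crossprod(U, Ind)
    It - Xt %*% qr.coef(qrX, It)
  }
  ok0 <- calls == 0
  ok0[is.na(ok0)] <- FALSE
  ok1 <- calls == 1
  ok1[is.na(ok1)] <- FALSE
  ok2 <- calls == 2
  ok2[is.na(ok2)] <- FALSE
  E0 <- resid_ind(ok0)
  E1 <- resid_ind(ok1)
  E2 <- resid_ind(ok2)

  n_used <- rep.int(n, m)
  beta_out <- matrix(NA_real_, m, 3)
  Fv <- rep(NA_real_, m)
  dfn <- rep(NA_integer_, m)
  dfd <- rep(NA_real_, m)
  pv <- rep(NA_real_, m)
  untest <- rep(FALSE, m)
  Elist <- list(E0, E1, E2)
  for (j in seq_len(m)) {
    counts <- c(n0[j], n1[j], n2[j])
    present <- which(counts > 0L)           # 1-based genotype class + 1
    if (length(present) < 2L) {
      n_used[j] <- sum(counts)
      untest[j] <- TRUE
      next
    }
    if (any_na[j]) {
      one <- snp_association(data, spec, stats::setNames(
        as.integer(calls[, j]), ids), G, ratio)
      n_used[j] <- one$n_used
      beta_out[j, ] <- c(one$beta_g0, one$beta_g1, one$beta_g2)
      Fv[j] <- one$F
      dfn[j] <- one$df_num
      dfd[j] <- one$df_den
      pv[j] <- one$p
      untest[j] <- one$untestable
      next
    }
    ref <- present[which.max(counts[present])]
    non_ref <- setdiff(present, ref)
    E <- vapply(non_ref, function(k) Elist[[k]][, j], numeric(n))
    ft <- snp_ftest_core(E, r, RSS0, n, p, counts[non_ref])
    if (is.null(ft)) {
      untest[j] <- TRUE
      next
    }
    beta_out[j, non_ref[ft$kept]] <- ft$beta
    Fv[j] <- ft$F
    dfn[j] <- ft$df_num
    dfd[j] <- ft$df_den
    pv[j] <- ft$p
  }
  out <- cbind(panel$map[c("snp", "chr", "pos")],
               data.frame(n_used = n_used, beta_g0 = beta_out[, 1],
                          beta_g1 = beta_out[, 2], beta_g2 = beta_out[, 3],
                          F = Fv, df_num = dfn, df_den = dfd, p = pv,
                          untestable = untest))
  out$n0 <- n0
  out$n1 <- n1
  out$n2 <- n2

  tested <- !is.na(out$p)
  out$q <- NA_real_
  if (any(tested)) out$q[tested] <- qvalues(out$p[tested])
  out$neg_log10_p <- -log10(out$p)
  out$suggestive <- !is.na(out$q) & out$q < fdr_suggestive
  out$significant <- !is.na(out$q) & out$q < fdr_significant
  rownames(out) <- NULL

  summary <- list(
    lambda_gc = if (any(tested)) genomic_inflation(out$p[tested]) else
      NA_real_,
    n_snps_tested = sum(tested),
    n_suggestive = sum(out$suggestive),
    n_significant = sum(out$significant),
    ratio = ratio
  )
  list(results = out, summary = summary)
}

#' Genomic inflation factor
#'
#' lambda = median(observed chi2) / median(chi2_1), with each p-value
#' converted to the 1-df chi-square quantile it corresponds to (the
#' 1-df convention is kept even for 2-df SNP tests).
#'
#' @param p_values vector of p-values in (0, 1].
#' @return the inflation factor lambda.
#' @export
genomic_inflation <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no p-values", call. = FALSE)
  if (any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 by Storey's smoother — pi0(lambda) =
#' mean(p > lambda) / (1 - lambda) on the grid lambda = 0.05, 0.10, ...,
#' 0.95, smoothed with a cubic smoothing spline (df = 3) and evaluated at
#' the grid maximum, clipped to (0, 1] — then applies the step-up rule
#' q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j).  With fewer
#' than `min_m` p-values the smoother is unreliable and pi0 falls back to
#' 1, in which case the q-values equal Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param p_values vector of p-values in (0, 1].
#' @param pi0 optional: force the null proportion (e.g. 1).
#' @param min_m minimum number of p-values for the pi0 smoother.
#' @return q-values, monotone non-decreasing in p.
#' @export
qvalues <- function(p_values, pi0 = NULL, min_m = 100L) {
  p <- p_values
  if (anyNA(p)) stop("p-values must not be NA", call. = FALSE)
  if (any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(p)
  if (is.null(pi0)) {
    if (m < min_m) {
      pi0 <- 1
    } else {
      lam <- seq(0.05, 0.95, by = 0.05)
      pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
      pi0 <- stats::predict(fit, x = max(lam))$y
      pi0 <- min(pi0, 1)
      if (pi0 <= 0) pi0 <- 1
    }
  }
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]", call. = FALSE)
  ord <- order(p, decreasing = TRUE)
  ranked <- pi0 * m * p[ord] / seq(m, 1)
  q <- cummin(pmin(ranked, 1))
  out <- numeric(m)
  out[ord] <- q
  out
}

#' FDR significance calls
#'
#' Counts SNPs below the suggestive and significant FDR thresholds.
#'
#' @param q_values vector of q-values (NA = untested).
#' @param fdr_suggestive,fdr_significant thresholds (strict `<`).
#' @return list `n_suggestive`, `n_significant`, and logical flag vectors
#'   `suggestive`, `significant`.
#' @export
significance_calls <- function(q_values, fdr_suggestive = 0.10,
                               fdr_significant = 0.05) {
  sug <- !is.na(q_values) & q_values < fdr_suggestive
  sig <- !is.na(q_values) & q_values < fdr_significant
  list(n_suggestive = sum(sug), n_significant = sum(sig),
       suggestive = sug, significant = sig)
}
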