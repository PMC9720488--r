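# REML animal model with a single genomic or pedigree relationship
# matrix.  The restricted likelihood is profiled on the variance ratio
# lambda = sigma_a2 / sigma_e2 after a one-off eigendecomposition of the
# relationship matrix (exact for one record per animal), so many fits can
# reuse the same decomposition.  Standard errors come from the inverse
# expected information of (sigma_a2, sigma_e2); h2 by the delta method.

#' Specify an animal model
#'
#' @param response name of the response column.
#' @param fixed character vector of categorical fixed-effect columns
#'   (fitted in order after the intercept).
#' @param animal name of the animal-id column mapping observations to the
#'   relationship matrix.
#' @param kinship which relationship source the model expects
#'   (`"pedigree_A"` or `"genomic_G"`); informational.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(response, fixed = character(),
                       animal = "animal",
                       kinship = c("pedigree_A", "genomic_G")) {
  kinship <- match.arg(kinship)
  structure(list(response = response, fixed = fixed, animal = animal,
                 kinship = kinship), class = "model_spec")
}

# design matrix for intercept + categorical fixed effects, with aliased
# columns dropped deterministically (first occurrence kept) by
# Gram-Schmidt rank screening
build_fixed_design <- function(data, fixed) {
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (f in fixed) {
    v <- factor(data[[f]])
    if (nlevels(v) > 1L) {
      mm <- stats::model.matrix(~ v)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(f, levels(v)[-1L])
      X <- cbind(X, mm)
    }
  }
  keep <- logical(ncol(X))
  Q <- matrix(0, n, 0)
  dropped <- character(0)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    r <- v - Q %*% crossprod(Q, v)
    if (sqrt(sum(r^2)) > 1e-8 * max(1, sqrt(sum(v^2)))) {
      keep[j] <- TRUE
      Q <- cbind(Q, r / sqrt(sum(r^2)))
    } else {
      dropped <- c(dropped, colnames(X)[j])
    }
  }
  if (length(dropped))
    warning("dropping aliased fixed-effect column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  list(X = X[, keep, drop = FALSE], dropped = dropped)
}

# profiled REML log-likelihood at variance ratio lambda, on rotated data
reml_profile <- function(lambda, d, yt, Xt) {
  n <- length(yt)
  p <- ncol(Xt)
  h <- lambda * d + 1
  Xw <- Xt / h
  XtHiX <- crossprod(Xt, Xw)
  Xty <- crossprod(Xw, yt)
  R <- chol(XtHiX)
  beta <- backsolve(R, forwardsolve(t(R), Xty))
  yPy <- sum(yt^2 / h) - drop(crossprod(Xty, beta))
  sigma_e2 <- yPy / (n - p)
  logL <- -0.5 * ((n - p) * (log(2 * pi) + log(sigma_e2) + 1) +
                    sum(log(h)) + 2 * sum(log(diag(R))))
  list(logL = logL, sigma_e2 = sigma_e2, beta = drop(beta))
}

# average-information matrix for (sigma_a2, sigma_e2) in the rotated
# model: AI_kl = 0.5 * y'P V_k P V_l P y with V_k diagonal (d or 1);
# quadratic forms a'Pb via P = A - A Xt B^-1 Xt' A with A = diag(1/v)
average_information <- function(yt, Xt, v, d) {
  a <- 1 / v
  B <- crossprod(Xt, Xt * a)
  Bi <- chol2inv(chol(B))
  quad_P <- function(x, z) {
    drop(sum(x * a * z) -
           crossprod(crossprod(Xt, a * x), Bi %*% crossprod(Xt, a * z)))
  }
  beta <- Bi %*% crossprod(Xt, a * yt)
  Py <- a * drop(yt - Xt %*% beta)
  qa <- d * Py
  qe <- Py
  matrix(0.5 * c(quad_P(qa, qa), quad_P(qa, qe),
                 quad_P(qa, qe), quad_P(qe, qe)), 2L)
}

# delta-method SE of h2 = sa2/(sa2+se2) from the sampling covariance of
# (sa2, se2)
h2_delta_se <- function(sigma_a2, sigma_e2, cov_sigma) {
  tot <- sigma_a2 + sigma_e2
  grad <- c(sigma_e2, -sigma_a2) / tot^2
  sqrt(max(0, drop(t(grad) %*% cov_sigma %*% grad)))
}

#' Fit a REML animal model
#'
#' Fits y = X b + a + e with a ~ N(0, K sigma_a2), e ~ N(0, I sigma_e2),
#' one record per animal.  The restricted likelihood is maximised exactly
#' over the variance ratio lambda = sigma_a2/sigma_e2 on the spectral
#' decomposition of K (Brent search on log lambda), with sigma_e2 and the
#' fixed effects profiled out.  Aliased fixed-effect columns (e.g. a
#' factor confounded with another) are dropped with a warning, first
#' occurrence kept.  A flat profile (e.g. K = I with one record per
#' animal, where only sigma_a2 + sigma_e2 is identifiable) is flagged via
#' `converged = FALSE`.
#'
#' @param data data.frame holding response, fixed-effect and animal-id
#'   columns; rows with missing values are dropped.
#' @param spec a [model_spec()].
#' @param K relationship matrix covering all animals in `data` (ignored
#'   when `eig` is given).
#' @param eig optional [kinship_eigen()] of K over exactly the analysed
#'   animals, to reuse across fits.
#' @param lambda_bounds search range for the variance ratio.
#' @return object of class `varcomp_fit`: variance components, h2 with
#'   delta-method SE, REML log-likelihoods of the full and no-animal
#'   (lambda = 0) models, convergence flags and metadata.
#' @export
fit_animal_model <- function(data, spec, K = NULL, eig = NULL,
                             lambda_bounds = c(1e-6, 1e6)) {
  stopifnot(inherits(spec, "model_spec"))
  cols <- c(spec$response, spec$fixed, spec$animal)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cc <- stats::complete.cases(data[cols])
  data <- data[cc, , drop = FALSE]
  y <- data[[spec$response]]
  ids <- as.character(data[[spec$animal]])
  if (anyDuplicated(ids))
    stop("one record per animal is required", call. = FALSE)
  n <- length(y)
  if (n < 2L || stats::var(y) == 0)
    stop("need >= 2 animals and non-degenerate response", call. = FALSE)

  des <- build_fixed_design(data, spec$fixed)
  X <- des$X
  p <- ncol(X)

  if (is.null(eig)) {
    if (is.null(K)) stop("provide K or eig", call. = FALSE)
    eig <- kinship_eigen(K, ids)
  } else {
    stopifnot(inherits(eig, "kinship_eigen"))
    if (!identical(eig$ids, ids))
      stop("eig was computed for a different animal set/order", call. = FALSE)
  }
  d <- eig$values
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  n_evals <- 0L
  obj <- function(loglam) {
    n_evals <<- n_evals + 1L
    reml_profile(exp(loglam), d, yt, Xt)$logL
  }
  lo <- log(lambda_bounds[1])
  hi <- log(lambda_bounds[2])
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-8)
  lambda <- exp(opt$maximum)
  at_opt <- reml_profile(lambda, d, yt, Xt)
  l_lo <- reml_profile(lambda_bounds[1], d, yt, Xt)$logL
  l_hi <- reml_profile(lambda_bounds[2], d, yt, Xt)$logL
  reduced <- reml_profile(0, d, yt, Xt)

  flat <- (max(at_opt$logL, l_lo, l_hi) -
             min(at_opt$logL, l_lo, l_hi)) < 1e-6
  at_lower <- l_lo >= at_opt$logL - 1e-8
  if (at_lower && !flat) {
    lambda <- 0
    at_opt <- reduced
  }

  sigma_e2 <- at_opt$sigma_e2
  floor_a <- 1e-8 * stats::var(y)
  sigma_a2 <- max(lambda * sigma_e2, if (lambda > 0) floor_a else 0)
  h2 <- sigma_a2 / (sigma_a2 + sigma_e2)

  # average-information matrix for (sigma_a2, sigma_e2) at the estimates
  v <- pmax(sigma_a2 * d + sigma_e2, 1e-12)
  Fi <- average_information(yt, Xt, v, d)
  cov_sigma <- tryCatch(solve(Fi), error = function(e)
    matrix(NA_real_, 2L, 2L))
  se_h2 <- h2_delta_se(sigma_a2, sigma_e2, cov_sigma)

  structure(list(
    sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, h2 = h2, se_h2 = se_h2,
    se_sigma_a2 = sqrt(pmax(0, cov_sigma[1, 1])),
    se_sigma_e2 = sqrt(pmax(0, cov_sigma[2, 2])),
    cov_sigma = cov_sigma, ratio = lambda,
    logL = at_opt$logL, logL_reduced = reduced$logL,
    beta = at_opt$beta, fixed_names = colnames(X),
    converged = !flat, flat_likelihood = flat,
    boundary = lambda <= lambda_bounds[1] || lambda >= lambda_bounds[2] ||
      lambda == 0,
    n = n, rank_X = p, dropped_aliased = des$dropped,
    n_evals = n_evals, ids = ids, response = spec$response
  ), class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat(sprintf("REML animal model for '%s' (n = %d)\n", x$response, x$n))
  cat(sprintf("  sigma_a2 = %.4f  sigma_e2 = %.4f  ratio = %.4f\n",
              x$sigma_a2, x$sigma_e2, x$ratio))
  cat(sprintf("  h2 = %.3f (SE %.3f)\n", x$h2, x$se_h2))
  cat(sprintf("  REML logL = %.3f (no-animal model: %.3f)\n",
              x$logL, x$logL_reduced))
  if (!x$converged) cat("  WARNING: flat likelihood, not identifiable\n")
  invisible(x)
}

#' Heritability with standard error
#'
#' h2 = sigma_a2 / (sigma_a2 + sigma_e2); SE by the delta method from the
#' sampling covariance of the variance components.
#'
#' @param est a [fit_animal_model()] result.
#' @return list `h2`, `se`.
#' @export
heritability <- function(est) {
  stopifnot(inherits(est, "varcomp_fit"))
  if (est$sigma_a2 + est$sigma_e2 <= 0)
    stop("total variance is zero", call. = FALSE)
  list(h2 = est$h2, se = est$se_h2)
}

#' Likelihood-ratio test for additive genetic variance
#'
#' Tests sigma_a2 = 0 by Lambda = 2 (logL_full - logL_reduced), clipped
#' at zero.  Because the null value lies on the boundary of the parameter
#' space, the default reference distribution is the equal mixture
#' 0.5 chi2_0 + 0.5 chi2_1, i.e. p = 0.5 P(chi2_1 >= Lambda); the plain
#' chi2_1 p-value is available with `mixture = FALSE`.
#'
#' @param full a [fit_animal_model()] result.
#' @param reduced_logL REML log-likelihood of the model without the
#'   animal effect (same fixed effects); defaults to the one stored in
#'   `full`.
#' @param mixture use the boundary mixture reference (default TRUE).
#' @return list `statistic`, `p_value`.
#' @export
lrt_additive_variance <- function(full, reduced_logL = NULL,
                                  mixture = TRUE) {
  stopifnot(inherits(full, "varcomp_fit"))
  if (is.null(reduced_logL)) reduced_logL <- full$logL_reduced
  stat <- 2 * (full$logL - reduced_logL)
  if (stat < -1e-6)
    warning("reduced logL exceeds full logL; statistic set to 0",
            call. = FALSE)
  stat <- max(0, stat)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (mixture) p <- 0.5 * p
  list(statistic = stat, p_value = p)
}
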