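make_vc_data <- function(seed, n_hens = 40, h2 = 0.5, mu = 2) {
  cfg <- sim_config(n_hens = n_hens, n_sires = 4, family_size = 4)
  ped <- simulate_pedigree(cfg, seed = seed)
  hens <- ped$animal[!is.na(ped$hatch_week)]
  bv <- simulate_breeding_values(ped, h2, seed = seed + 1)
  set.seed(seed + 2)
  y <- mu + bv[hens] + rnorm(length(hens), 0, sqrt(1 - h2))
  list(ped = ped, hens = hens,
       data = data.frame(animal = hens, y = y,
                         hw = factor(ped$hatch_week[match(hens,
                                                          ped$animal)])))
}

test_that("REML matches the brute-force profiled grid optimizer", {
  spec <- model_spec("y", fixed = "hw")
  for (seed in c(4, 14, 24)) {
    d <- make_vc_data(seed)
    A <- additive_relationship_matrix(d$ped)
    fit <- fit_animal_model(d$data, spec, K = A)
    X <- stats::model.matrix(~ d$data$hw)
    o <- reml_oracle(d$data$y, X, A[d$hens, d$hens])
    expect_equal(fit$logL, o$logL, tolerance = 1e-4)
    expect_equal(fit$sigma_a2, o$sigma_a2, tolerance = 1e-4)
    expect_equal(fit$sigma_e2, o$sigma_e2, tolerance = 1e-4)
  }
})

test_that("estimates are invariant to record order and response shifts", {
  d <- make_vc_data(5, n_hens = 60)
  A <- additive_relationship_matrix(d$ped)
  spec <- model_spec("y", fixed = "hw")
  f1 <- fit_animal_model(d$data, spec, K = A)
  perm <- sample(nrow(d$data))
  f2 <- fit_animal_model(d$data[perm, ], spec, K = A)
  d3 <- d$data
  d3$y <- d3$y + 100
  f3 <- fit_animal_model(d3, spec, K = A)
  expect_equal(f2$sigma_a2, f1$sigma_a2, tolerance = 1e-6)
  expect_equal(f2$logL, f1$logL, tolerance = 1e-6)
  expect_equal(f3$sigma_a2, f1$sigma_a2, tolerance = 1e-6)
  expect_equal(f3$h2, f1$h2, tolerance = 1e-6)
})

test_that("a trait without genetic variance is pushed to the boundary", {
  cfg <- sim_config(n_hens = 800, n_sires = 40)
  ped <- simulate_pedigree(cfg, seed = 6)
  hens <- ped$animal[!is.na(ped$hatch_week)]
  set.seed(7)
  dat <- data.frame(animal = hens, y = rnorm(length(hens)),
                    hw = factor(ped$hatch_week[match(hens, ped$animal)]))
  A <- additive_relationship_matrix(ped)
  fit <- fit_animal_model(dat, model_spec("y", fixed = "hw"), K = A)
  expect_lt(fit$h2, 0.1)
  lrt <- lrt_additive_variance(fit)
  expect_gt(lrt$p_value, 0.01)
})

test_that("an identity kinship with one record per animal is flagged flat", {
  set.seed(8)
  n <- 50
  ids <- sprintf("a%02d", 1:n)
  I <- diag(n)
  dimnames(I) <- list(ids, ids)
  dat <- data.frame(animal = ids, y = rnorm(n))
  fit <- fit_animal_model(dat, model_spec("y"), K = I)
  expect_false(fit$converged)
  expect_true(fit$flat_likelihood)
})

test_that("aliased fixed-effect columns are dropped deterministically", {
  d <- make_vc_data(9, n_hens = 60)
  d$data$hw2 <- d$data$hw                 # perfectly confounded copy
  A <- additive_relationship_matrix(d$ped)
  expect_warning(
    fit <- fit_animal_model(d$data, model_spec("y", fixed = c("hw", "hw2")),
                            K = A),
    "aliased")
  ref <- suppressWarnings(
    fit_animal_model(d$data, model_spec("y", fixed = "hw"), K = A))
  expect_equal(fit$logL, ref$logL, tolerance = 1e-8)
})

test_that("heritability and its delta-method SE follow the closed forms", {
  sehalf <- layres:::h2_delta_se(1, 1, diag(c(0.01, 0.01)))
  expect_equal(sehalf, sqrt(2 * 0.01) / 4, tolerance = 1e-12)  # 0.03536
  d <- make_vc_data(10)
  A <- additive_relationship_matrix(d$ped)
  fit <- fit_animal_model(d$data, model_spec("y", fixed = "hw"), K = A)
  h <- heritability(fit)
  expect_equal(h$h2, fit$sigma_a2 / (fit$sigma_a2 + fit$sigma_e2))
  expect_gte(h$se, 0)
})

test_that("the boundary-mixture LRT reproduces reference quantiles", {
  f0 <- structure(list(logL = -10, logL_reduced = -10),
                  class = "varcomp_fit")
  expect_equal(lrt_additive_variance(f0)$p_value, 0.5)
  f1 <- structure(list(logL = 0, logL_reduced = -2.706 / 2),
                  class = "varcomp_fit")
  expect_equal(lrt_additive_variance(f1)$p_value, 0.05, tolerance = 1e-3)
  expect_equal(lrt_additive_variance(f1, mixture = FALSE)$p_value, 0.0999,
               tolerance = 1e-3)
  f2 <- structure(list(logL = -10, logL_reduced = -9.99),
                  class = "varcomp_fit")
  expect_warning(out <- lrt_additive_variance(f2), "exceeds")
  expect_equal(out$statistic, 0)
})

test_that("the null LRT rejects at roughly the nominal rate", {
  cfg <- sim_config(n_hens = 150, n_sires = 10)
  ped <- simulate_pedigree(cfg, seed = 11)
  hens <- ped$animal[!is.na(ped$hatch_week)]
  A <- additive_relationship_matrix(ped)
  eig <- kinship_eigen(A, hens)
  spec <- model_spec("y")
  set.seed(12)
  rej <- vapply(1:60, function(r) {
    dat <- data.frame(animal = hens, y = rnorm(length(hens)))
    fit <- fit_animal_model(dat, spec, eig = eig)
    lrt_additive_variance(fit)$p_value < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.15)        # nominal 5%, boundary test is conservative
})
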