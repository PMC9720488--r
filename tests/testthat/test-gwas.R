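test_that("genomic inflation factor matches its defining quantiles", {
  expect_equal(genomic_inflation(rep(0.5, 11)), 1)
  grid <- seq(1e-4, 1, length.out = 2001)
  expect_equal(genomic_inflation(grid), 1, tolerance = 0.01)
  expect_gt(genomic_inflation(grid / 2), 1)
  expect_error(genomic_inflation(c(0.5, 0)), "0, 1")
  expect_error(genomic_inflation(c(0.5, 1.2)), "0, 1")
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 is 1", {
  set.seed(20)
  p <- runif(500)^1.3
  expect_equal(qvalues(p, pi0 = 1), p.adjust(p, "BH"), tolerance = 1e-12)
  # few p-values: smoother falls back to pi0 = 1
  expect_equal(qvalues(0.04), 0.04)
  q <- qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in p
  expect_true(all(q >= p * min(1, max(q) / max(p)) - 1e-12))
  expect_error(qvalues(c(0.1, NA)), "NA")
  expect_error(qvalues(c(0.1, 0)), "0, 1")
})

test_that("uniform null p-values yield essentially no discoveries", {
  set.seed(21)
  p <- runif(800)
  q <- qvalues(p)
  expect_equal(sum(q < 0.05), 0)
})

test_that("the fixed-ratio mixed test collapses to ANOVA without relatedness", {
  spec <- model_spec("y", fixed = "f")
  set.seed(22)
  for (r in 1:5) {
    n <- 50 + 10 * r
    g <- sample(0:2, n, replace = TRUE, prob = c(0.3, 0.5, 0.2))
    f <- factor(sample(1:3, n, replace = TRUE))
    y <- rnorm(n) + 0.4 * (g == 2)
    ids <- paste0("a", seq_len(n))
    dat <- data.frame(animal = ids, y = y, f = f)
    I <- diag(n)
    dimnames(I) <- list(ids, ids)
    for (ratio in c(0, 2.5)) {      # V proportional to I either way
      res <- snp_association(dat, spec, setNames(g, ids), I, ratio)
      a <- anova(lm(y ~ f + factor(g)))
      expect_equal(res$F, a["factor(g)", "F value"], tolerance = 1e-8)
      expect_equal(res$p, a["factor(g)", "Pr(>F)"], tolerance = 1e-8)
      expect_equal(res$df_num, a["factor(g)", "Df"])
      expect_equal(res$df_den, a["Residuals", "Df"])
    }
  }
})

test_that("a two-class SNP is tested on one degree of freedom", {
  set.seed(23)
  n <- 60
  ids <- paste0("a", seq_len(n))
  g <- sample(c(0L, 2L), n, replace = TRUE)     # hemizygous-coded Z SNP
  dat <- data.frame(animal = ids, y = rnorm(n))
  I <- diag(n)
  dimnames(I) <- list(ids, ids)
  res <- snp_association(dat, model_spec("y"), setNames(g, ids), I, 0.5)
  expect_equal(res$df_num, 1L)
  # single class: untestable
  res1 <- snp_association(dat, model_spec("y"),
                          setNames(rep(1L, n), ids), I, 0.5)
  expect_true(res1$untestable)
})

test_that("significance calls count strict FDR thresholds", {
  out <- significance_calls(c(0.04, 0.07, 0.2))
  expect_equal(out$n_suggestive, 2L)
  expect_equal(out$n_significant, 1L)
  all1 <- significance_calls(rep(1, 5))
  expect_equal(all1$n_suggestive, 0L)
  expect_equal(all1$n_significant, 0L)
})

test_that("genome scan finds an injected large-effect SNP and handles missing calls", {
  cfg <- sim_config(n_hens = 300, n_snps = 150, n_genotyped = 300,
                    n_sires = 20)
  ped <- simulate_pedigree(cfg, seed = 24)
  map <- simulate_snp_map(cfg, seed = 24)
  panel <- simulate_genotypes(ped, map, cfg, seed = 24)
  hens <- ped$animal[!is.na(ped$hatch_week)]
  panel <- subset_panel(panel, hens)
  qc <- qc_pipeline(panel)
  G <- stabilize_grm(vanraden_grm(qc$panel))
  target <- colnames(qc$panel$calls)[10]
  set.seed(25)
  y <- rnorm(length(hens)) + 1.5 * qc$panel$calls[, target]
  dat <- data.frame(animal = hens, y = y,
                    hw = factor(ped$hatch_week[match(hens, ped$animal)]))
  spec <- model_spec("y", fixed = "hw")
  gw <- run_gwas(dat, spec, qc$panel, G, ratio = 0.3)
  res <- gw$results
  expect_equal(res$snp[which.min(res$p)], target)
  expect_true(gw$summary$n_significant >= 1)
  expect_true(all(res$df_num[!res$untestable] >= 1))
  ok <- !is.na(res$q)
  qs <- res$q[ok][order(res$p[ok])]
  expect_true(all(diff(qs) >= -1e-12))
  # per-SNP missing-call exclusion agrees with the direct single-SNP fit
  calls <- qc$panel$calls
  j <- which(colSums(is.na(calls)) > 0)[1]
  if (!is.na(j)) {
    direct <- snp_association(dat, spec,
                              setNames(calls[, j], rownames(calls)),
                              G, 0.3)
    expect_equal(res$p[j], direct$p, tolerance = 1e-10)
    expect_equal(res$n_used[j], direct$n_used)
  }
  empty <- geno_panel(matrix(integer(0), length(hens), 0,
                             dimnames = list(hens, NULL)),
                      data.frame(snp = character(0),
                                 chr = character(0),
                                 pos = integer(0)))
  expect_error(run_gwas(dat, spec, empty, G, 0.3), "empty")
})

test_that("GRM correction controls inflation that plain ANOVA shows", {
  cfg <- sim_config(n_hens = 500, n_snps = 400, n_genotyped = 500,
                    n_sires = 12, family_size = 8)
  ped <- simulate_pedigree(cfg, seed = 26)
  map <- simulate_snp_map(cfg, seed = 26)
  panel <- subset_panel(simulate_genotypes(ped, map, cfg, seed = 26),
                        ped$animal[!is.na(ped$hatch_week)])
  hens <- rownames(panel$calls)
  bv <- simulate_breeding_values(ped, 0.3, seed = 27)
  set.seed(28)
  y <- bv[hens] + rnorm(length(hens), 0, sqrt(0.7))
  dat <- data.frame(animal = hens, y = y)
  spec <- model_spec("y")
  qc <- qc_pipeline(panel)
  G <- stabilize_grm(vanraden_grm(qc$panel))
  A <- additive_relationship_matrix(ped)
  fit <- fit_animal_model(dat, spec, K = A)
  corrected <- run_gwas(dat, spec, qc$panel, G, ratio = fit$ratio)
  I <- diag(length(hens))
  dimnames(I) <- list(hens, hens)
  plain <- run_gwas(dat, spec, qc$panel, I, ratio = 0)
  expect_lte(corrected$summary$lambda_gc, 1.05)
  expect_gt(plain$summary$lambda_gc, corrected$summary$lambda_gc)
})
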