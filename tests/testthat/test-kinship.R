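test_that("tabular A-matrix reproduces classic identities", {
  ped <- data.frame(animal = c("A", "B", "C", "D", "E"),
                    sire = c(NA, NA, "A", "A", "C"),
                    dam = c(NA, NA, "B", "B", "D"))
  A <- additive_relationship_matrix(ped)
  expect_equal(A["A", "A"], 1)                  # founder
  expect_equal(A["A", "C"], 0.5)                # parent-offspring
  expect_equal(A["C", "D"], 0.5)                # full sibs
  expect_equal(A["E", "E"], 1.25)               # offspring of full sibs
  expect_equal(A, t(A))
  expect_true(all(diag(A) >= 1))
})

test_that("A-matrix agrees with gene-dropping Monte Carlo on a small pedigree", {
  ped <- data.frame(
    animal = c("S1", "S2", "D1", "H1", "H2", "H3", "H4", "X1"),
    sire = c(NA, NA, NA, "S1", "S1", "S2", "S2", "H1"),
    dam = c(NA, NA, NA, "D1", "D1", "D1", "D1", "H3"))
  A <- additive_relationship_matrix(ped)
  Amc <- amatrix_gene_drop(ped, reps = 4000)
  expect_lt(max(abs(A - Amc[rownames(A), colnames(A)])), 0.05)
})

test_that("VanRaden G matches the hand-computed 2x2 example", {
  calls <- matrix(c(0L, 2L, 2L, 0L), 2, 2,
                  dimnames = list(c("i1", "i2"), c("s1", "s2")))
  map <- data.frame(snp = c("s1", "s2"), chr = "1", pos = 1:2)
  G <- vanraden_grm(geno_panel(calls, map))
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("identical individuals share a G row and monomorphic SNPs drop out", {
  calls <- rbind(i1 = c(0L, 1L, 2L, 2L), i2 = c(0L, 1L, 2L, 2L),
                 i3 = c(2L, 1L, 0L, 2L))
  colnames(calls) <- paste0("s", 1:4)
  map <- data.frame(snp = colnames(calls), chr = "1", pos = 1:4)
  G <- vanraden_grm(geno_panel(calls, map))   # s4 monomorphic: ignored
  expect_equal(G["i1", "i2"], G["i1", "i1"])
  mono <- matrix(2L, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(vanraden_grm(geno_panel(mono,
                                       data.frame(snp = c("s1", "s2"),
                                                  chr = "1", pos = 1:2))),
               "monomorphic")
})

test_that("G has mean diagonal near 1 under HWE and is order-invariant", {
  cfg <- sim_config(n_hens = 2, n_snps = 400)
  ped <- data.frame(animal = sprintf("F%03d", 1:300),
                    sire = NA_character_, dam = NA_character_,
                    sex = "M", hatch_week = NA_integer_)
  map <- simulate_snp_map(cfg, seed = 8)
  map <- map[!map$is_z, ]
  panel <- simulate_genotypes(ped, map, cfg, seed = 8)
  G <- vanraden_grm(panel)
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)
  # permuting individuals permutes G; SNP order is irrelevant
  perm <- sample(nrow(panel$calls))
  Gp <- vanraden_grm(geno_panel(panel$calls[perm, ], panel$map))
  expect_equal(Gp, G[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
  sperm <- sample(ncol(panel$calls))
  Gs <- vanraden_grm(geno_panel(panel$calls[, sperm],
                                panel$map[sperm, ]))
  expect_equal(Gs, G, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identity blending restores invertibility without distorting I", {
  v <- c(1, 1, -2) / sqrt(6)
  G1 <- 3 * tcrossprod(v)                       # rank 1, singular
  dimnames(G1) <- list(letters[1:3], letters[1:3])
  expect_equal(stabilize_grm(G1, 0), G1, ignore_attr = TRUE)
  Gs <- stabilize_grm(G1, 0.01)
  expect_gte(min(eigen(Gs, symmetric = TRUE)$values), 0.01 - 1e-12)
  expect_equal(stabilize_grm(diag(3), 0.01), diag(3), ignore_attr = TRUE)
  expect_error(stabilize_grm(G1, 1), "blend_weight")
})

test_that("kinship_eigen validates ids and clips tiny negatives", {
  G <- diag(3)
  dimnames(G) <- list(c("a", "b", "c"), c("a", "b", "c"))
  e <- kinship_eigen(G, c("b", "a"))
  expect_equal(e$values, c(1, 1))
  expect_error(kinship_eigen(G, c("a", "zz")), "absent")
})
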