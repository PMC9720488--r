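# Independent oracles, deliberately sharing no code with the package.

# dense-matrix REML by grid search + refinement on the variance ratio
reml_oracle <- function(y, X, K, grid = exp(seq(log(1e-6), log(1e6),
                                                length.out = 200))) {
  n <- length(y)
  p <- ncol(X)
  ll <- function(lam) {
    H <- lam * K + diag(n)
    Hi <- solve(H)
    XtHiX <- t(X) %*% Hi %*% X
    b <- solve(XtHiX, t(X) %*% Hi %*% y)
    r <- y - X %*% b
    s2 <- drop(t(r) %*% Hi %*% r) / (n - p)
    -0.5 * ((n - p) * (log(2 * pi) + log(s2) + 1) +
              as.numeric(determinant(H)$modulus) +
              as.numeric(determinant(XtHiX)$modulus))
  }
  lv <- vapply(grid, ll, numeric(1))
  i <- which.max(lv)
  o <- stats::optimize(ll, c(grid[max(1, i - 1)], grid[min(length(grid),
                                                           i + 1)]),
                       maximum = TRUE, tol = 1e-12)
  lam <- o$maximum
  H <- lam * K + diag(n)
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  b <- solve(XtHiX, t(X) %*% Hi %*% y)
  r <- y - X %*% b
  s2 <- drop(t(r) %*% Hi %*% r) / (n - p)
  list(lambda = lam, logL = o$objective, sigma_e2 = s2,
       sigma_a2 = lam * s2)
}

# expected genome sharing by gene-dropping Monte Carlo: drops a single
# unlinked locus with unique founder alleles and averages allele-pair
# identity; a_ij = 2 * kinship_ij
amatrix_gene_drop <- function(ped, reps = 5000, seed = 99) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  acc <- matrix(0, n, n)
  for (r in seq_len(reps)) {
    al <- matrix(0L, n, 2)
    next_allele <- 1L
    for (i in idx) {
      if (is.na(si[i])) {
        al[i, 1] <- next_allele
        next_allele <- next_allele + 1L
      } else al[i, 1] <- al[si[i], sample(2L, 1L)]
      if (is.na(di[i])) {
        al[i, 2] <- next_allele
        next_allele <- next_allele + 1L
      } else al[i, 2] <- al[di[i], sample(2L, 1L)]
    }
    # kinship: average identity over the 4 allele pairings
    for (i in idx) for (j in idx[idx >= i]) {
      k <- (sum(al[i, 1] == al[j, ]) + sum(al[i, 2] == al[j, ])) / 4
      if (i == j) k <- (1 + (al[i, 1] == al[i, 2])) / 2
      acc[i, j] <- acc[i, j] + 2 * k
      if (i != j) acc[j, i] <- acc[j, i] + 2 * k
    }
  }
  dimnames(acc) <- list(ped$animal, ped$animal)
  acc / reps
}

# fixture: a 1221-hen panel with SNPs of known genotype-class counts
qc_fixture <- function() {
  n <- 1221
  mkcol <- function(counts) {
    stopifnot(sum(counts) == n)
    rep(0:2, counts)
  }
  calls <- cbind(
    drop_me = mkcol(c(9, 9, 1203)),        # two classes < 10 -> discard
    keep2lv = mkcol(c(9, 600, 612)),       # one rare class -> keep 2 levels
    clean = mkcol(c(300, 600, 321)),       # untouched
    mono = mkcol(c(0, 0, 1221)),           # monomorphic -> discard
    zhet = c(rep(0L, 600), rep(1L, 30), rep(2L, 591))  # Z with 30 hets
  )
  rownames(calls) <- sprintf("H%04d", 1:n)
  storage.mode(calls) <- "integer"
  map <- data.frame(snp = colnames(calls),
                    chr = c("1", "1", "2", "2", "Z"),
                    pos = c(10L, 20L, 10L, 20L, 10L))
  geno_panel(calls, map)
}

# small deterministic test pedigree: 2 sires, 2 dams, hens in 2 families
tiny_pedigree <- function(n_per_family = 3) {
  hens <- sprintf("H%02d", seq_len(2 * n_per_family))
  data.frame(
    animal = c("S1", "S2", "D1", "D2", hens),
    sire = c(NA, NA, NA, NA, rep(c("S1", "S2"), each = n_per_family)),
    dam = c(NA, NA, NA, NA, rep(c("D1", "D2"), each = n_per_family)),
    sex = c("M", "M", "F", "F", rep("F", length(hens))),
    hatch_week = c(NA, NA, NA, NA,
                   rep_len(1:3, length(hens))),
    stringsAsFactors = FALSE
  )
}
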