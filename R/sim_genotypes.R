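#' Simulate a SNP map
#'
#' Allocates SNPs to chromosomes proportionally to `chrom_weights`, draws
#' strictly increasing base-pair positions within each chromosome and a
#' founder allele frequency per SNP (uniform on `maf_range`).  Chromosome
#' `"Z"` is flagged as the sex chromosome.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return data.frame `snp`, `chr`, `pos`, `freq`, `is_z`.
#' @export
simulate_snp_map <- function(config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  w <- config$chrom_weights / sum(config$chrom_weights)
  n_per <- floor(config$n_snps * w)
  rem <- config$n_snps - sum(n_per)
  if (rem > 0) {
    top <- order(config$n_snps * w - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[top] <- n_per[top] + 1L
  }
  chr <- rep(config$chromosomes, n_per)
  pos <- unlist(lapply(seq_along(n_per), function(i) {
    k <- n_per[i]
    if (k == 0L) return(integer(0))
    # ~3 Mb per weight unit keeps positions distinct and ordered
    sort(sample.int(max(k * 10L, config$chrom_weights[i] * 3e6L), k))
  }), use.names = FALSE)
  data.frame(
    snp = sprintf("SNP%05d", seq_along(chr)),
    chr = chr,
    pos = as.integer(pos),
    freq = stats::runif(length(chr), config$maf_range[1], config$maf_range[2]),
    is_z = chr == "Z",
    stringsAsFactors = FALSE
  )
}

#' Construct a genotype panel
#'
#' Couples a calls matrix (individuals x SNPs, entries 0/1/2/NA counting
#' copies of the alternative allele) with its SNP map.  On the Z
#' chromosome, female carriers are hemizygous: their single allele is coded
#' homozygous-like (0 or 2), never 1.
#'
#' @param calls integer matrix, rownames = animal ids, colnames = SNP ids.
#' @param map SNP map data.frame (`snp`, `chr`, `pos`, optional `is_z`).
#' @return object of class `geno_panel` with elements `calls` and `map`.
#' @export
geno_panel <- function(calls, map) {
  if (!is.matrix(calls)) stop("calls must be a matrix", call. = FALSE)
  if (ncol(calls) > 0L && (is.null(rownames(calls)) ||
                           is.null(colnames(calls))))
    stop("calls must have individual rownames and SNP colnames",
         call. = FALSE)
  if (!all(c("snp", "chr", "pos") %in% names(map)))
    stop("map needs columns snp, chr, pos", call. = FALSE)
  if (ncol(calls) != nrow(map) ||
      (ncol(calls) > 0L &&
       !identical(colnames(calls), as.character(map$snp))))
    stop("calls columns and map rows must match (same SNPs, same order)",
         call. = FALSE)
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  dim(bad) <- dim(calls)
  if (any(bad, na.rm = TRUE)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype code at individual '%s', SNP '%s'",
                 rownames(calls)[w[1]], colnames(calls)[w[2]]),
         call. = FALSE)
  }
  if (is.null(map$is_z)) map$is_z <- map$chr %in% c("Z", "z")
  structure(list(calls = calls, map = map), class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("geno_panel: %d individuals x %d SNPs (%d chromosome(s)%s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chr)),
              if (any(x$map$is_z)) ", incl. Z" else ""))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Simulate genotypes by Mendelian gene dropping
#'
#' Founders draw genotypes from Hardy--Weinberg proportions at each SNP's
#' founder allele frequency; offspring receive one gamete per parent, each
#' allele sampled from the parent's genotype.  Z-linked SNPs: males carry
#' two Z alleles; females carry a single, paternally inherited Z allele
#' coded 0/2 (so female Z calls are never 1).  Missing calls are injected
#' completely at random at `config$geno_missing_rate`.
#'
#' @param ped pedigree (parents before offspring; see [simulate_pedigree()]).
#' @param snp_map SNP map from [simulate_snp_map()].
#' @param config a [sim_config()] (supplies the missingness rate).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a [geno_panel()] covering every animal in the pedigree.
#' @export
simulate_genotypes <- function(ped, snp_map, config = sim_config(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- validate_pedigree(ped)
  if (is.null(snp_map$freq))
    stop("snp_map must carry founder allele frequencies (column 'freq')",
         call. = FALSE)
  if (is.null(snp_map$is_z)) snp_map$is_z <- snp_map$chr %in% c("Z", "z")
  n <- nrow(ped)
  m <- nrow(snp_map)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  female <- is.na(ped$sex) | ped$sex == "F"
  zc <- snp_map$is_z
  p <- snp_map$freq

  calls <- matrix(0L, n, m, dimnames = list(ped$animal, snp_map$snp))
  founder <- is.na(si) & is.na(di)

  nf <- sum(founder)
  if (nf) {
    pm <- matrix(p, nf, m, byrow = TRUE)
    g <- matrix(stats::rbinom(nf * m, 2L, pm), nf, m)
    if (any(zc)) {
      fz <- female[founder]
      if (any(fz)) {
        # hemizygous females: single allele, doubled code
        g[fz, zc] <- 2L * matrix(
          stats::rbinom(sum(fz) * sum(zc), 1L, pm[fz, zc, drop = FALSE]),
          sum(fz), sum(zc))
      }
    }
    calls[founder, ] <- g
  }

  off <- which(!founder)
  if (length(off)) {
    # depth-2 pedigree: all parents are founders, drop for all offspring at once
    if (any(is.na(si[off])) || any(is.na(di[off])))
      stop("non-founders must have both parents recorded", call. = FALSE)
    if (any(!founder[si[off]]) || any(!founder[di[off]])) {
      # deeper pedigrees: sequential per-animal drop
      for (i in off) {
        gs <- calls[si[i], ]
        gd <- calls[di[i], ]
        pat <- stats::rbinom(m, 1L, gs / 2)
        if (female[i]) {
          g <- pat + stats::rbinom(m, 1L, gd / 2)
          g[zc] <- 2L * pat[zc]
        } else {
          g <- pat + stats::rbinom(m, 1L, gd / 2)
        }
        calls[i, ] <- g
      }
    } else {
      no <- length(off)
      gs <- calls[si[off], , drop = FALSE]
      gd <- calls[di[off], , drop = FALSE]
      pat <- matrix(stats::rbinom(no * m, 1L, gs / 2), no, m)
      mat <- matrix(stats::rbinom(no * m, 1L, gd / 2), no, m)
      g <- pat + mat
      if (any(zc)) {
        fo <- female[off]
        if (any(fo))
          g[fo, zc] <- 2L * pat[fo, zc, drop = FALSE]
        if (any(!fo)) {
          # male offspring: maternal Z allele is the dam's single allele
          g[!fo, zc] <- pat[!fo, zc, drop = FALSE] +
            gd[!fo, zc, drop = FALSE] %/% 2L
        }
      }
      calls[off, ] <- g
    }
  }

  if (config$geno_missing_rate > 0) {
    drop <- stats::runif(n * m) < config$geno_missing_rate
    calls[drop] <- NA_integer_
  }
  geno_panel(calls, snp_map)
}
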