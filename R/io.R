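# Plain-text formats: pedigree CSV, genotype matrix + SNP map TSV (with a
# PLINK .ped/.map text dialect reader), egg-log CSV, NAb CSV, YAML config.
# Unknown parents are encoded "0" on disk and NA in memory.

#' Read a pedigree CSV
#'
#' Expects columns `animal,sire,dam` (optionally `sex,hatch_week`); `"0"`
#' or empty marks an unknown parent.  Records are validated and
#' reordered parents-first (see [validate_pedigree()]).
#'
#' @param path file path.
#' @return pedigree data.frame.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if ("hatch_week" %in% names(ped))
    ped$hatch_week <- as.integer(ped$hatch_week)
  validate_pedigree(ped)
}

#' Write a pedigree CSV
#'
#' @param ped pedigree data.frame.
#' @param path file path.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Read a genotype matrix and SNP map
#'
#' The matrix TSV has one row per individual (first column `id`) and one
#' column per SNP with entries 0/1/2 or NA; the map TSV has columns
#' `snp`, `chr`, `pos` (and optionally `freq`).  Dimensions and SNP ids
#' must agree.
#'
#' @param path_matrix genotype matrix TSV.
#' @param path_map SNP map TSV.
#' @return a [geno_panel()].
#' @export
read_genotypes <- function(path_matrix, path_map) {
  gm <- utils::read.delim(path_matrix, stringsAsFactors = FALSE,
                          check.names = FALSE)
  map <- utils::read.delim(path_map, stringsAsFactors = FALSE)
  ids <- as.character(gm[[1L]])
  calls <- as.matrix(gm[, -1L, drop = FALSE])
  storage.mode(calls) <- "integer"
  rownames(calls) <- ids
  if (ncol(calls) != nrow(map))
    stop(sprintf("genotype matrix has %d SNPs but map has %d",
                 ncol(calls), nrow(map)), call. = FALSE)
  colnames(calls) <- map$snp
  geno_panel(calls, map)
}

#' Write a genotype panel
#'
#' @param panel a [geno_panel()].
#' @param path_matrix,path_map output TSV paths.
#' @export
write_genotypes <- function(panel, path_matrix, path_map) {
  stopifnot(inherits(panel, "geno_panel"))
  df <- data.frame(id = rownames(panel$calls), panel$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path_matrix, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(panel$map, path_map, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' Read genotypes in the PLINK text dialect
#'
#' Reads `<prefix>.ped` / `<prefix>.map`.  Each SNP's two allele columns
#' are converted to a 0/1/2 count of the alternative allele, where the
#' reference allele is the first non-missing allele encountered in file
#' order ("0" = missing call).
#'
#' @param prefix path prefix (without extension).
#' @return a [geno_panel()].
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"),
                           stringsAsFactors = FALSE,
                           col.names = c("chr", "snp", "cm", "pos"))
  ped <- utils::read.table(paste0(prefix, ".ped"),
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m)
    stop(sprintf(".ped has %d genotype columns but .map lists %d SNPs",
                 ncol(ped) - 6L, m), call. = FALSE)
  ids <- ped[[2L]]
  calls <- matrix(NA_integer_, nrow(ped), m,
                  dimnames = list(ids, map$snp))
  for (j in seq_len(m)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    seen <- c(a1, a2)
    seen <- seen[seen != "0"]
    if (!length(seen)) next
    ref <- seen[1L]
    ok <- a1 != "0" & a2 != "0"
    calls[ok, j] <- (a1[ok] != ref) + (a2[ok] != ref)
  }
  geno_panel(calls, data.frame(snp = map$snp, chr = as.character(map$chr),
                               pos = map$pos, stringsAsFactors = FALSE))
}

#' Read/write egg-collection logs and NAb tables
#'
#' Egg logs are CSVs with columns `hen,day,eggs`; NAb tables carry
#' `hen,isotype,titer,plate,age_class,hatch_week`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_egg_log <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hen", "day", "eggs")
  if (!all(need %in% names(x)))
    stop("egg log needs columns hen, day, eggs", call. = FALSE)
  x$day <- as.integer(x$day)
  x$eggs <- as.integer(x$eggs)
  x
}

#' @rdname read_egg_log
#' @param x data.frame to write.
#' @export
write_egg_log <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}

#' Read a YAML pipeline/simulation configuration
#'
#' Top-level keys are passed to [sim_config()]; nested lists (`nab`,
#' `egg`) are merged over the defaults, so a file can override single
#' parameters.
#'
#' @param path YAML file.
#' @return a [sim_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- formals(sim_config)
  args <- list()
  for (nm in names(raw)) {
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", nm, call. = FALSE)
    if (nm %in% c("nab", "egg")) {
      base <- eval(defaults[[nm]])
      args[[nm]] <- utils::modifyList(base, raw[[nm]])
    } else {
      args[[nm]] <- raw[[nm]]
    }
  }
  do.call(sim_config, args)
}

#' Subset a genotype panel to chosen individuals
#'
#' @param panel a [geno_panel()].
#' @param ids individual ids to keep, in order.
#' @return a [geno_panel()].
#' @export
subset_panel <- function(panel, ids) {
  stopifnot(inherits(panel, "geno_panel"))
  j <- match(ids, rownames(panel$calls))
  if (anyNA(j))
    stop("individual(s) absent from panel: ",
         paste(utils::head(ids[is.na(j)], 5L), collapse = ", "),
         call. = FALSE)
  geno_panel(panel$calls[j, , drop = FALSE], panel$map)
}
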