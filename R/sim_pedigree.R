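#' Simulate a one-generation batch pedigree
#'
#' Creates founder sires and dams plus a single generation of female hens
#' partitioned into maternal (dam) families.  Dams are nested within sires
#' round-robin, so maternal families under the same sire are paternal
#' half-sib groups and hens within a family are full sibs.  Each hen is
#' assigned to one of three hatch weeks with the configured proportions.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return data.frame with columns `animal`, `sire`, `dam` (NA = unknown
#'   parent), `sex` (`"F"`/`"M"`), `hatch_week` (1--3, NA for founders),
#'   ordered parents-before-offspring.
#' @export
simulate_pedigree <- function(config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n_hens <- config$n_hens
  n_fam <- as.integer(ceiling(n_hens / config$family_size))
  n_sires <- min(config$n_sires, n_fam)

  sire_ids <- sprintf("S%04d", seq_len(n_sires))
  dam_ids <- sprintf("D%04d", seq_len(n_fam))
  hen_ids <- sprintf("H%05d", seq_len(n_hens))

  dam_of_hen <- rep(seq_len(n_fam), each = config$family_size)[seq_len(n_hens)]
  sire_of_dam <- rep_len(seq_len(n_sires), n_fam)
  hatch <- sample.int(3L, n_hens, replace = TRUE, prob = config$hatch_props)

  ped <- data.frame(
    animal = c(sire_ids, dam_ids, hen_ids),
    sire = c(rep(NA_character_, n_sires + n_fam),
             sire_ids[sire_of_dam[dam_of_hen]]),
    dam = c(rep(NA_character_, n_sires + n_fam), dam_ids[dam_of_hen]),
    sex = c(rep("M", n_sires), rep("F", n_fam), rep("F", n_hens)),
    hatch_week = c(rep(NA_integer_, n_sires + n_fam), hatch),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
}

#' Validate and topologically order a pedigree table
#'
#' Checks column presence, id uniqueness and acyclicity; reorders records
#' so every parent precedes its offspring (Kahn's algorithm).  Parents that
#' appear only as `sire`/`dam` entries are added as founder records.
#'
#' @param ped data.frame with columns `animal`, `sire`, `dam` and
#'   optionally `sex`, `hatch_week`.  `NA` or `"0"` marks unknown parents.
#' @return the validated pedigree, parents before offspring.
#' @export
validate_pedigree <- function(ped) {
  need <- c("animal", "sire", "dam")
  miss <- setdiff(need, names(ped))
  if (length(miss))
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ped$animal <- as.character(ped$animal)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  ped$sire[ped$sire %in% c("0", "")] <- NA_character_
  ped$dam[ped$dam %in% c("0", "")] <- NA_character_
  if (anyDuplicated(ped$animal))
    stop("duplicate animal id(s): ",
         paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "),
         call. = FALSE)
  self <- !is.na(ped$sire) & ped$sire == ped$animal |
    !is.na(ped$dam) & ped$dam == ped$animal
  if (any(self))
    stop("animal listed as its own parent: ",
         paste(ped$animal[self], collapse = ", "), call. = FALSE)

  # implicit founders: parents never listed as animals
  ghost <- setdiff(c(ped$sire, ped$dam), c(ped$animal, NA))
  if (length(ghost)) {
    add <- ped[rep(1L, length(ghost)), , drop = FALSE]
    add[] <- NA
    add$animal <- ghost
    add$sire <- NA_character_
    add$dam <- NA_character_
    ped <- rbind(add, ped)
    rownames(ped) <- NULL
  }

  idx <- seq_len(nrow(ped))
  names(idx) <- ped$animal
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  # Kahn topological sort
  n_par <- (!is.na(si)) + (!is.na(di))
  children <- split(rep(idx, 2L), c(si, di))
  order_out <- integer(0)
  ready <- which(n_par == 0L)
  while (length(ready)) {
    order_out <- c(order_out, ready)
    newly <- integer(0)
    for (a in ready) {
      kids <- children[[as.character(a)]]
      if (is.null(kids)) next
      for (k in kids) {
        n_par[k] <- n_par[k] - 1L
        if (n_par[k] == 0L) newly <- c(newly, k)
      }
    }
    ready <- newly
  }
  if (length(order_out) != nrow(ped))
    stop("pedigree contains a cycle (an animal is its own ancestor)",
         call. = FALSE)
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate additive breeding values on a pedigree
#'
#' Founders draw from Normal(0, `sigma_a2`); each non-founder receives the
#' mean of its parents' values plus a Mendelian-sampling deviate with
#' variance `sigma_a2`/2 (an unknown parent contributes value 0 and its
#' missing half of the sampling variance, i.e. `sigma_a2`/4 extra per
#' unknown parent).  Inbreeding of parents is ignored: in a two-generation
#' batch pedigree founder parents are unrelated, so the resulting
#' covariance of values equals A * `sigma_a2` in expectation.
#'
#' @param ped pedigree from [simulate_pedigree()] / [validate_pedigree()].
#' @param sigma_a2 additive genetic variance (>= 0).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return named numeric vector of breeding values, one per animal.
#' @export
simulate_breeding_values <- function(ped, sigma_a2, seed = NULL) {
  if (sigma_a2 < 0) stop("sigma_a2 must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ped <- validate_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  bv <- numeric(n)
  if (sigma_a2 > 0) {
    z <- stats::rnorm(n)
    founder <- is.na(si) & is.na(di)
    off <- which(!founder)
    bv[founder] <- z[founder] * sqrt(sigma_a2)
    if (length(off) && all(founder[si[off]] | is.na(si[off])) &&
        all(founder[di[off]] | is.na(di[off]))) {
      # depth-2 pedigree: all parents are founders, fill in one pass
      pa <- ifelse(is.na(si[off]), 0, bv[si[off]])
      ma <- ifelse(is.na(di[off]), 0, bv[di[off]])
      # Mendelian sampling variance: sigma_a2/4 per (known or unknown) parent
      ms_var <- sigma_a2 / 2 + (is.na(si[off]) + is.na(di[off])) *
        sigma_a2 / 4
      bv[off] <- (pa + ma) / 2 + z[off] * sqrt(ms_var)
    } else {
      for (i in off) {
        s <- si[i]
        d <- di[i]
        pa <- if (is.na(s)) 0 else bv[s]
        ma <- if (is.na(d)) 0 else bv[d]
        ms_var <- sigma_a2 / 2 + (is.na(s) + is.na(d)) * sigma_a2 / 4
        bv[i] <- (pa + ma) / 2 + z[i] * sqrt(ms_var)
      }
    }
  }
  names(bv) <- ped$animal
  bv
}
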