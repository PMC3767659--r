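#' Colony-structured genotype tables
#'
#' The central container of the package: one row per individual, with columns
#' `id`, `colony`, `caste`, `ploidy` followed by two integer columns per
#' microsatellite locus named `<locus>.1` and `<locus>.2`. Allele calls are
#' integer allele sizes in base pairs; `0` encodes a missing call. Diploid
#' rows carry both calls at a typed locus (or two zeros when the locus
#' failed); haploid males carry their single call in `<locus>.1` and `0` in
#' `<locus>.2`.
#'
#' @param df data.frame in the layout above.
#' @return A validated `genotype_table` (a data.frame subclass).
#' @export
genotype_table <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("id", "colony", "caste", "ploidy")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("genotype table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  castes <- c("queen", "worker", "male", "alate_female", "dealate_queen")
  bad <- setdiff(unique(as.character(df$caste)), castes)
  if (length(bad) > 0) {
    stop("unknown caste label(s): ", paste(bad, collapse = ", "))
  }
  if (!all(df$ploidy %in% c(1L, 2L))) stop("ploidy must be 1 or 2")
  if (any(is.na(df$colony)) || any(!nzchar(as.character(df$colony)))) {
    stop("colony ids must be non-empty")
  }
  loci <- locus_names(df)
  if (length(loci) == 0) stop("no locus columns found (expect <locus>.1/.2)")
  for (loc in loci) {
    a1 <- df[[paste0(loc, ".1")]]
    a2 <- df[[paste0(loc, ".2")]]
    if (any(is.na(a1)) || any(is.na(a2))) {
      stop("allele calls must be integers (0 for missing), locus ", loc)
    }
    dip <- df$ploidy == 2L
    half <- dip & xor(a1 == 0, a2 == 0)
    if (any(half)) {
      stop("diploid row ", df$id[which(half)[1]],
           " has a single allele call at locus ", loc)
    }
    if (any(df$ploidy == 1L & a2 != 0)) {
      stop("haploid row with two allele calls at locus ", loc)
    }
  }
  df$id <- as.character(df$id)
  df$colony <- as.character(df$colony)
  df$caste <- as.character(df$caste)
  df$ploidy <- as.integer(df$ploidy)
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' Locus names of a genotype table
#' @param df genotype table or compatible data.frame.
#' @return character vector of locus names.
#' @export
locus_names <- function(df) {
  cols <- grep("\\.1$", names(df), value = TRUE)
  loci <- sub("\\.1$", "", cols)
  loci[paste0(loci, ".2") %in% names(df)]
}

# n x 2 integer matrix of allele calls at one locus (0 = missing)
locus_calls <- function(df, locus) {
  cbind(df[[paste0(locus, ".1")]], df[[paste0(locus, ".2")]])
}

# alleles of one individual (row index) at one locus; NULL when untyped
indiv_alleles <- function(df, i, locus) {
  a <- c(df[[paste0(locus, ".1")]][i], df[[paste0(locus, ".2")]][i])
  if (df$ploidy[i] == 1L) a <- a[1]
  if (all(a == 0)) return(NULL)
  a
}

# diploid-only subset of given castes
diploid_subset <- function(df, castes = NULL) {
  keep <- df$ploidy == 2L
  if (!is.null(castes)) keep <- keep & df$caste %in% castes
  df[keep, , drop = FALSE]
}

#' Per-locus missing-data report
#' @param table genotype table.
#' @return data.frame with locus, n_missing, n_typed.
#' @export
missing_report <- function(table) {
  loci <- locus_names(table)
  out <- lapply(loci, function(loc) {
    calls <- locus_calls(table, loc)
    miss <- calls[, 1] == 0 & (table$ploidy == 1L | calls[, 2] == 0)
    data.frame(locus = loc, n_missing = sum(miss), n_typed = sum(!miss))
  })
  do.call(rbind, out)
}
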