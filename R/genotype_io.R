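#' File formats: genotype CSV, GENEPOP, FASTA alignments
#'
#' @name genotype_io
NULL

#' Read a colony genotype CSV
#'
#' The CSV dialect is UTF-8, comma-separated, header mandatory, with columns
#' `id,colony,caste,ploidy` followed by two integer columns per locus
#' (suffixes `.1`/`.2`); missing allele calls are written `0`.
#'
#' @param path file path.
#' @return a [genotype_table]; the per-locus missing-data report is attached
#'   as attribute `"missing_report"`.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  tab <- genotype_table(df)
  attr(tab, "missing_report") <- missing_report(tab)
  tab
}

#' Write a colony genotype CSV
#' @param table a [genotype_table].
#' @param path output path.
#' @export
write_genotypes <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a GENEPOP file
#'
#' Diploid individuals only (GENEPOP convention). Allele sizes are recoded by
#' rank, smallest size first, to codes 001, 002, ...; missing calls become
#' 000. One `Pop` block per level of `pop_by`.
#'
#' @param table a [genotype_table]; haploid rows are rejected.
#' @param path output path.
#' @param pop_by grouping column (default "colony").
#' @param title title line.
#' @return invisibly, the allele recoding map (list per locus: named vector
#'   code -> allele size).
#' @export
write_genepop <- function(table, path, pop_by = "colony",
                          title = "sociogen export") {
  if (any(table$ploidy != 2L)) {
    stop("GENEPOP output is defined for diploid individuals only; ",
         "drop haploid males first")
  }
  loci <- locus_names(table)
  recode <- lapply(loci, function(loc) {
    sizes <- sort(unique(c(locus_calls(table, loc))))
    sizes <- sizes[sizes != 0]
    if (length(sizes) > 999) stop("more than 999 alleles at locus ", loc)
    stats::setNames(sizes, sprintf("%03d", seq_along(sizes)))
  })
  names(recode) <- loci
  code_of <- function(loc, size) {
    if (size == 0) return("000")
    names(recode[[loc]])[match(size, recode[[loc]])]
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci, con)
  for (pop in unique(table[[pop_by]])) {
    writeLines("Pop", con)
    sub <- table[table[[pop_by]] == pop, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      codes <- vapply(loci, function(loc) {
        a <- locus_calls(sub, loc)[i, ]
        paste0(code_of(loc, a[1]), code_of(loc, a[2]))
      }, "")
      writeLines(paste0(sub$id[i], " , ", paste(codes, collapse = " ")), con)
    }
  }
  invisible(recode)
}

#' Read a GENEPOP file written by [write_genepop]
#'
#' @param path file path.
#' @param recode optional recoding map returned by [write_genepop]; when
#'   given, codes are mapped back to allele sizes.
#' @return a [genotype_table] (caste "worker", population stored as colony).
#' @export
read_genepop <- function(path, recode = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3) stop("not a GENEPOP file: ", path)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no Pop separator found")
  loci <- trimws(lines[2:(first_pop - 1)])
  # locus names may also be comma-separated on one line
  if (length(loci) == 1 && grepl(",", loci)) {
    loci <- trimws(strsplit(loci, ",")[[1]])
  }
  rows <- list(); pop_idx <- 0L
  for (ln in lines[first_pop:length(lines)]) {
    if (toupper(trimws(ln)) == "POP") { pop_idx <- pop_idx + 1L; next }
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, ",")[[1]]
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
    if (length(codes) != length(loci)) {
      stop("row ", id, ": expected ", length(loci), " genotypes")
    }
    al <- lapply(seq_along(loci), function(j) {
      cc <- codes[j]
      w <- nchar(cc) / 2
      a <- c(substr(cc, 1, w), substr(cc, w + 1, 2 * w))
      a <- as.integer(a)
      if (!is.null(recode)) {
        a <- vapply(a, function(x) {
          if (x == 0) 0L else unname(recode[[loci[j]]][sprintf("%03d", x)])
        }, integer(1))
      }
      sort2(a)
    })
    r <- as.list(unlist(al))
    names(r) <- paste0(rep(loci, each = 2), c(".1", ".2"))
    rows[[length(rows) + 1]] <- c(list(id = id,
                                       colony = sprintf("P%02d", pop_idx),
                                       caste = "worker", ploidy = 2L), r)
  }
  genotype_table(do.call(rbind, lapply(rows, as.data.frame)))
}

#' Gap-free haplotype alignment
#'
#' @param m character matrix (rows = sequences, columns = sites) over
#'   A, C, G, T, N; rownames are sequence ids.
#' @return object of class `hap_alignment`.
#' @export
hap_alignment <- function(m) {
  stopifnot(is.matrix(m), is.character(m))
  m[] <- toupper(m)
  if (any(m %in% c("-", "."))) stop("gap characters are not allowed")
  bad <- setdiff(unique(c(m)), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) stop("invalid characters: ", paste(bad, collapse = ","))
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  structure(list(ids = rownames(m), seq = m, length = ncol(m)),
            class = "hap_alignment")
}

#' Read an aligned gap-free FASTA file
#'
#' All sequences must have equal length and contain only A/C/G/T/N;
#' lowercase input is uppercased; gaps are rejected.
#'
#' @param path FASTA path.
#' @return a [hap_alignment].
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("empty FASTA file: ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1) {
    stop("sequences are not aligned (unequal lengths: ",
         paste(unique(lens), collapse = ","), ")")
  }
  chm <- toupper(as.character(as.matrix(dna)))
  if (any(chm %in% c("-", "."))) stop("gap characters are not allowed")
  hap_alignment(chm)
}

#' Write a haplotype alignment as FASTA
#' @param alignment a [hap_alignment].
#' @param path output path.
#' @export
write_fasta_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "hap_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alignment$ids)) {
    writeLines(paste0(">", alignment$ids[i]), con)
    writeLines(paste(alignment$seq[i, ], collapse = ""), con)
  }
  invisible(path)
}
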