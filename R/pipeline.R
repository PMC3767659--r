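#' Config-driven pipeline orchestration
#'
#' A single JSON configuration fully specifies a run: the synthetic scenario
#' (or input file paths), the stages to execute, and an explicit seed and
#' permutation count for every stochastic stage (no hidden defaults).
#' Stages run in dependency order io/simulate -> sociogenetics -> popgen ->
#' spatial -> mtdna -> demography and write both machine-readable JSON and
#' human-readable TSV reports.
#'
#' @name pipeline
NULL

STAGES <- c("simulate", "sociogen", "popgen", "spatial", "mtdna",
            "demography")

#' Validate a pipeline configuration
#'
#' @param config list (parsed JSON).
#' @return the validated config, invisibly; errors on a bad config.
#' @export
validate_config <- function(config) {
  stages <- config$stages %||% STAGES
  bad <- setdiff(stages, STAGES)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  needs_sim <- any(c("sociogen", "popgen", "spatial") %in% stages)
  if (needs_sim && !"simulate" %in% stages &&
      is.null(config$inputs$genotypes)) {
    stop("stages ", paste(intersect(stages, c("sociogen", "popgen", "spatial")),
                          collapse = ","),
         " need the simulate stage or inputs$genotypes")
  }
  if ("mtdna" %in% stages && !"simulate" %in% stages &&
      is.null(config$inputs$fasta)) {
    stop("mtdna stage needs the simulate stage or inputs$fasta")
  }
  seed_of <- function(stage) config[[stage]]$seed
  for (stage in intersect(stages, c("simulate", "popgen", "spatial",
                                    "mtdna"))) {
    if (is.null(seed_of(stage))) {
      stop("stochastic stage '", stage, "' requires an explicit seed")
    }
  }
  for (stage in intersect(stages, c("popgen", "spatial", "mtdna"))) {
    np <- config[[stage]]$n_perm %||% config[[stage]]$n_perms
    if (!is.null(np) && np < 999) {
      stop("permutation counts must be >= 999 (stage ", stage, ")")
    }
  }
  invisible(config)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the analysis pipeline
#'
#' @param config path to a JSON config file, or an equivalent list.
#' @param outdir output directory (overrides `config$outdir`).
#' @return invisibly, the summary list (also written to
#'   `<outdir>/summary.json`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  validate_config(config)
  stages <- config$stages %||% STAGES
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(package_version = as.character(utils::packageVersion("sociogen")),
                  stages = stages, config = config)

  geno <- NULL; coords <- NULL; transect <- NULL; panel <- NULL

  if ("simulate" %in% stages) {
    sc <- config$simulate
    panel <- make_locus_panel(sc$n_loci %||% 7L,
                              unlist(sc$allele_count_range %||% c(4, 13)),
                              seed = sc$seed)
    tmpl <- colony_spec(n_workers = sc$n_workers %||% 16L,
                        contributions = unlist(sc$contributions %||%
                                                 c(8L, 5L, 3L)))
    pl <- plot_spec(side_length = sc$side_length %||% 34,
                    n_nests = sc$n_nests %||% 20L,
                    placement = sc$placement %||% "random",
                    seed = sc$seed)
    sim <- simulate_plot(panel, pl, tmpl,
                         mask_rate = sc$mask_rate %||% 0)
    geno <- sim$genotypes; coords <- sim$coords
    write_genotypes(geno, file.path(outdir, "genotypes.csv"))
    write_tsv(coords, file.path(outdir, "coordinates.tsv"))
    # hidden truth goes to a sidecar, never into the analysis tables
    jsonlite::write_json(lapply(sim$truth, function(t) {
      list(queen = t$queen, fathers = t$fathers, father_of = t$father_of)
    }), file.path(outdir, "truth_sidecar.json"), auto_unbox = TRUE)
    ts <- sc$transect %||% list()
    tsp <- transect_spec(n_sites = ts$n_sites %||% 14L,
                         site_spacing = ts$site_spacing %||% 10,
                         samples_per_site = ts$samples_per_site %||% 2L,
                         mutation_steps_within = ts$steps_within %||% 1L,
                         mutation_steps_between = ts$steps_between %||% 14L)
    transect <- simulate_transect_mtdna(tsp, seed = sc$seed)
    write_fasta_alignment(transect$alignment,
                          file.path(outdir, "transect.fasta"))
    summary$simulate <- list(n_colonies = length(unique(geno$colony)),
                             n_individuals = nrow(geno))
  } else if (!is.null(config$inputs$genotypes)) {
    geno <- read_genotypes(config$inputs$genotypes)
    if (!is.null(config$inputs$coordinates)) {
      coords <- read.csv(config$inputs$coordinates)
    }
  }

  if ("sociogen" %in% stages) {
    mw <- config$sociogen$min_workers %||% 8L
    freqs <- if (!is.null(panel)) {
      lapply(panel, function(l) stats::setNames(l$frequencies, l$alleles))
    } else NULL
    rows <- list()
    for (cl in unique(geno$colony)) {
      nw <- sum(geno$colony == cl & geno$caste == "worker" &
                  geno$ploidy == 2L)
      if (nw < mw) next
      ped <- colony_pedigree(geno, cl, panel_freqs = freqs,
                             min_workers = mw)
      rows[[cl]] <- data.frame(colony = cl, n_workers = nw, m_p = ped$m_p,
                               m_e_p = ped$m_e_p,
                               p_nondetect_two_males =
                                 ped$p_nondetect_two_males,
                               p_nondetect_worker_son =
                                 ped$p_nondetect_worker_son,
                               queen_observed = ped$queen_observed)
    }
    ped_df <- do.call(rbind, rows)
    write_tsv(ped_df, file.path(outdir, "pedigree.tsv"))
    summary$sociogen <- list(n_colonies = nrow(ped_df),
                             mean_m_p = mean(ped_df$m_p),
                             mean_m_e_p = mean(ped_df$m_e_p, na.rm = TRUE))
  }

  if ("popgen" %in% stages) {
    pg <- config$popgen
    ls <- locus_summaries(geno)
    write_tsv(ls$per_locus, file.path(outdir, "locus_summaries.tsv"))
    hwe <- hwe_exact_resampled(geno, n_replicates = pg$n_replicates %||% 20L,
                               seed = pg$seed,
                               n_mc = pg$n_perm %||% 2000L,
                               alpha = pg$alpha %||% 0.05)
    fs <- weir_cockerham_fstats(geno, n_boot = pg$n_boot %||% 1000L,
                                seed = pg$seed)
    summary$popgen <- list(overall_h_e = ls$overall$h_e,
                           overall_h_o = ls$overall$h_o,
                           hwe_significant = hwe$n_significant,
                           hwe_tests = hwe$n_tests,
                           fis = fs$fis, fst = fs$fst,
                           se_fis = fs$se_fis, se_fst = fs$se_fst)
  }

  if ("spatial" %in% stages) {
    sp <- config$spatial
    side <- config$simulate$side_length %||% 34
    ce <- clark_evans_R(coords[, c("x", "y")], area = side^2,
                        boundary = 4 * side)
    fst_m <- pairwise_fst(geno)
    ibd <- ibd_table(fst_m, coords)
    write_tsv(ibd, file.path(outdir, "ibd_pairs.tsv"))
    ids <- rownames(fst_m)
    xy <- as.matrix(coords[match(ids, coords$colony), c("x", "y")])
    geo <- as.matrix(stats::dist(xy))
    # rank-based Mantel statistic is invariant to the ln transform, so raw
    # distances are equivalent to ln(distance)
    mt <- mantel_test(fst_m / (1 - fst_m), geo,
                      n_perms = sp$n_perms %||% 10000L, seed = sp$seed)
    summary$spatial <- list(clark_evans_R = ce$R, clark_evans_p = ce$p,
                            mantel_r = mt$statistic, mantel_p = mt$p)
  }

  if ("mtdna" %in% stages) {
    mc <- config$mtdna
    aln <- if (!is.null(transect)) transect$alignment
           else read_fasta_alignment(config$inputs$fasta)
    site <- if (!is.null(transect)) transect$site else NULL
    col <- collapse_haplotypes(aln, site = site)
    write_tsv(data.frame(id = aln$ids, haplotype = col$assignment),
              file.path(outdir, "haplotypes.tsv"))
    pd <- pairwise_p_distance(col$haplotypes)
    net <- median_joining_network(col$haplotypes)
    write_tsv(net$edges, file.path(outdir, "mj_network_edges.tsv"))
    summary$mtdna <- list(n_haplotypes = nrow(col$haplotypes$seq),
                          max_p_percent = max(pd$p_percent, na.rm = TRUE))
    if (!is.null(transect) && length(unique(transect$group)) > 1) {
      subm <- pairwise_p_distance(aln)$substitutions
      am <- amova(subm, pop = as.character(transect$site),
                  group = as.character(transect$group),
                  n_perm = mc$n_perm %||% 1000L, seed = mc$seed,
                  squared = TRUE)
      summary$mtdna$amova_percent <- as.list(am$percent)
      summary$mtdna$amova_p <- as.list(am$p)
    }
  }

  if ("demography" %in% stages) {
    cen <- if (!is.null(config$inputs$census)) {
      read.csv(config$inputs$census)
    } else NULL
    if (!is.null(cen)) {
      nsr <- numerical_sex_ratio(cen)
      write_tsv(nsr$per_nest, file.path(outdir, "sex_ratio.tsv"))
      has_sex <- (cen$n_males + cen$n_alate_females) > 0
      tab <- base::table(factor(cen$queenright, levels = c(FALSE, TRUE)),
                         factor(has_sex, levels = c(TRUE, FALSE)))
      y <- yates_chi2(as.matrix(tab))
      summary$demography <- list(chi2 = y$statistic, p = y$p,
                                 nsr = nsr$by_status$mean)
    }
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}

#' Command-line entry point
#'
#' Subcommands mirror the pipeline stages: `simulate`, `sociogen`, `popgen`,
#' `spatial`, `mtdna`, `demography`, `run-all`. Each takes `--config` and
#' optionally `--outdir`.
#'
#' @param args character vector (defaults to the command line).
#' @return exit status, invisibly.
#' @export
sociogen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0("usage: sociogen <",
                  paste(c(STAGES, "run-all"), collapse = "|"),
                  "> --config FILE [--outdir DIR]")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  if (!cmd %in% c(STAGES, "run-all")) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(invisible(1L))
  }
  get_opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else NULL
  }
  cfg_path <- get_opt("--config")
  if (is.null(cfg_path)) { message(usage); return(invisible(1L)) }
  config <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  if (cmd != "run-all") {
    config$stages <- intersect(c("simulate", cmd), config$stages %||%
                                 c("simulate", cmd))
  }
  status <- tryCatch({
    run_pipeline(config, outdir = get_opt("--outdir"))
    0L
  }, error = function(e) {
    message("pipeline error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
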