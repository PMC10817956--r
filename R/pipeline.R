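# End-to-end orchestration: YAML run configuration, the three pipeline
# entry points (simulate, diversity, scan), and the reproducibility
# manifest. All tabular outputs are TSV; intervals are BED (0-based
# half-open). These functions are the package's subcommand surface; a thin
# command-line wrapper ships in inst/cli/sweepscan.R.

known_config_keys <- list(
  top = c("io", "filters", "scan", "populations", "simulate", "annotate"),
  io = c("vcf", "popmap", "out_dir"),
  filters = c("maf_min", "gq_min", "dp_min", "max_missing", "hwe_p_min",
              "biallelic_only", "relatedness_max", "contigs"),
  scan = c("window_size", "step", "min_snps", "zhp_max", "zfst_min",
           "abs_xpehh_min", "emp_p_max", "ehh_cutoff", "max_extend_bp"),
  populations = c("hp_pool", "group_a", "group_b"),
  simulate = c("seed", "n_pops", "Ne", "split_gen", "migration_rate", "L",
               "mu", "rec", "sweep", "sample_sizes", "depth_mean",
               "gq_const", "burn_in", "reinject_budget"),
  annotate = c("genes", "flank_bp"))

#' Read and validate a YAML run configuration
#'
#' Sections: `io` (paths), `filters` ([filter_config()] fields plus an
#' optional `contigs` allow-list), `scan` ([scan_config()] fields),
#' `populations` (`hp_pool`, `group_a`, `group_b` population lists),
#' `simulate` ([sim_config()] fields) and `annotate` (`genes`, `flank_bp`).
#' Unknown keys are rejected before any computation.
#'
#' @param path YAML file, or a list already parsed.
#' @return Validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("run configuration must be a mapping")
  bad <- setdiff(names(cfg), known_config_keys$top)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (sec in intersect(names(cfg), names(known_config_keys))) {
    if (sec == "top") next
    bad <- setdiff(names(cfg[[sec]]), known_config_keys[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

config_call <- function(f, args) do.call(f, args[!vapply(args, is.null, TRUE)])

write_manifest <- function(path, cfg, extra = list()) {
  man <- list(config = unclass(cfg), run = extra)
  yaml::write_yaml(man, path)
  invisible(path)
}

input_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the simulation subcommand
#'
#' Builds a [sim_config()] from the `simulate` section, runs
#' [wf_simulate()], and writes the phased VCF, the population map, the
#' ground-truth BED and a run manifest into `out_dir`.
#'
#' @param cfg A `run_config` (or path to one).
#' @param out_dir Output directory (default from `io$out_dir`).
#' @return Invisibly, the named vector of output paths.
#' @export
run_simulate <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  out_dir <- out_dir %||% cfg$io$out_dir %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc_args <- cfg$simulate %||% list()
  if (is.null(sc_args$seed)) {
    sc_args$seed <- sample.int(.Machine$integer.max, 1L)
    message("no seed in configuration; generated seed ", sc_args$seed)
  }
  sc <- config_call(sim_config, sc_args)
  truth <- wf_simulate(sc)
  vcf_path <- file.path(out_dir, "sim.vcf")
  paths <- write_vcf(truth, vcf_path,
                     popmap_path = file.path(out_dir, "sim.popmap.tsv"))
  write_truth_bed(truth, file.path(out_dir, "sim.truth.bed"))
  write_manifest(file.path(out_dir, "manifest.yaml"), cfg,
                 list(subcommand = "simulate", seed = sc$seed,
                      n_sites = length(truth$positions),
                      sweep = truth$sweep))
  invisible(c(paths, truth_bed = file.path(out_dir, "sim.truth.bed")))
}

# Shared input stage: read VCF + popmap, restrict contigs, apply filters.
load_filtered <- function(cfg) {
  vcf <- cfg$io$vcf %||% stop("io$vcf missing")
  popmap <- cfg$io$popmap %||% stop("io$popmap missing")
  gm <- read_vcf(vcf)
  pm <- read_popmap(popmap)
  if (!is.null(cfg$filters$contigs)) {
    keep <- gm$variants$contig %in% cfg$filters$contigs
    gm <- subset_variants(gm, keep)
    gm$contig_lengths <-
      gm$contig_lengths[names(gm$contig_lengths) %in% cfg$filters$contigs]
  }
  fc_args <- cfg$filters %||% list()
  fc_args$contigs <- NULL
  fc <- config_call(filter_config, fc_args)
  flt <- apply_filters(gm, fc, pm)
  list(gm = flt$gm, report = flt$report, pm = pm, fc = fc,
       vcf = vcf, popmap = popmap)
}

scan_windows <- function(gm, sc) {
  if (is.null(gm$contig_lengths))
    stop("VCF header carries no contig lengths; cannot build windows")
  make_windows(gm$contig_lengths, sc$window_size, sc$step)
}

#' Run the selection-signature scan subcommand
#'
#' Applies the filters, builds the window grid, and runs the two scan
#' approaches: the pooled-Hp scan over the configured population pool, and
#' the groupA-vs-groupB ZFst + XP-EHH scans whose candidate windows are
#' intersected and merged into sweep regions. Regions are annotated when a
#' gene file is configured. Every threshold and standardization constant is
#' echoed into the run manifest; reruns from the same inputs and
#' configuration are byte-identical.
#'
#' @param cfg A `run_config` (or path to one).
#' @param out_dir Output directory (default from `io$out_dir`).
#' @return Invisibly, a list with the scan tables and merged regions.
#' @export
run_scan <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  out_dir <- out_dir %||% cfg$io$out_dir %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config_call(scan_config, cfg$scan %||% list())
  inp <- load_filtered(cfg)
  gm <- inp$gm; pm <- inp$pm
  write_filter_report(inp$report, file.path(out_dir, "filter_report.tsv"))
  windows <- scan_windows(gm, sc)

  pops <- cfg$populations %||% list()
  hp_pool <- pops$hp_pool %||% unique(pm$population)
  group_a <- pops$group_a %||% unique(pm$population[pm$group == "groupA"])
  group_b <- pops$group_b %||% unique(pm$population[pm$group == "groupB"])

  hp <- hp_scan(pool_populations(gm, pm, hp_pool), windows, sc)
  write_tsv(hp, file.path(out_dir, "hp_scan.tsv"))
  hp_regions <- merge_regions(hp[hp$candidate, , drop = FALSE],
                              stat_col = "zhp")
  hp_regions$source <- rep("hp", nrow(hp_regions))

  gmA <- pool_populations(gm, pm, group_a)
  gmB <- pool_populations(gm, pm, group_b)
  if (is.null(gmA$hap) || all(is.na(gmA$hap)) || all(is.na(gmB$hap)))
    stop("XP-EHH requires phased input genotypes")
  fst <- fst_scan(gmA, gmB, windows, sc)
  write_tsv(fst, file.path(out_dir, "fst_scan.tsv"))
  xp <- xpehh_scan(gmA, gmB, windows, sc)
  write_tsv(xp, file.path(out_dir, "xpehh_scan.tsv"))
  common <- intersect_candidates(fst, xp)
  cr <- common_regions(fst, xp)
  cr2 <- if (nrow(cr)) data.frame(contig = cr$contig, start = cr$start,
                                  end = cr$end, direction = cr$direction,
                                  n_windows = NA_integer_,
                                  peak = cr$peak_zfst, source = "fst_xpehh")
         else NULL
  regions <- rbind(hp_regions, cr2)
  if (is.null(regions))
    regions <- data.frame(contig = character(0), start = numeric(0),
                          end = numeric(0), direction = character(0),
                          n_windows = integer(0), peak = numeric(0),
                          source = character(0))
  genes <- if (!is.null(cfg$annotate$genes)) read_genes(cfg$annotate$genes)
           else NULL
  write_report(regions, genes, file.path(out_dir, "regions.tsv"),
               flank_bp = cfg$annotate$flank_bp %||% 30000)

  write_manifest(file.path(out_dir, "manifest.yaml"), cfg, list(
    subcommand = "scan",
    inputs = input_checksums(c(inp$vcf, inp$popmap,
                               cfg$annotate$genes %||% character(0))),
    thresholds = unclass(sc),
    hp_pool = hp_pool, group_a = group_a, group_b = group_b,
    standardization = list(
      hp_mean = attr(hp, "hp_mean"), hp_sd = attr(hp, "hp_sd"),
      fst_mean = attr(fst, "fst_mean"), fst_sd = attr(fst, "fst_sd"),
      xpehh_mean = attr(xp, "xpehh_mean"), xpehh_sd = attr(xp, "xpehh_sd")),
    filter_counts = as.list(inp$report$dropped),
    n_sites_kept = inp$report$n_kept))
  invisible(list(hp = hp, fst = fst, xpehh = xp, common = common,
                 regions = regions))
}

#' Run the diversity subcommand
#'
#' Per-population windowed nucleotide diversity, per-sample inbreeding F,
#' pairwise genome-wide weighted Fst between all population pairs, LD-decay
#' curves per group, the LD-pruned SNP list, and PCA coordinates.
#' Groups with a single sample skip LD/PCA with a warning.
#'
#' @param cfg A `run_config` (or path to one).
#' @param out_dir Output directory (default from `io$out_dir`).
#' @return Invisibly, a list with the computed tables.
#' @export
run_diversity <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  out_dir <- out_dir %||% cfg$io$out_dir %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config_call(scan_config, cfg$scan %||% list())
  inp <- load_filtered(cfg)
  gm <- inp$gm; pm <- inp$pm
  windows <- scan_windows(gm, sc)
  by_pop <- split_by_population(gm, pm)

  pi_tabs <- lapply(names(by_pop), function(p) {
    tab <- nucleotide_diversity(by_pop[[p]], windows)
    tab$population <- p
    tab
  })
  pi_all <- do.call(rbind, pi_tabs)
  write_tsv(pi_all, file.path(out_dir, "pi_windows.tsv"))

  fh <- inbreeding_f(gm)
  write_tsv(fh, file.path(out_dir, "inbreeding.tsv"))

  pops <- names(by_pop)
  pairs <- if (length(pops) >= 2L) utils::combn(pops, 2L) else NULL
  fst_summary <- if (!is.null(pairs)) {
    data.frame(pop_a = pairs[1L, ], pop_b = pairs[2L, ],
               fst = apply(pairs, 2L, function(pr) {
                 wt <- windowed_weighted_fst(by_pop[[pr[1L]]],
                                             by_pop[[pr[2L]]], windows)
                 comp <- wc_fst_sites(genotype_counts(by_pop[[pr[1L]]]),
                                      genotype_counts(by_pop[[pr[2L]]]))
                 ok <- !is.na(comp$a)
                 sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
               }))
  } else data.frame(pop_a = character(0), pop_b = character(0),
                    fst = numeric(0))
  write_tsv(fst_summary, file.path(out_dir, "fst_pairs.tsv"))

  for (grp in unique(pm$group)) {
    gmg <- pool_populations(gm, pm, unique(pm$population[pm$group == grp]))
    if (n_samples(gmg) < 2L) {
      warning("group ", grp, " has a single sample; LD decay skipped")
      next
    }
    ld <- ld_decay(gmg)
    write_tsv(ld, file.path(out_dir, paste0("ld_decay_", grp, ".tsv")))
  }

  kept <- ld_prune(gm)
  writeLines(sprintf("%s\t%d", gm$variants$contig[kept],
                     gm$variants$pos[kept]),
             file.path(out_dir, "ld_pruned_snps.tsv"))
  if (n_samples(gm) >= 2L) {
    pc <- pca_genotypes(subset_variants(gm, seq_len(n_variants(gm)) %in% kept))
    coords <- data.frame(sample = rownames(pc$coords), pc$coords)
    write_tsv(coords, file.path(out_dir, "pca_coords.tsv"))
    write_tsv(data.frame(component = seq_along(pc$eigenvalues),
                         eigenvalue = pc$eigenvalues,
                         prop_var = pc$prop_var),
              file.path(out_dir, "pca_eigenvalues.tsv"))
  }
  write_manifest(file.path(out_dir, "manifest.yaml"), cfg, list(
    subcommand = "diversity",
    inputs = input_checksums(c(inp$vcf, inp$popmap)),
    n_sites_kept = inp$report$n_kept))
  invisible(list(pi = pi_all, inbreeding = fh, fst_pairs = fst_summary,
                 pruned = kept))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
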