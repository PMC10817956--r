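# Forward-in-time Wright-Fisher simulator producing phased multi-population
# panels with optional planted additive sweeps. Infinite-sites mutation keeps
# every site biallelic; positions are integers on [0, L) drawn by rejection.

#' Simulation configuration
#'
#' Builds the configuration for [wf_simulate()]: a common ancestral population
#' evolved to mutation-drift equilibrium, an instantaneous split into
#' `n_pops` descendant populations, independent drift with optional symmetric
#' migration, and an optional additive sweep planted in one population.
#'
#' @param seed Integer seed; the run is fully deterministic given the config.
#' @param n_pops Number of descendant populations (>= 1).
#' @param Ne Diploid population size of every population (and the ancestor).
#' @param split_gen Generations before present at which the populations split.
#' @param migration_rate Per-generation fraction of individuals exchanged
#'   between each pair of populations (symmetric island exchange), in `[0, 1)`.
#' @param L Sequence length in bp (one contig).
#' @param mu Per-bp per-generation mutation rate (infinite sites).
#' @param rec Per-bp per-generation crossover probability; crossovers per
#'   gamete are Poisson with mean `rec * L`, breakpoints uniform.
#' @param sweep Optional list with elements `pop` (1-based population
#'   index, or a vector of indices when the same pressure acts on several
#'   populations of a group), `position` (bp, default `floor(L / 2)`), `s`
#'   (additive selection coefficient, fitnesses 1, 1 + s, 1 + 2s), and
#'   `start_gen` (generations before present at which selection starts;
#'   default `split_gen`).
#' @param sample_sizes Diploid samples drawn per population (recycled).
#' @param depth_mean Mean of the Poisson per-genotype DP emitted by
#'   [write_vcf()].
#' @param gq_const Constant GQ emitted by [write_vcf()].
#' @param burn_in Ancestral burn-in generations; default `10 * Ne`.
#' @param reinject_budget How many times a lost beneficial allele is
#'   re-injected before the sweep is reported lost.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_pops = 2L, Ne = 50L, split_gen = 25L,
                       migration_rate = 0, L = 1e6, mu = 5e-6, rec = 1e-6,
                       sweep = NULL, sample_sizes = 10L, depth_mean = 64,
                       gq_const = 60L, burn_in = NULL,
                       reinject_budget = 50L) {
  n_pops <- as.integer(n_pops)
  Ne <- as.integer(Ne)
  stopifnot(n_pops >= 1L, Ne >= 1L, split_gen >= 0L, L >= 1,
            mu >= 0, rec >= 0,
            migration_rate >= 0, migration_rate < 1,
            depth_mean > 0)
  sample_sizes <- as.integer(rep_len(sample_sizes, n_pops))
  if (any(sample_sizes < 1L) || any(sample_sizes > Ne))
    stop("sample_sizes must satisfy 0 < sample_sizes[i] <= Ne")
  if (is.null(burn_in)) burn_in <- 10L * Ne
  if (!is.null(sweep)) {
    if (is.null(sweep$position)) sweep$position <- floor(L / 2)
    if (is.null(sweep$start_gen)) sweep$start_gen <- split_gen
    stopifnot(all(sweep$pop >= 1L), all(sweep$pop <= n_pops),
              !anyDuplicated(sweep$pop),
              sweep$position >= 0, sweep$position < L,
              sweep$s >= 0, sweep$start_gen <= split_gen)
    sweep$pop <- as.integer(sweep$pop)
    sweep$position <- as.integer(sweep$position)
  }
  structure(list(seed = as.integer(seed), n_pops = n_pops, Ne = Ne,
                 split_gen = as.integer(split_gen),
                 migration_rate = migration_rate, L = as.integer(L),
                 mu = mu, rec = rec, sweep = sweep,
                 sample_sizes = sample_sizes, depth_mean = depth_mean,
                 gq_const = as.integer(gq_const),
                 burn_in = as.integer(burn_in),
                 reinject_budget = as.integer(reinject_budget)),
            class = "sim_config")
}

# Draw `m` integer positions on [0, L) distinct from `existing` and from each
# other (rejection sampling; ties between concurrent draws also rejected).
draw_new_positions <- function(m, existing, L) {
  out <- integer(0)
  while (length(out) < m) {
    cand <- sample.int(L, m - length(out), replace = TRUE) - 1L
    cand <- setdiff(unique(cand), c(existing, out))
    out <- c(out, cand)
  }
  out
}

# One generation of WF reproduction for a single population, no mutation.
# Internal orientation: S x 2N (sites in rows, haplotypes in columns, two
# consecutive columns per diploid). Each offspring haplotype is a recombinant
# mosaic of one random parent's two haplotypes.
wf_reproduce <- function(H, pos, L, rec, weights = NULL) {
  .wf_reproduce_cpp(H, as.numeric(pos), L, rec, weights)
}

# Add infinite-sites mutations to a list of population haplotype matrices
# sharing one position vector. Returns list(H = list, pos = vector), sorted.
add_mutations <- function(Hs, pos, L, mu) {
  m_per <- vapply(Hs, function(H) stats::rpois(1L, ncol(H) * mu * L), 0)
  m_tot <- sum(m_per)
  if (m_tot == 0L) return(list(Hs = Hs, pos = pos))
  newpos <- draw_new_positions(m_tot, pos, L)
  owner <- rep(seq_along(Hs), m_per)
  Hs <- lapply(seq_along(Hs), function(i) {
    H <- Hs[[i]]
    newrows <- matrix(0L, m_tot, ncol(H))
    mine <- which(owner == i)
    if (length(mine)) {
      gam <- sample.int(ncol(H), length(mine), replace = TRUE)
      newrows[cbind(mine, gam)] <- 1L
    }
    rbind(H, newrows)
  })
  # the reproduction kernel requires ascending positions (it copies whole
  # runs between crossover breakpoints), so restore sort order after the
  # append
  pos <- c(pos, newpos)
  o <- order(pos)
  list(Hs = lapply(Hs, function(H) H[o, , drop = FALSE]), pos = pos[o])
}

# Drop sites lost or fixed across all populations, keeping `keep_pos`.
drop_nonsegregating <- function(Hs, pos, keep_pos = integer(0)) {
  if (length(pos) == 0L) return(list(Hs = Hs, pos = pos))
  tot <- Reduce(`+`, lapply(Hs, rowSums))
  nh_tot <- sum(vapply(Hs, ncol, 0L))
  keep <- tot > 0L & tot < nh_tot
  if (length(keep_pos)) keep[pos %in% keep_pos] <- TRUE
  list(Hs = lapply(Hs, function(H) H[keep, , drop = FALSE]), pos = pos[keep])
}

#' Evolve a haplotype panel under Wright-Fisher reproduction
#'
#' Low-level generation loop used by [wf_simulate()], exposed for direct
#' experiments on drift (e.g. fixation probabilities, heterozygosity decay).
#' Not seeded internally: call `set.seed()` first for reproducibility.
#'
#' @param H `2N x S` matrix of 0/1 alleles (two consecutive rows per diploid).
#' @param pos Integer site positions, strictly increasing.
#' @param L Sequence length in bp.
#' @param gens Number of generations.
#' @param mu,rec Per-bp per-generation mutation and crossover rates.
#' @param weights Optional length-`N` parent sampling weights, or a function
#'   `f(H, pos)` returning them, applied every generation.
#' @param drop Which non-segregating sites to remove each generation:
#'   `"both"` (lost and fixed), `"lost"`, or `"none"`.
#' @return `list(H =, pos =)` after `gens` generations.
#' @export
wf_evolve <- function(H, pos, L, gens, mu = 0, rec = 0, weights = NULL,
                      drop = c("both", "lost", "none")) {
  drop <- match.arg(drop)
  H <- t(H)  # internal orientation: sites x haplotypes
  for (g in seq_len(gens)) {
    # without mutation an absorbed state can never change again
    if (mu == 0 && (length(pos) == 0L ||
                    all(rowSums(H) %in% c(0L, ncol(H))))) break
    w <- if (is.function(weights)) weights(t(H), pos) else weights
    H <- wf_reproduce(H, pos, L, rec, w)
    st <- add_mutations(list(H), pos, L, mu)
    H <- st$Hs[[1L]]
    pos <- st$pos
    if (drop != "none" && length(pos)) {
      rs <- rowSums(H)
      keep <- if (drop == "both") rs > 0L & rs < ncol(H) else rs > 0L
      H <- H[keep, , drop = FALSE]
      pos <- pos[keep]
    }
  }
  o <- order(pos)
  list(H = t(H[o, , drop = FALSE]), pos = pos[o])
}

# Symmetric migration: exchange Binomial(Ne, m) random individuals between
# each unordered pair of populations.
migrate <- function(Hs, Ne, m) {
  np <- length(Hs)
  if (m <= 0 || np < 2L) return(Hs)
  for (i in seq_len(np - 1L)) for (j in seq((i + 1L), np)) {
    k <- stats::rbinom(1L, Ne, m)
    if (k == 0L) next
    ii <- sample.int(Ne, k)
    jj <- sample.int(Ne, k)
    ci <- as.vector(rbind(2L * ii - 1L, 2L * ii))
    cj <- as.vector(rbind(2L * jj - 1L, 2L * jj))
    tmp <- Hs[[i]][, ci, drop = FALSE]
    Hs[[i]][, ci] <- Hs[[j]][, cj, drop = FALSE]
    Hs[[j]][, cj] <- tmp
  }
  Hs
}

#' Simulate a phased multi-population panel
#'
#' Runs the discrete-generation Wright-Fisher model described in
#' [sim_config()]: ancestral burn-in, instantaneous split, independent drift
#' with optional symmetric migration, and an optional additive sweep. With a
#' sweep, parents are sampled with weight `1 + s * dosage` at the focal site
#' from `start_gen` onward; the beneficial allele is injected on one random
#' haplotype when absent and re-injected on loss until the budget is
#' exhausted, in which case the truth record reports the sweep as lost.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_truth`: per-population phased haplotype
#'   matrices (`2 * sample_size` rows each) over the union of sites
#'   segregating in the pooled sample, ascending positions, sample IDs, and a
#'   sweep truth record (`pop`, `position`, `s`, `final_freq` in the full
#'   swept population, `lost`).
#' @export
wf_simulate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  Ne <- config$Ne
  nh <- 2L * Ne
  L <- config$L

  # ancestral burn-in (sites x haplotypes internally)
  H <- matrix(0L, 0L, nh)
  pos <- integer(0)
  for (g in seq_len(config$burn_in)) {
    H <- wf_reproduce(H, pos, L, config$rec)
    st <- add_mutations(list(H), pos, L, config$mu)
    st <- drop_nonsegregating(st$Hs, st$pos)
    H <- st$Hs[[1L]]
    pos <- st$pos
  }

  # split: identical copies, then independent drift
  Hs <- replicate(config$n_pops, H, simplify = FALSE)
  sw <- config$sweep
  sw_state <- if (is.null(sw)) NULL else
    list(budget = config$reinject_budget, lost = FALSE, active = FALSE)

  for (g in seq_len(config$split_gen)) {
    gbp <- config$split_gen - g + 1L   # generations before present
    weights_list <- vector("list", config$n_pops)
    if (!is.null(sw) && !isTRUE(sw_state$lost) && gbp <= sw$start_gen) {
      first_gen <- !isTRUE(sw_state$active) && gbp == sw$start_gen
      sw_state$active <- TRUE
      # at the very first generation after the split the populations are
      # still identical copies, so a sweep shared by several populations of
      # a group is planted on the same haplotype background in each
      shared_carrier <- if (first_gen && gbp == config$split_gen)
        sample.int(nh, 1L) else NA_integer_
      for (sp in sw$pop) {
        j <- match(sw$position, pos)
        freq <- if (is.na(j)) 0L else sum(Hs[[sp]][j, ])
        if (freq == 0L) {
          if (sw_state$budget > 0L) {
            sw_state$budget <- sw_state$budget - 1L
            if (is.na(j)) {  # add the focal site to every population,
                             # preserving ascending position order
              pos <- c(pos, sw$position)
              o <- order(pos)
              Hs <- lapply(Hs, function(Hp)
                rbind(Hp, 0L)[o, , drop = FALSE])
              pos <- pos[o]
              j <- match(sw$position, pos)
            }
            carrier <- if (!is.na(shared_carrier)) shared_carrier
                       else sample.int(nh, 1L)
            Hs[[sp]][j, carrier] <- 1L
          } else {
            sw_state$lost <- TRUE
            break
          }
        }
        if (!sw_state$lost && sw$s > 0) {
          j <- match(sw$position, pos)
          dos <- Hs[[sp]][j, seq(1L, nh, 2L)] + Hs[[sp]][j, seq(2L, nh, 2L)]
          weights_list[[sp]] <- 1 + sw$s * dos
        }
      }
    }
    Hs <- lapply(seq_along(Hs), function(i)
      wf_reproduce(Hs[[i]], pos, L, config$rec, weights_list[[i]]))
    st <- add_mutations(Hs, pos, L, config$mu)
    Hs <- migrate(st$Hs, Ne, config$migration_rate)
    keep_pos <- if (!is.null(sw) && isTRUE(sw_state$active) &&
                    !isTRUE(sw_state$lost)) sw$position else integer(0)
    st <- drop_nonsegregating(Hs, st$pos, keep_pos)
    Hs <- st$Hs
    pos <- st$pos
  }

  sweep_rec <- NULL
  if (!is.null(sw)) {
    j <- match(sw$position, pos)
    final_freq <- if (is.na(j)) 0 else
      mean(unlist(lapply(sw$pop, function(sp) Hs[[sp]][j, ])))
    sweep_rec <- list(pop = sw$pop, position = sw$position, s = sw$s,
                      start_gen = sw$start_gen, final_freq = final_freq,
                      lost = isTRUE(sw_state$lost))
  }

  # draw diploid samples, restrict to sites segregating in the union sample
  haps <- vector("list", config$n_pops)
  sample_ids <- vector("list", config$n_pops)
  for (i in seq_len(config$n_pops)) {
    ids <- sort(sample.int(Ne, config$sample_sizes[i]))
    cols <- as.vector(rbind(2L * ids - 1L, 2L * ids))
    haps[[i]] <- Hs[[i]][, cols, drop = FALSE]
    sample_ids[[i]] <- sprintf("P%dS%02d", i, seq_len(config$sample_sizes[i]))
  }
  if (length(pos)) {
    tot <- Reduce(`+`, lapply(haps, rowSums))
    nh_samp <- sum(vapply(haps, ncol, 0L))
    keep <- which(tot > 0L & tot < nh_samp)
    keep <- keep[order(pos[keep])]
    haps <- lapply(haps, function(Hp) t(Hp[keep, , drop = FALSE]))
    pos <- pos[keep]
  }  else {
    haps <- lapply(haps, t)
  }
  names(haps) <- names(sample_ids) <- paste0("pop", seq_len(config$n_pops))

  structure(list(haps = haps, positions = pos, contig = "chr1", L = L,
                 sample_ids = sample_ids, sweep = sweep_rec,
                 seed = config$seed, config = config,
                 missing = NULL, low_gq = NULL),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  ns <- vapply(x$haps, function(h) nrow(h) %/% 2L, 0L)
  cat("Wright-Fisher simulated panel (seed ", x$seed, ")\n", sep = "")
  cat("  contig ", x$contig, ", length ", x$L, " bp, ",
      length(x$positions), " segregating sites\n", sep = "")
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(x$haps), ns), collapse = ", "), "\n")
  if (!is.null(x$sweep))
    cat(sprintf("  sweep: pop %s at %d bp, s = %g, final freq %.3f%s\n",
                paste(x$sweep$pop, collapse = ","), x$sweep$position,
                x$sweep$s, x$sweep$final_freq,
                if (x$sweep$lost) " (lost)" else ""))
  invisible(x)
}

#' Degrade a simulated panel with missing and low-quality genotypes
#'
#' Randomly masks diploid genotypes to missing and flags others for a GQ
#' below the filtering threshold, at the stated rates. The masks are honoured
#' by [write_vcf()]. Deterministic given `seed`.
#'
#' @param truth A `sim_truth` object.
#' @param missing_rate,low_gq_rate Per-genotype probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return The `sim_truth` with `missing` and `low_gq` mask lists
#'   (one `n_samples x n_sites` logical matrix per population).
#' @export
degrade <- function(truth, missing_rate = 0, low_gq_rate = 0,
                    seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "sim_truth"),
            missing_rate >= 0, missing_rate <= 1,
            low_gq_rate >= 0, low_gq_rate <= 1)
  set.seed(seed)
  S <- length(truth$positions)
  mk <- function(rate) lapply(truth$haps, function(h) {
    n <- nrow(h) %/% 2L
    matrix(stats::runif(n * S) < rate, n, S)
  })
  truth$missing <- mk(missing_rate)
  truth$low_gq <- mk(low_gq_rate)
  truth
}

#' Write a simulated panel as a phased VCF plus a population map
#'
#' Emits VCF 4.2 with one contig (header `##contig` carries its length),
#' phased `GT`, per-genotype `DP ~ Poisson(depth_mean)` and constant `GQ`
#' (demoted to 10 for genotypes flagged by [degrade()]); genotypes masked by
#' [degrade()] are written `./.`. A sidecar TSV maps
#' `sample<TAB>population<TAB>group`.
#'
#' @param truth A `sim_truth` object with at least one site.
#' @param path Output VCF path.
#' @param popmap_path Output population-map TSV path (default: `path` with
#'   extension replaced by `.popmap.tsv`); `NA` suppresses it.
#' @param groups Named character vector population -> group; by default the
#'   first half of the populations is `groupA`, the rest `groupB`.
#' @param seed Seed for the DP draws (default derived from the truth seed, so
#'   identical config + seed gives a byte-identical file).
#' @return Invisibly, `c(vcf = path, popmap = popmap_path)`.
#' @export
write_vcf <- function(truth, path, popmap_path = NULL, groups = NULL,
                      seed = truth$seed + 1000L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (length(truth$positions) == 0L)
    stop("refusing to write a VCF with no segregating sites")
  set.seed(seed)
  pops <- names(truth$haps)
  if (is.null(groups)) {
    nA <- ceiling(length(pops) / 2)
    groups <- stats::setNames(rep(c("groupA", "groupB"),
                                  c(nA, length(pops) - nA)), pops)
  }
  samples <- unlist(truth$sample_ids, use.names = FALSE)
  S <- length(truth$positions)

  gt_cols <- lapply(seq_along(truth$haps), function(i) {
    h <- truth$haps[[i]]
    n <- nrow(h) %/% 2L
    a1 <- t(h[seq(1L, 2L * n, 2L), , drop = FALSE])  # S x n
    a2 <- t(h[seq(2L, 2L * n, 2L), , drop = FALSE])
    gt <- matrix(paste0(a1, "|", a2), S, n)
    if (!is.null(truth$missing)) gt[t(truth$missing[[i]])] <- "./."
    gq <- matrix(truth$config$gq_const, S, n)
    if (!is.null(truth$low_gq)) gq[t(truth$low_gq[[i]])] <- 10L
    dp <- matrix(stats::rpois(S * n, truth$config$depth_mean), S, n)
    matrix(paste0(gt, ":", dp, ":", gq), S, n)
  })
  gt_all <- do.call(cbind, gt_cols)

  hdr <- c("##fileformat=VCFv4.2",
           "##source=sweepscan_wf_simulate",
           sprintf("##contig=<ID=%s,length=%d>", truth$contig, truth$L),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(truth$contig, truth$positions + 1L, ".", "A", "C", ".",
                "PASS", ".", "GT:DP:GQ",
                apply(gt_all, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)

  if (is.null(popmap_path))
    popmap_path <- sub("\\.vcf$", "", path)
  if (!is.na(popmap_path)) {
    popmap_path <- if (grepl("popmap\\.tsv$", popmap_path)) popmap_path
                   else paste0(popmap_path, ".popmap.tsv")
    pm <- data.frame(
      sample = samples,
      population = rep(pops, vapply(truth$sample_ids, length, 0L)),
      group = unname(groups[rep(pops, vapply(truth$sample_ids, length, 0L))]))
    utils::write.table(pm, popmap_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(vcf = path, popmap = if (is.na(popmap_path)) NA_character_
                                   else popmap_path))
}

#' Write the ground-truth sweep locus as BED
#'
#' @param truth A `sim_truth` object.
#' @param path Output path. The file is empty when no sweep was simulated.
#' @export
write_truth_bed <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(truth$sweep)) {
    writeLines(character(0), path)
  } else {
    sw <- truth$sweep
    writeLines(sprintf("%s\t%d\t%d\tsweep_pop%d_s%g_freq%.3f%s", truth$contig,
                       sw$position, sw$position + 1L, sw$pop, sw$s,
                       sw$final_freq, if (sw$lost) "_lost" else ""),
               path)
  }
  invisible(path)
}
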