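# VCF ingestion, the genotype data model, and the SNP/sample quality filters.
# Internal coordinates are 0-based half-open; VCF I/O is 1-based inclusive and
# the conversion is confined to this file.

#' Construct a genotype matrix object
#'
#' The central container: variant table, diploid dosage matrix
#' (samples x variants, values 0/1/2/NA), phased haplotype matrix
#' (2*samples x variants, 0/1/NA; NA where a genotype is unphased or
#' missing), and optional per-genotype GQ/DP.
#'
#' @param variants data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, `biallelic`.
#' @param dos samples x variants integer matrix, rownames = sample IDs.
#' @param hap 2*samples x variants matrix or NULL (no phased data).
#' @param gq,dp Optional samples x variants numeric matrices.
#' @param contig_lengths Named vector of contig lengths (bp), or NULL.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(variants, dos, hap = NULL, gq = NULL, dp = NULL,
                        contig_lengths = NULL) {
  stopifnot(is.data.frame(variants), nrow(variants) == ncol(dos))
  if (!is.null(hap)) {
    stopifnot(nrow(hap) == 2L * nrow(dos), ncol(hap) == ncol(dos))
    both <- !is.na(hap[seq(1L, nrow(hap), 2L), , drop = FALSE]) &
            !is.na(hap[seq(2L, nrow(hap), 2L), , drop = FALSE])
    hsum <- hap[seq(1L, nrow(hap), 2L), , drop = FALSE] +
            hap[seq(2L, nrow(hap), 2L), , drop = FALSE]
    bad <- both & !is.na(dos) & hsum != dos
    if (any(bad, na.rm = TRUE))
      stop("dosage must equal the sum of the two haplotype alleles")
  }
  structure(list(variants = variants, dos = dos, hap = hap, gq = gq, dp = dp,
                 samples = rownames(dos), contig_lengths = contig_lengths),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix: ", nrow(x$dos), " samples x ", ncol(x$dos),
      " variants on ", length(unique(x$variants$contig)), " contig(s)\n",
      sep = "")
  cat("  phased haplotypes: ", if (is.null(x$hap)) "no" else "yes",
      "; GQ: ", if (is.null(x$gq)) "no" else "yes",
      "; DP: ", if (is.null(x$dp)) "no" else "yes", "\n", sep = "")
  invisible(x)
}

n_samples <- function(gm) nrow(gm$dos)
n_variants <- function(gm) ncol(gm$dos)

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses GT (required), GQ and DP (optional) with vcfR. Unphased genotypes
#' get NA in the haplotype view but a valid dosage; multi-allelic or non-SNP
#' records are retained and marked `biallelic = FALSE` for the filter stage.
#' Contig lengths are taken from the `##contig` header lines.
#'
#' @param path VCF file (plain or bgzipped).
#' @param region Optional `"contig:start-end"` query, 1-based inclusive.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, region = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  fmt <- vcf@gt[, 1L]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stop("VCF FORMAT lacks GT at one or more records; GT is required")

  variants <- data.frame(contig = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  variants$biallelic <- !grepl(",", variants$alt) &
    nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$alt %in% c("A", "C", "G", "T")

  gt <- vcfR::extract.gt(vcf, "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L)
  has_gq <- any(grepl("(^|:)GQ(:|$)", fmt))
  has_dp <- any(grepl("(^|:)DP(:|$)", fmt))
  gq <- if (has_gq) vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE) else NULL
  dp <- if (has_dp) vcfR::extract.gt(vcf, "DP", as.numeric = TRUE) else NULL

  a1c <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2c <- substr(gt, 3L, 3L)
  tonum <- function(ch) {
    out <- suppressWarnings(as.integer(ch))
    out  # "." and "" become NA
  }
  a1 <- tonum(a1c); a2 <- tonum(a2c)
  dim(a1) <- dim(a2) <- dim(gt)
  # alleles beyond 1 (multi-allelic) are treated as uncalled for the
  # biallelic dosage model; such records are dropped by the biallelic filter
  a1[a1 > 1L] <- NA_integer_
  a2[a2 > 1L] <- NA_integer_
  dosv <- a1 + a2
  phased <- sep == "|" & !is.na(a1) & !is.na(a2)
  dim(phased) <- dim(gt)

  nsamp <- ncol(gt)
  nvar <- nrow(gt)
  samples <- colnames(gt)
  dos <- t(matrix(dosv, nvar, nsamp))
  rownames(dos) <- samples
  hap <- matrix(NA_integer_, 2L * nsamp, nvar)
  for (s in seq_len(nsamp)) {
    ok <- phased[, s]
    hap[2L * s - 1L, ok] <- a1[ok, s]
    hap[2L * s, ok] <- a2[ok, s]
  }
  gqm <- if (has_gq) t(gq) else NULL
  dpm <- if (has_dp) t(dp) else NULL
  if (!is.null(gqm)) rownames(gqm) <- samples
  if (!is.null(dpm)) rownames(dpm) <- samples

  meta <- vcf@meta
  cl <- regmatches(meta, regexec(
    "^##contig=<ID=([^,>]+),.*length=([0-9]+)", meta))
  cl <- cl[vapply(cl, length, 0L) == 3L]
  contig_lengths <- if (length(cl))
    stats::setNames(as.numeric(vapply(cl, `[`, "", 3L)),
                    vapply(cl, `[`, "", 2L)) else NULL

  gm <- geno_matrix(variants, dos, hap, gqm, dpm, contig_lengths)
  if (!is.null(region)) {
    mm <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(mm) != 4L) stop("region must be 'contig:start-end'")
    keep <- gm$variants$contig == mm[2L] &
      gm$variants$pos >= as.integer(mm[3L]) &
      gm$variants$pos <= as.integer(mm[4L])
    gm <- subset_variants(gm, keep)
  }
  gm
}

# Subset helpers keep all parallel structures aligned.
subset_variants <- function(gm, keep) {
  gm$variants <- gm$variants[keep, , drop = FALSE]
  rownames(gm$variants) <- NULL
  gm$dos <- gm$dos[, keep, drop = FALSE]
  if (!is.null(gm$hap)) gm$hap <- gm$hap[, keep, drop = FALSE]
  if (!is.null(gm$gq)) gm$gq <- gm$gq[, keep, drop = FALSE]
  if (!is.null(gm$dp)) gm$dp <- gm$dp[, keep, drop = FALSE]
  gm
}

subset_samples <- function(gm, idx) {
  if (is.character(idx)) idx <- match(idx, gm$samples)
  if (anyNA(idx)) stop("unknown sample in subset")
  hrows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  gm$dos <- gm$dos[idx, , drop = FALSE]
  if (!is.null(gm$hap)) gm$hap <- gm$hap[hrows, , drop = FALSE]
  if (!is.null(gm$gq)) gm$gq <- gm$gq[idx, , drop = FALSE]
  if (!is.null(gm$dp)) gm$dp <- gm$dp[idx, , drop = FALSE]
  gm$samples <- rownames(gm$dos)
  gm
}

#' Read / write a population map
#'
#' A population map assigns every sample to a population and every population
#' to a comparison group (e.g. the two climate-extreme groups whose ordering
#' fixes the XP-EHH sign convention: groupA first).
#'
#' @param path TSV with header `sample`, `population`, `group`.
#' @return data.frame of class `pop_map`.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "population", "group") %in% names(pm)))
  if (anyDuplicated(pm$sample)) stop("duplicated sample in population map")
  class(pm) <- c("pop_map", "data.frame")
  pm
}

#' @rdname read_popmap
#' @param pm A population-map data.frame.
#' @export
write_popmap <- function(pm, path) {
  utils::write.table(pm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test on the heterozygote count given the
#' allele counts: the P-value sums the probabilities of all heterozygote
#' counts (same parity, same allele totals) no more probable than the
#' observed one. Monomorphic sites return 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return P-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  stopifnot(n >= 1)
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0L) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(n_Aa = h | allele counts) up to the shared constant
  # lfactorial(n) - lchoose(2n, nA): multinomial coefficient times 2^h
  lp <- -lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) + hets * log(2)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Pairwise relatedness (Yang et al. Ajk estimator)
#'
#' Averages `((g_i - 2p)(g_j - 2p)) / (2p(1-p))` over polymorphic sites for
#' each sample pair; the diagonal uses
#' `(g^2 - (1 + 2p) g + 2 p^2) / (2p(1-p))` so non-inbred samples have
#' expectation 1. Sites with allele frequency 0 or 1 are skipped; missing
#' genotypes are excluded pairwise.
#'
#' @param gm A [geno_matrix()] with at least 2 samples.
#' @return Symmetric samples x samples matrix.
#' @export
relatedness_matrix <- function(gm) {
  D <- gm$dos
  stopifnot(nrow(D) >= 2L)
  called <- !is.na(D)
  nall <- 2 * colSums(called)
  p <- colSums(D, na.rm = TRUE) / nall
  use <- is.finite(p) & p > 0 & p < 1
  if (!any(use)) stop("no polymorphic site for relatedness estimation")
  D <- D[, use, drop = FALSE]
  called <- called[, use, drop = FALSE]
  p <- p[use]
  w <- 1 / (2 * p * (1 - p))
  X <- sweep(D, 2L, 2 * p)               # g - 2p, NA at missing
  Z <- sweep(X, 2L, sqrt(w), `*`)
  Z[!called] <- 0
  num <- tcrossprod(Z)
  cnt <- tcrossprod(called * 1)
  A <- num / cnt
  # diagonal: per-sample estimator
  dterm <- (D^2 - sweep(D, 2L, 1 + 2 * p, `*`) +
              matrix(2 * p^2, nrow(D), ncol(D), byrow = TRUE)) *
           matrix(w, nrow(D), ncol(D), byrow = TRUE)
  dterm[!called] <- NA
  diag(A) <- 1 + rowMeans(dterm, na.rm = TRUE)
  dimnames(A) <- list(gm$samples, gm$samples)
  A
}

#' Filtering thresholds
#'
#' Keep rules read strictly: genotype kept iff `GQ > gq_min` and
#' `DP > dp_min`; site kept iff biallelic SNP, missing rate `< max_missing`,
#' `MAF > maf_min` (union sample, called alleles only), and HWE exact
#' `P >= hwe_p_min`; one member of any sample pair with relatedness
#' `> relatedness_max` is removed. Set a threshold to `NA` to disable it.
#'
#' @param maf_min,gq_min,dp_min,max_missing,hwe_p_min,relatedness_max
#'   Numeric thresholds (NA disables).
#' @param biallelic_only Drop non-biallelic/non-SNP records.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(maf_min = 0.05, gq_min = 15, dp_min = 3,
                          max_missing = 0.20, hwe_p_min = 1e-7,
                          biallelic_only = TRUE, relatedness_max = 0.9) {
  structure(list(maf_min = maf_min, gq_min = gq_min, dp_min = dp_min,
                 max_missing = max_missing, hwe_p_min = hwe_p_min,
                 biallelic_only = isTRUE(biallelic_only),
                 relatedness_max = relatedness_max),
            class = "filter_config")
}

#' Apply the SNP and sample quality filters
#'
#' Order of operations: per-genotype masking (low GQ, low DP become missing),
#' then site-level drops in fixed order (non-biallelic, missingness, MAF,
#' HWE), then relatedness-based removal of one member of each related sample
#' pair (the one with higher missingness; ties keep the earlier sample ID).
#'
#' @param gm A [geno_matrix()].
#' @param fc A [filter_config()].
#' @param pm Optional population map (unused by the filters themselves but
#'   validated against the sample set when given).
#' @return `list(gm =, report =)` where the report (class `filter_report`)
#'   counts sites dropped per reason and samples removed; kept + dropped
#'   equals the input at every stage.
#' @export
apply_filters <- function(gm, fc = filter_config(), pm = NULL) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(fc, "filter_config"))
  if (!is.null(pm) && !all(gm$samples %in% pm$sample))
    stop("population map does not cover all VCF samples")
  n_in <- n_variants(gm)

  # genotype-level masking
  n_masked <- 0L
  mask <- NULL
  if (!is.na(fc$gq_min)) {
    if (is.null(gm$gq)) warning("no GQ in input; GQ filter is a no-op")
    else mask <- !is.na(gm$gq) & gm$gq <= fc$gq_min
  }
  if (!is.na(fc$dp_min)) {
    if (is.null(gm$dp)) warning("no DP in input; DP filter is a no-op")
    else {
      m2 <- !is.na(gm$dp) & gm$dp <= fc$dp_min
      mask <- if (is.null(mask)) m2 else mask | m2
    }
  }
  if (!is.null(mask) && any(mask)) {
    n_masked <- sum(mask & !is.na(gm$dos))
    gm$dos[mask] <- NA_integer_
    if (!is.null(gm$hap)) {
      idx <- which(mask, arr.ind = TRUE)
      gm$hap[cbind(2L * idx[, 1L] - 1L, idx[, 2L])] <- NA_integer_
      gm$hap[cbind(2L * idx[, 1L], idx[, 2L])] <- NA_integer_
    }
  }

  reason <- rep(NA_character_, n_variants(gm))
  alive <- rep(TRUE, n_variants(gm))

  if (fc$biallelic_only) {
    bad <- alive & !gm$variants$biallelic
    reason[bad] <- "non_biallelic"
    alive <- alive & !bad
  }
  called <- !is.na(gm$dos)
  miss_rate <- 1 - colMeans(called)
  if (!is.na(fc$max_missing)) {
    bad <- alive & miss_rate >= fc$max_missing
    reason[bad] <- "missingness"
    alive <- alive & !bad
  }
  ac <- colSums(gm$dos, na.rm = TRUE)
  an <- 2 * colSums(called)
  af <- ifelse(an > 0, ac / an, NA_real_)
  maf <- pmin(af, 1 - af)
  if (!is.na(fc$maf_min)) {
    bad <- alive & (is.na(maf) | maf <= fc$maf_min)
    reason[bad] <- "maf"
    alive <- alive & !bad
  }
  if (!is.na(fc$hwe_p_min)) {
    idx <- which(alive)
    hwep <- vapply(idx, function(j) {
      d <- gm$dos[, j]
      hwe_exact_test(sum(d == 0L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
                     sum(d == 2L, na.rm = TRUE))
    }, 0)
    bad <- idx[hwep < fc$hwe_p_min]
    reason[bad] <- "hwe"
    alive[bad] <- FALSE
  }

  counts <- c(non_biallelic = sum(reason == "non_biallelic", na.rm = TRUE),
              missingness = sum(reason == "missingness", na.rm = TRUE),
              maf = sum(reason == "maf", na.rm = TRUE),
              hwe = sum(reason == "hwe", na.rm = TRUE))
  site_table <- data.frame(contig = gm$variants$contig[!alive],
                           pos = gm$variants$pos[!alive],
                           reason = reason[!alive])
  gm <- subset_variants(gm, alive)

  # sample-level relatedness removal
  removed <- character(0)
  if (!is.na(fc$relatedness_max) && n_samples(gm) >= 2L &&
      n_variants(gm) >= 1L) {
    A <- tryCatch(relatedness_matrix(gm), error = function(e) NULL)
    if (!is.null(A)) {
      smiss <- rowMeans(is.na(gm$dos))
      repeat {
        off <- A
        off[!upper.tri(off)] <- NA
        if (all(is.na(off)) || max(off, na.rm = TRUE) <= fc$relatedness_max)
          break
        ij <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1L, ]
        si <- rownames(A)[ij[1L]]; sj <- rownames(A)[ij[2L]]
        drop_s <- if (smiss[si] > smiss[sj]) si
                  else if (smiss[sj] > smiss[si]) sj
                  else sj   # tie: drop the later sample ID
        removed <- c(removed, drop_s)
        keep <- setdiff(rownames(A), drop_s)
        A <- A[keep, keep, drop = FALSE]
        smiss <- smiss[keep]
      }
      if (length(removed))
        gm <- subset_samples(gm, setdiff(gm$samples, removed))
    }
  }

  if (n_variants(gm) == 0L) warning("no variants survive filtering")
  report <- structure(list(n_input = n_in, n_kept = n_variants(gm),
                           dropped = counts, genotypes_masked = n_masked,
                           samples_removed = removed,
                           site_table = site_table),
                      class = "filter_report")
  stopifnot(report$n_kept + sum(counts) == n_in)
  list(gm = gm, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report: ", x$n_input, " sites in, ", x$n_kept, " kept\n",
      sep = "")
  for (r in names(x$dropped))
    cat(sprintf("  dropped (%s): %d\n", r, x$dropped[[r]]))
  cat("  genotypes masked (GQ/DP):", x$genotypes_masked, "\n")
  if (length(x$samples_removed))
    cat("  samples removed (relatedness):",
        paste(x$samples_removed, collapse = ", "), "\n")
  invisible(x)
}

#' Write the filter report to TSV
#'
#' @param report A `filter_report`.
#' @param path Output path for the per-site table; a `.summary.tsv` sidecar
#'   carries the per-reason counts.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report$site_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summ <- data.frame(metric = c("n_input", "n_kept", "genotypes_masked",
                                paste0("dropped_", names(report$dropped)),
                                "samples_removed"),
                     value = c(report$n_input, report$n_kept,
                               report$genotypes_masked,
                               unname(report$dropped),
                               length(report$samples_removed)))
  utils::write.table(summ, paste0(path, ".summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a genotype matrix by population
#'
#' @param gm A [geno_matrix()].
#' @param pm A population map covering the samples.
#' @param pops Populations to extract (default: all in the map order).
#' @return Named list of per-population `geno_matrix` objects; every variant
#'   column is retained (sites monomorphic within a population are kept --
#'   downstream window statistics decide their own handling).
#' @export
split_by_population <- function(gm, pm, pops = unique(pm$population)) {
  unknown <- setdiff(pops, pm$population)
  if (length(unknown))
    stop("unknown population(s): ", paste(unknown, collapse = ", "))
  out <- lapply(pops, function(p) {
    ss <- intersect(gm$samples, pm$sample[pm$population == p])
    subset_samples(gm, ss)
  })
  names(out) <- pops
  out
}

#' Pool populations into a single genotype matrix
#'
#' @inheritParams split_by_population
#' @return One `geno_matrix` whose samples are the concatenation of the
#'   requested populations' samples (in map order).
#' @export
pool_populations <- function(gm, pm, pops = unique(pm$population)) {
  unknown <- setdiff(pops, pm$population)
  if (length(unknown))
    stop("unknown population(s): ", paste(unknown, collapse = ", "))
  ss <- intersect(gm$samples, pm$sample[pm$population %in% pops])
  subset_samples(gm, ss)
}
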