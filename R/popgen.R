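# Diversity and structure statistics: sliding windows, nucleotide diversity,
# per-sample inbreeding, Weir-Cockerham Fst, LD r2 / decay / pruning, PCA.

#' Build sliding genomic windows
#'
#' Windows start at 0, `step`, `2 * step`, ... while the start is inside the
#' contig; the last windows are truncated at the contig end. Coordinates are
#' 0-based half-open.
#'
#' @param contig_lengths Named vector of contig lengths in bp.
#' @param size,step Window size and slide step in bp (`size >= step > 0`).
#' @return data.frame `contig`, `start`, `end`, sorted.
#' @export
make_windows <- function(contig_lengths, size = 20000, step = 10000) {
  stopifnot(size >= step, step > 0, length(contig_lengths) >= 1)
  if (is.null(names(contig_lengths)))
    stop("contig_lengths must be named")
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq.int(0, max(0, len - 1), by = step)
    data.frame(contig = ctg, start = starts,
               end = pmin(starts + size, len))
  })
  do.call(rbind, out)
}

# Index variant columns falling in each window. Returns a list (per window)
# of column indices into gm's variant table. Positions are converted to the
# internal 0-based convention here.
window_site_index <- function(gm, windows) {
  pos0 <- gm$variants$pos - 1L
  ctg <- gm$variants$contig
  lapply(seq_len(nrow(windows)), function(k) {
    idx <- which(ctg == windows$contig[k])
    p <- pos0[idx]
    o <- order(p)
    idx <- idx[o]; p <- p[o]
    lo <- findInterval(windows$start[k] - 0.5, p) + 1L
    hi <- findInterval(windows$end[k] - 0.5, p)
    if (hi < lo) integer(0) else idx[lo:hi]
  })
}

#' Windowed nucleotide diversity (pi)
#'
#' Per site the pairwise-difference proportion is
#' `c_ref * c_alt / choose(c_ref + c_alt, 2)` on called allele counts; the
#' window value is the sum over sites divided by the full window span in bp.
#'
#' @param gm A [geno_matrix()] for one population.
#' @param windows Windows from [make_windows()].
#' @return The window table with `n_snps` (sites with called alleles) and
#'   `pi`; windows with no called site get `pi = 0` and `n_snps = 0`.
#' @export
nucleotide_diversity <- function(gm, windows) {
  called <- !is.na(gm$dos)
  an <- 2 * colSums(called)
  ac <- colSums(gm$dos, na.rm = TRUE)
  cref <- an - ac
  site_val <- ifelse(an >= 2, cref * ac / choose(an, 2), 0)
  wi <- window_site_index(gm, windows)
  windows$n_snps <- vapply(wi, function(ix) sum(an[ix] > 0), 0)
  windows$pi <- vapply(seq_along(wi), function(k)
    sum(site_val[wi[[k]]]) / (windows$end[k] - windows$start[k]), 0)
  windows
}

#' Per-sample inbreeding coefficient F
#'
#' Method-of-moments estimator `F = (O_hom - E_hom) / (L - E_hom)` where, for
#' each of the sample's called sites, the expected homozygosity under random
#' mating is `1 - 2 p (1 - p) * 2n / (2n - 1)` with `p` the allele frequency
#' and `n` the called diploid count at the site.
#'
#' @param gm A [geno_matrix()] with >= 2 samples.
#' @return data.frame `sample`, `o_hom`, `e_hom`, `n_sites`, `f` (`NA` for a
#'   sample with no usable site).
#' @export
inbreeding_f <- function(gm) {
  stopifnot(n_samples(gm) >= 2L)
  called <- !is.na(gm$dos)
  ncall <- colSums(called)
  an <- 2 * ncall
  p <- ifelse(an > 0, colSums(gm$dos, na.rm = TRUE) / an, NA_real_)
  e_site <- ifelse(an >= 2, 1 - 2 * p * (1 - p) * an / (an - 1), NA_real_)
  usable <- !is.na(e_site)
  hom <- (gm$dos == 0L | gm$dos == 2L)
  hom[!called] <- NA
  o_hom <- rowSums(hom[, usable, drop = FALSE], na.rm = TRUE)
  cl <- called[, usable, drop = FALSE]
  e_hom <- as.vector(cl %*% e_site[usable])
  n_sites <- rowSums(cl)
  f <- ifelse(n_sites > 0 & (n_sites - e_hom) != 0,
              (o_hom - e_hom) / (n_sites - e_hom), NA_real_)
  data.frame(sample = gm$samples, o_hom = o_hom, e_hom = e_hom,
             n_sites = n_sites, f = f, row.names = NULL)
}

#' Weir-Cockerham variance components at one site (two populations)
#'
#' The 1984 diploid estimator with `r = 2` populations, from per-population
#' genotype counts `(n_homref, n_het, n_homalt)`: among-population (`a`),
#' among-individual (`b`) and within-individual (`c`) components, and the
#' per-site ratio `a / (a + b + c)`.
#'
#' @param countsA,countsB Length-3 genotype count vectors.
#' @return `list(a =, b =, c =, fst =)`; all `NA` when the site is
#'   monomorphic across both populations (`a + b + c = 0`) or a population
#'   has no called genotype.
#' @export
wc_fst_components <- function(countsA, countsB) {
  v <- wc_fst_sites(matrix(as.numeric(countsA), 3L),
                    matrix(as.numeric(countsB), 3L))
  list(a = v$a[1L], b = v$b[1L], c = v$c[1L], fst = v$fst[1L])
}

# Vectorized WC components over sites; cntA/cntB are 3 x S matrices of
# genotype counts (rows: hom-ref, het, hom-alt).
wc_fst_sites <- function(cntA, cntB) {
  n1 <- colSums(cntA); n2 <- colSums(cntB)
  p1 <- ifelse(n1 > 0, (cntA[2L, ] + 2 * cntA[3L, ]) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, (cntB[2L, ] + 2 * cntB[3L, ]) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, cntA[2L, ] / n1, NA_real_)
  h2 <- ifelse(n2 > 0, cntB[2L, ] / n2, NA_real_)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  bad <- !is.finite(a) | !is.finite(b) | !is.finite(cc) | n1 < 1 | n2 < 1
  denom <- a + b + cc
  fst <- ifelse(!bad & denom != 0, a / denom, NA_real_)
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  fst[bad | denom == 0] <- NA_real_
  list(a = a, b = b, c = cc, fst = fst)
}

genotype_counts <- function(gm) {
  d <- gm$dos
  rbind(colSums(d == 0L, na.rm = TRUE),
        colSums(d == 1L, na.rm = TRUE),
        colSums(d == 2L, na.rm = TRUE))
}

#' Windowed weighted Weir-Cockerham Fst
#'
#' Window Fst is the ratio of sums `sum(a) / sum(a + b + c)` over the
#' window's usable sites (not the mean of per-site ratios).
#'
#' @param gmA,gmB Per-group [geno_matrix()] objects over the same variants.
#' @param windows Windows from [make_windows()].
#' @param min_sites Windows with fewer usable sites get `NA`.
#' @return Window table with `n_snps` (usable sites) and `fst`.
#' @export
windowed_weighted_fst <- function(gmA, gmB, windows, min_sites = 1L) {
  stopifnot(n_variants(gmA) == n_variants(gmB))
  comp <- wc_fst_sites(genotype_counts(gmA), genotype_counts(gmB))
  usable <- !is.na(comp$a)
  wi <- window_site_index(gmA, windows)
  num <- vapply(wi, function(ix) sum(comp$a[ix][usable[ix]]), 0)
  den <- vapply(wi, function(ix)
    sum((comp$a + comp$b + comp$c)[ix][usable[ix]]), 0)
  nsn <- vapply(wi, function(ix) sum(usable[ix]), 0)
  windows$n_snps <- nsn
  windows$fst <- ifelse(nsn >= min_sites & den != 0, num / den, NA_real_)
  windows
}

#' Haplotype r-squared between two sites
#'
#' `D = f11 - p1 p2` over jointly-called haplotypes;
#' `r2 = D^2 / (p1 (1 - p1) p2 (1 - p2))`.
#'
#' @param h1,h2 Vectors of 0/1 alleles (one entry per haplotype; NA allowed).
#' @return r-squared in `[0, 1]`, or `NA` when fewer than 2 jointly-called
#'   haplotypes remain or either site is monomorphic in the jointly-called
#'   set.
#' @export
ld_r2 <- function(h1, h2) {
  ok <- !is.na(h1) & !is.na(h2)
  if (sum(ok) < 2L) return(NA_real_)
  x <- h1[ok]; y <- h2[ok]
  p1 <- mean(x); p2 <- mean(y)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) return(NA_real_)
  D <- mean(x * y) - p1 * p2
  D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}

#' Linkage-disequilibrium decay curve
#'
#' Mean r-squared between all intra-contig site pairs at distance
#' `(0, max_dist]`, both sites with MAF >= `maf_min`, binned by distance.
#' Uses haplotype r2 when phased data are available, otherwise squared
#' dosage correlation; the mode is recorded in the `mode` attribute.
#'
#' @param gm A [geno_matrix()] for the group.
#' @param max_dist Maximum pair distance in bp.
#' @param maf_min Minor-allele-frequency floor for both sites.
#' @param bin_bp Distance bin width in bp.
#' @param per_contig Also return per-contig curves (as an attribute).
#' @return data.frame `bin_start`, `bin_end`, `mean_r2`, `n_pairs` covering
#'   `(0, max_dist]`; empty bins have `n_pairs = 0` and `NA` mean.
#' @export
ld_decay <- function(gm, max_dist = 15000, maf_min = 0.05, bin_bp = 1000,
                     per_contig = FALSE) {
  use_hap <- !is.null(gm$hap) && any(!is.na(gm$hap))
  X <- if (use_hap) gm$hap else gm$dos
  mode <- if (use_hap) "haplotype" else "dosage"
  called <- !is.na(gm$dos)
  an <- 2 * colSums(called)
  af <- ifelse(an > 0, colSums(gm$dos, na.rm = TRUE) / an, NA_real_)
  maf <- pmin(af, 1 - af)
  pass <- !is.na(maf) & maf >= maf_min

  nb <- ceiling(max_dist / bin_bp)
  empty <- data.frame(bin_start = (seq_len(nb) - 1L) * bin_bp,
                      bin_end = pmin(seq_len(nb) * bin_bp, max_dist),
                      mean_r2 = NA_real_, n_pairs = 0L)
  acc <- function(idx) {
    sums <- numeric(nb); cnts <- integer(nb)
    pos <- gm$variants$pos[idx]
    o <- order(pos); idx <- idx[o]; pos <- pos[o]
    for (i in seq_along(idx)) {
      hi <- findInterval(pos[i] + max_dist + 0.5, pos)
      if (hi <= i) next
      js <- (i + 1L):hi
      d <- pos[js] - pos[i]
      r2 <- suppressWarnings(
        stats::cor(X[, idx[i]], X[, idx[js], drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      r2 <- as.vector(r2)
      keep <- !is.na(r2) & d > 0
      if (!any(keep)) next
      b <- pmin(ceiling(d[keep] / bin_bp), nb)
      for (u in unique(b)) {
        sums[u] <- sums[u] + sum(r2[keep][b == u])
        cnts[u] <- cnts[u] + sum(b == u)
      }
    }
    out <- empty
    out$mean_r2 <- ifelse(cnts > 0, sums / cnts, NA_real_)
    out$n_pairs <- cnts
    out
  }

  contigs <- unique(gm$variants$contig)
  per <- lapply(contigs, function(ctg)
    acc(which(pass & gm$variants$contig == ctg)))
  names(per) <- contigs
  pooled <- empty
  tot <- Reduce(`+`, lapply(per, function(d)
    cbind(ifelse(is.na(d$mean_r2), 0, d$mean_r2) * d$n_pairs, d$n_pairs)))
  pooled$n_pairs <- as.integer(tot[, 2L])
  pooled$mean_r2 <- ifelse(tot[, 2L] > 0, tot[, 1L] / tot[, 2L], NA_real_)
  attr(pooled, "mode") <- mode
  if (per_contig) attr(pooled, "per_contig") <- per
  pooled
}

#' Greedy LD pruning (plink indep-pairwise style)
#'
#' Scans windows of `window_snps` consecutive SNPs advancing by `step_snps`;
#' within each window, for every pair with r-squared above `r2_max` the
#' later-positioned SNP of the pair is removed. r2 here is the squared
#' dosage correlation. No surviving pair within any scanned window exceeds
#' `r2_max`.
#'
#' @param gm A [geno_matrix()].
#' @param window_snps,step_snps Window length and step in SNP counts.
#' @param r2_max Pruning threshold.
#' @return Integer vector of kept variant indices (ascending).
#' @export
ld_prune <- function(gm, window_snps = 50L, step_snps = 5L, r2_max = 0.5) {
  keep <- rep(TRUE, n_variants(gm))
  for (ctg in unique(gm$variants$contig)) {
    idx <- which(gm$variants$contig == ctg)
    idx <- idx[order(gm$variants$pos[idx])]
    S <- length(idx)
    if (S < 2L) next
    i0 <- 1L
    repeat {
      win <- idx[i0:min(i0 + window_snps - 1L, S)]
      aw <- win[keep[win]]
      if (length(aw) >= 2L) {
        r2 <- suppressWarnings(
          stats::cor(gm$dos[, aw, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        for (i in seq_len(length(aw) - 1L)) {
          if (!keep[aw[i]]) next
          for (j in seq(i + 1L, length(aw))) {
            if (!keep[aw[j]]) next
            if (!is.na(r2[i, j]) && r2[i, j] > r2_max) keep[aw[j]] <- FALSE
          }
        }
      }
      if (i0 + window_snps - 1L >= S) break
      i0 <- i0 + step_snps
    }
  }
  which(keep)
}

#' Principal component analysis of genotypes
#'
#' Patterson scaling: each dosage column is centred by `2 p` and divided by
#' `sqrt(p (1 - p))` with `p` the allele-frequency estimate; missing values
#' become 0 after centring (mean imputation); monomorphic columns are
#' dropped. Coordinates are projections on the top eigenvectors of the
#' sample covariance of the scaled genotypes.
#'
#' @param gm A [geno_matrix()] (ideally LD-pruned) with >= 2 samples.
#' @param n_components Number of PCs returned.
#' @return `list(coords, eigenvalues, prop_var, n_sites)`; eigenvalues are
#'   non-increasing and sum to the total variance of the scaled data.
#' @export
pca_genotypes <- function(gm, n_components = 10L) {
  stopifnot(n_samples(gm) >= 2L)
  D <- gm$dos
  called <- !is.na(D)
  an <- 2 * colSums(called)
  p <- ifelse(an > 0, colSums(D, na.rm = TRUE) / an, NA_real_)
  use <- !is.na(p) & p > 0 & p < 1
  D <- D[, use, drop = FALSE]
  p <- p[use]
  X <- sweep(D, 2L, 2 * p)
  X <- sweep(X, 2L, sqrt(p * (1 - p)), `/`)
  X[is.na(X)] <- 0
  S <- ncol(X)
  C <- tcrossprod(X) / S
  eig <- eigen(C, symmetric = TRUE)
  k <- min(n_components, nrow(C))
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(k)], 0)), k)
  rownames(coords) <- gm$samples
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords, eigenvalues = eig$values,
       prop_var = eig$values / sum(eig$values), n_sites = S)
}
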