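# The three selection-signature scans (pooled heterozygosity ZHp, windowed
# ZFst, window-mean standardized XP-EHH) and the candidate-calling logic:
# empirical P-values, fixed Z thresholds, XP-EHH directionality, scan
# intersection and region merging.

#' Scan configuration
#'
#' Thresholds and window geometry for the selection scans. Defaults: 20 kb
#' windows sliding by 10 kb with at least 10 SNPs per scored window;
#' candidates at `ZHp <= -4`, `ZFst > 3.7`, `|XP-EHH_std| > 2.6`, empirical
#' `P < 0.01`; EHH curves truncated below 0.05 or beyond 1 Mb.
#'
#' @param window_size,step Window geometry in bp.
#' @param min_snps Minimum scored SNPs for a window to enter a scan.
#' @param zhp_max ZHp call threshold (windows at or below are candidates).
#' @param zfst_min,abs_xpehh_min Z thresholds for the two group scans.
#' @param emp_p_max Empirical P-value threshold.
#' @param ehh_cutoff EHH truncation level.
#' @param max_extend_bp Maximum EHH extension from the core, bp.
#' @return List of class `scan_config`.
#' @export
scan_config <- function(window_size = 20000, step = 10000, min_snps = 10L,
                        zhp_max = -4, zfst_min = 3.7, abs_xpehh_min = 2.6,
                        emp_p_max = 0.01, ehh_cutoff = 0.05,
                        max_extend_bp = 1e6) {
  stopifnot(window_size >= step, step > 0, min_snps >= 1L,
            is.finite(zhp_max), is.finite(zfst_min), is.finite(abs_xpehh_min),
            emp_p_max > 0, emp_p_max <= 1, ehh_cutoff >= 0, max_extend_bp > 0)
  structure(list(window_size = window_size, step = step,
                 min_snps = as.integer(min_snps), zhp_max = zhp_max,
                 zfst_min = zfst_min, abs_xpehh_min = abs_xpehh_min,
                 emp_p_max = emp_p_max, ehh_cutoff = ehh_cutoff,
                 max_extend_bp = max_extend_bp),
            class = "scan_config")
}

#' Pooled heterozygosity of a window
#'
#' `Hp = 2 * sum(n_maj) * sum(n_min) / (sum(n_maj) + sum(n_min))^2` where
#' `n_maj`/`n_min` are each SNP's observed major and minor allele counts in
#' the pooled sample. Algebraically bounded in `[0, 0.5]`.
#'
#' @param n_maj,n_min Per-SNP major and minor allele counts.
#' @return Hp value.
#' @export
pooled_heterozygosity <- function(n_maj, n_min) {
  stopifnot(length(n_maj) == length(n_min), all(n_maj >= n_min))
  x <- sum(n_maj); y <- sum(n_min)
  if (x + y == 0) return(NA_real_)
  2 * x * y / (x + y)^2
}

#' Empirical P-values by genome-wide rank
#'
#' Upper tail: `p_i = #\{j : x_j >= x_i\} / N`; lower tail analogous. Tied
#' values share the larger P.
#'
#' @param x Statistic vector (one entry per scored window).
#' @param tail `"upper"` or `"lower"`.
#' @return P-values in `(0, 1]`.
#' @export
empirical_pvalues <- function(x, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  n <- length(x)
  stopifnot(n >= 1L)
  if (tail == "upper") (n + 1L - rank(x, ties.method = "min")) / n
  else rank(x, ties.method = "max") / n
}

#' Pooled-heterozygosity (ZHp) scan
#'
#' Computes window Hp on the pooled sample, standardizes genome-wide over
#' windows meeting `min_snps` (major/minor orientation is per SNP within the
#' pool, not inherited from REF/ALT), and flags candidates with
#' `ZHp <= zhp_max`. The lower-tail empirical P-value is reported alongside.
#'
#' @param gm Pooled [geno_matrix()] (the configured population set).
#' @param windows Windows from [make_windows()].
#' @param cfg A [scan_config()].
#' @return Window table with `n_snps`, `hp`, `zhp`, `emp_p`, `candidate`;
#'   unscored windows (below `min_snps`) carry NA statistics. The
#'   standardization mean/sd are attached as attributes.
#' @export
hp_scan <- function(gm, windows, cfg = scan_config()) {
  called <- !is.na(gm$dos)
  an <- 2 * colSums(called)
  ac <- colSums(gm$dos, na.rm = TRUE)
  nmaj <- pmax(ac, an - ac)
  nmin <- pmin(ac, an - ac)
  wi <- window_site_index(gm, windows)
  windows$n_snps <- vapply(wi, function(ix) sum(an[ix] > 0), 0)
  windows$hp <- vapply(wi, function(ix) {
    ix <- ix[an[ix] > 0]
    if (!length(ix)) return(NA_real_)
    pooled_heterozygosity(nmaj[ix], nmin[ix])
  }, 0)
  scored <- windows$n_snps >= cfg$min_snps & !is.na(windows$hp)
  if (sum(scored) < 2L)
    stop("fewer than 2 scored windows; cannot standardize Hp")
  m <- mean(windows$hp[scored]); s <- stats::sd(windows$hp[scored])
  if (s == 0) stop("all scored windows have identical Hp; cannot standardize")
  windows$zhp <- ifelse(scored, (windows$hp - m) / s, NA_real_)
  windows$emp_p <- NA_real_
  windows$emp_p[scored] <- empirical_pvalues(windows$zhp[scored], "lower")
  windows$candidate <- !is.na(windows$zhp) & windows$zhp <= cfg$zhp_max
  attr(windows, "hp_mean") <- m
  attr(windows, "hp_sd") <- s
  windows
}

#' Extended haplotype homozygosity decay from a core site
#'
#' EHH at distance x is the probability that two random haplotypes are
#' identical over all sites from the core out to x:
#' `sum(choose(n_h, 2)) / choose(n, 2)` over extended-haplotype classes. The
#' curve starts at 1 at distance zero, is refined first by the core site and
#' then site by site outward, and is truncated once it falls below
#' `cutoff`, extends past `max_extend_bp`, or hits the contig end.
#' Haplotypes with missing data are dropped from the span as encountered.
#'
#' @param hap Haplotype matrix (haplotypes x sites, 0/1/NA).
#' @param positions Site positions (bp, ascending).
#' @param core Core site index (column of `hap`).
#' @param direction `"left"` or `"right"` of the core.
#' @param cutoff,max_extend_bp Truncation controls.
#' @return data.frame `distance`, `ehh`; non-increasing in `ehh` for
#'   complete data.
#' @export
ehh <- function(hap, positions, core, direction = c("right", "left"),
                cutoff = 0.05, max_extend_bp = 1e6) {
  direction <- match.arg(direction)
  S <- ncol(hap)
  stopifnot(core >= 1L, core <= S, length(positions) == S)
  sites <- if (direction == "right") core:S else core:1L
  active <- seq_len(nrow(hap))
  grp <- rep(1L, nrow(hap))
  out_d <- 0; out_e <- 1
  for (k in sites) {
    d <- abs(positions[k] - positions[core])
    if (d > max_extend_bp) {
      # flat extension to the truncation boundary
      out_d <- c(out_d, max_extend_bp); out_e <- c(out_e, out_e[length(out_e)])
      break
    }
    a <- hap[active, k]
    drop <- is.na(a)
    if (any(drop)) {
      active <- active[!drop]
      a <- a[!drop]
    }
    n <- length(active)
    if (n < 2L) break
    key <- grp[active] * 2L + a
    grp[active] <- match(key, unique(key))
    tab <- tabulate(grp[active])
    e <- sum(tab * (tab - 1) / 2) / (n * (n - 1) / 2)
    out_d <- c(out_d, d); out_e <- c(out_e, e)
    if (e < cutoff) break
  }
  data.frame(distance = out_d, ehh = out_e)
}

# Pair-based EHH engine used by xpehh_scan(). EHH over a span equals the
# fraction of haplotype pairs identical on it, and a pair stops contributing
# exactly at its first mismatch away from the core; precomputing that first
# mismatch position for every (pair, core) makes the genome scan linear in
# pairs instead of revisiting sites per core. Equivalent to the site-wise
# ehh()/ihh() route (asserted in the test suite).
pair_drop_positions <- function(H, pos) {
  n <- nrow(H)
  S <- ncol(H)
  pr <- utils::combn(n, 2L)
  P <- ncol(pr)
  right <- matrix(Inf, P, S)
  left <- matrix(-Inf, P, S)
  cores <- seq_len(S)
  for (p in seq_len(P)) {
    m <- which(H[pr[1L, p], ] != H[pr[2L, p], ])
    if (!length(m)) next
    ir <- findInterval(cores - 0.5, m) + 1L  # first mismatch at/after core
    ok <- ir <= length(m)
    right[p, ok] <- pos[m[ir[ok]]]
    il <- findInterval(cores, m)             # last mismatch at/before core
    ok <- il >= 1L
    left[p, ok] <- pos[m[il[ok]]]
  }
  list(right = right, left = left, n_pairs = P)
}

# One-sided iHH from pair drop distances: EHH evaluated on the SNP distance
# grid `site_d` (ascending, starting at 0 for the core, capped at the
# truncation boundary), trapezoid between consecutive evaluation points,
# truncated at the first point below `cutoff`.
ihh_from_drops <- function(d, n_pairs, site_d, cutoff) {
  if (length(site_d) < 2L) return(0)
  cnt <- findInterval(site_d, sort(d[is.finite(d)]))
  earr <- c(1, (n_pairs - cnt) / n_pairs)
  darr <- c(0, site_d)
  stop_k <- which(earr < cutoff)[1L]
  if (!is.na(stop_k)) {
    darr <- darr[seq_len(stop_k)]
    earr <- earr[seq_len(stop_k)]
  }
  sum(diff(darr) * (earr[-1L] + earr[-length(earr)]) / 2)
}

#' Integrated EHH
#'
#' Trapezoidal integral of the EHH decay over physical distance on both
#' sides of the core, summed. Units: bp x EHH.
#'
#' @param curve_left,curve_right Curves from [ehh()] (either may be NULL).
#' @return iHH value.
#' @export
ihh <- function(curve_left, curve_right = NULL) {
  trapz1 <- function(cv) {
    if (is.null(cv) || nrow(cv) < 2L) return(0)
    sum(diff(cv$distance) * (cv$ehh[-1L] + cv$ehh[-nrow(cv)]) / 2)
  }
  trapz1(curve_left) + trapz1(curve_right)
}

#' Cross-population EHH statistic at one SNP
#'
#' `XP-EHH = ln(iHH_A / iHH_B)` with A the first-listed group; positive
#' values indicate longer haplotype homozygosity (recent selection) in A.
#' Antisymmetric under swapping the groups.
#'
#' @param hapsA,hapsB Haplotype matrices over the same sites.
#' @param positions Site positions (bp).
#' @param core Core site index.
#' @param cutoff,max_extend_bp Passed to [ehh()].
#' @return Raw XP-EHH value, or NA when either side is unscoreable.
#' @export
xpehh_site <- function(hapsA, hapsB, positions, core, cutoff = 0.05,
                       max_extend_bp = 1e6) {
  iA <- ihh(ehh(hapsA, positions, core, "left", cutoff, max_extend_bp),
            ehh(hapsA, positions, core, "right", cutoff, max_extend_bp))
  iB <- ihh(ehh(hapsB, positions, core, "left", cutoff, max_extend_bp),
            ehh(hapsB, positions, core, "right", cutoff, max_extend_bp))
  if (iA <= 0 || iB <= 0) return(NA_real_)
  log(iA / iB)
}

#' XP-EHH scan
#'
#' Scores every SNP with complete (no-missing) phased genotypes in both
#' groups, standardizes the raw scores genome-wide, and aggregates per
#' window: mean standardized XP-EHH, mean absolute standardized XP-EHH, and
#' counts of positive/negative raw scores (zero scores count as neither).
#' The empirical P ranks windows on the mean absolute standardized score.
#'
#' @param gmA,gmB Phased per-group [geno_matrix()] objects over the same
#'   variants; group A first (sign convention).
#' @param windows Windows from [make_windows()].
#' @param cfg A [scan_config()].
#' @return Window table with `n_snps`, `mean_xpehh_std`,
#'   `mean_abs_xpehh_std`, `n_pos`, `n_neg`, `emp_p`, `candidate`,
#'   `direction`. Per-SNP scores are attached as attribute `snp_scores`.
#' @export
xpehh_scan <- function(gmA, gmB, windows, cfg = scan_config()) {
  stopifnot(n_variants(gmA) == n_variants(gmB))
  if (is.null(gmA$hap) || is.null(gmB$hap))
    stop("XP-EHH requires phased haplotypes in both groups")
  okA <- colSums(is.na(gmA$hap)) == 0L
  okB <- colSums(is.na(gmB$hap)) == 0L
  use <- okA & okB & gmA$variants$biallelic
  if (!any(use)) stop("no SNP with complete phased genotypes in both groups")

  raw_all <- rep(NA_real_, n_variants(gmA))
  for (ctg in unique(gmA$variants$contig)) {
    idx <- which(use & gmA$variants$contig == ctg)
    if (!length(idx)) next
    o <- order(gmA$variants$pos[idx])
    idx <- idx[o]
    pos <- gmA$variants$pos[idx] - 1L
    HA <- gmA$hap[, idx, drop = FALSE]
    HB <- gmB$hap[, idx, drop = FALSE]
    dropsA <- pair_drop_positions(HA, pos)
    dropsB <- pair_drop_positions(HB, pos)
    S <- length(idx)
    grid <- function(dists) {  # cap the site grid at the extension limit
      if (dists[length(dists)] > cfg$max_extend_bp)
        c(dists[dists <= cfg$max_extend_bp], cfg$max_extend_bp)
      else dists
    }
    ihh_group <- function(drops, k) {
      ihh_from_drops(drops$right[, k] - pos[k], drops$n_pairs,
                     grid(pos[k:S] - pos[k]), cfg$ehh_cutoff) +
        ihh_from_drops(pos[k] - drops$left[, k], drops$n_pairs,
                       grid(pos[k] - pos[k:1L]), cfg$ehh_cutoff)
    }
    raw_all[idx] <- vapply(seq_len(S), function(k) {
      iA <- ihh_group(dropsA, k)
      iB <- ihh_group(dropsB, k)
      if (iA <= 0 || iB <= 0) return(NA_real_)
      log(iA / iB)
    }, 0)
  }
  scored_snp <- !is.na(raw_all)
  if (sum(scored_snp) < 2L)
    stop("cannot standardize XP-EHH (fewer than 2 scored SNPs)")
  m <- mean(raw_all[scored_snp]); s <- stats::sd(raw_all[scored_snp])
  # identical panels give a constant (all-zero) score vector; its
  # standardized form is taken as zero rather than 0/0
  std <- if (s == 0) rep(0, length(raw_all)) else (raw_all - m) / s

  wi <- window_site_index(gmA, windows)
  agg <- function(f) vapply(wi, function(ix) {
    ix <- ix[scored_snp[ix]]
    if (!length(ix)) return(NA_real_)
    f(ix)
  }, 0)
  windows$n_snps <- vapply(wi, function(ix) sum(scored_snp[ix]), 0)
  windows$mean_xpehh_std <- agg(function(ix) mean(std[ix]))
  windows$mean_abs_xpehh_std <- agg(function(ix) mean(abs(std[ix])))
  windows$n_pos <- vapply(wi, function(ix) sum(raw_all[ix] > 0, na.rm = TRUE), 0)
  windows$n_neg <- vapply(wi, function(ix) sum(raw_all[ix] < 0, na.rm = TRUE), 0)
  scored <- windows$n_snps >= cfg$min_snps
  windows$emp_p <- NA_real_
  if (any(scored))
    windows$emp_p[scored] <-
      empirical_pvalues(windows$mean_abs_xpehh_std[scored], "upper")
  windows$candidate <- scored &
    !is.na(windows$mean_abs_xpehh_std) &
    windows$mean_abs_xpehh_std > cfg$abs_xpehh_min &
    !is.na(windows$emp_p) & windows$emp_p < cfg$emp_p_max &
    (windows$n_pos == 0 | windows$n_neg == 0)
  windows$direction <- ifelse(!windows$candidate, NA_character_,
                        ifelse(windows$n_pos > 0, "groupA",
                        ifelse(windows$n_neg > 0, "groupB", NA_character_)))
  attr(windows, "xpehh_mean") <- m
  attr(windows, "xpehh_sd") <- s
  attr(windows, "snp_scores") <-
    data.frame(contig = gmA$variants$contig[scored_snp],
               pos = gmA$variants$pos[scored_snp],
               xpehh_raw = raw_all[scored_snp],
               xpehh_std = std[scored_snp])
  windows
}

#' Windowed ZFst scan
#'
#' Windowed weighted Weir-Cockerham Fst standardized genome-wide over scored
#' windows; candidates need `ZFst > zfst_min` and empirical `P < emp_p_max`.
#'
#' @inheritParams xpehh_scan
#' @return Window table with `n_snps`, `fst`, `zfst`, `emp_p`, `candidate`.
#' @export
fst_scan <- function(gmA, gmB, windows, cfg = scan_config()) {
  wt <- windowed_weighted_fst(gmA, gmB, windows, min_sites = cfg$min_snps)
  scored <- !is.na(wt$fst) & wt$n_snps >= cfg$min_snps
  if (sum(scored) < 2L)
    stop("fewer than 2 scored windows; cannot standardize Fst")
  m <- mean(wt$fst[scored]); s <- stats::sd(wt$fst[scored])
  if (s == 0) stop("all scored windows have identical Fst; cannot standardize")
  wt$zfst <- ifelse(scored, (wt$fst - m) / s, NA_real_)
  wt$emp_p <- NA_real_
  wt$emp_p[scored] <- empirical_pvalues(wt$zfst[scored], "upper")
  wt$candidate <- !is.na(wt$zfst) & wt$zfst > cfg$zfst_min &
    !is.na(wt$emp_p) & wt$emp_p < cfg$emp_p_max
  attr(wt, "fst_mean") <- m
  attr(wt, "fst_sd") <- s
  wt
}

#' Apply the candidate-calling predicate of a scan
#'
#' Recomputes the candidate flag from a scan table's columns: Hp windows at
#' `ZHp <= zhp_max`; Fst windows at `ZFst > zfst_min` with empirical
#' `P < emp_p_max`; XP-EHH windows at `mean |XP-EHH_std| > abs_xpehh_min`
#' with empirical `P < emp_p_max` and all scored SNPs sharing one sign.
#'
#' @param scan A scan table from [hp_scan()], [fst_scan()] or [xpehh_scan()].
#' @param cfg A [scan_config()].
#' @param type `"hp"`, `"fst"` or `"xpehh"`.
#' @return Logical candidate vector.
#' @export
call_candidates <- function(scan, cfg = scan_config(),
                            type = c("hp", "fst", "xpehh")) {
  type <- match.arg(type)
  switch(type,
    hp = !is.na(scan$zhp) & scan$zhp <= cfg$zhp_max,
    fst = !is.na(scan$zfst) & scan$zfst > cfg$zfst_min &
      !is.na(scan$emp_p) & scan$emp_p < cfg$emp_p_max,
    xpehh = !is.na(scan$mean_abs_xpehh_std) &
      scan$mean_abs_xpehh_std > cfg$abs_xpehh_min &
      !is.na(scan$emp_p) & scan$emp_p < cfg$emp_p_max &
      (scan$n_pos == 0 | scan$n_neg == 0))
}

#' Intersect Fst and XP-EHH candidate windows
#'
#' Windows (same grid) flagged as candidates by both scans; the selection
#' direction is carried from the XP-EHH side.
#'
#' @param fst_scan_tab,xpehh_scan_tab Scan tables over the same windows.
#' @return data.frame of common candidate windows with `direction`, `zfst`,
#'   `mean_xpehh_std`, `mean_abs_xpehh_std`.
#' @export
intersect_candidates <- function(fst_scan_tab, xpehh_scan_tab) {
  key_f <- paste(fst_scan_tab$contig, fst_scan_tab$start, fst_scan_tab$end)
  key_x <- paste(xpehh_scan_tab$contig, xpehh_scan_tab$start,
                 xpehh_scan_tab$end)
  stopifnot(identical(sort(key_f), sort(key_x)))
  xf <- match(key_f, key_x)
  both <- fst_scan_tab$candidate & xpehh_scan_tab$candidate[xf]
  out <- fst_scan_tab[both, c("contig", "start", "end", "fst", "zfst",
                              "emp_p")]
  names(out)[names(out) == "emp_p"] <- "emp_p_fst"
  xs <- xpehh_scan_tab[xf[both], , drop = FALSE]
  out$mean_xpehh_std <- xs$mean_xpehh_std
  out$mean_abs_xpehh_std <- xs$mean_abs_xpehh_std
  out$emp_p_xpehh <- xs$emp_p
  out$direction <- xs$direction
  rownames(out) <- NULL
  out
}

#' Common sweep regions of the Fst and XP-EHH scans
#'
#' Candidate windows of each scan are first merged into candidate regions
#' ([merge_regions()]); a putative sweep region is then the overlap of an
#' Fst candidate region with an XP-EHH candidate region (common windows are
#' the special case of identical grid windows). The selection direction is
#' carried from the XP-EHH side; the peak ZFst and peak window-mean
#' standardized XP-EHH of the contributing regions are reported.
#'
#' @param fst_scan_tab,xpehh_scan_tab Scan tables over the same windows.
#' @return data.frame `contig`, `start`, `end`, `direction`, `peak_zfst`,
#'   `peak_xpehh_std`, sorted and non-overlapping within a direction.
#' @export
common_regions <- function(fst_scan_tab, xpehh_scan_tab) {
  empty <- data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      peak_zfst = numeric(0), peak_xpehh_std = numeric(0))
  rf <- merge_regions(fst_scan_tab[fst_scan_tab$candidate, , drop = FALSE],
                      stat_col = "zfst")
  rx <- merge_regions(xpehh_scan_tab[xpehh_scan_tab$candidate, , drop = FALSE],
                      stat_col = "mean_xpehh_std")
  if (nrow(rf) == 0L || nrow(rx) == 0L) return(empty)
  out <- empty
  for (i in seq_len(nrow(rf))) for (j in seq_len(nrow(rx))) {
    if (rf$contig[i] != rx$contig[j]) next
    s <- max(rf$start[i], rx$start[j])
    e <- min(rf$end[i], rx$end[j])
    if (s >= e) next
    out <- rbind(out, data.frame(contig = rf$contig[i], start = s, end = e,
                                 direction = rx$direction[j],
                                 peak_zfst = rf$peak[i],
                                 peak_xpehh_std = rx$peak[j]))
  }
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Merge candidate windows into sweep regions
#'
#' bedtools-merge semantics on 0-based half-open intervals: overlapping or
#' book-ended windows on the same contig with the same direction merge into
#' one region (windows without a direction merge among themselves). The peak
#' statistic (largest absolute value of `stat_col`) is recorded.
#'
#' @param cands data.frame with `contig`, `start`, `end`, optional
#'   `direction` and a statistic column.
#' @param stat_col Name of the per-window statistic used for the peak.
#' @return data.frame `contig`, `start`, `end`, `direction`, `n_windows`,
#'   `peak` -- non-overlapping within each direction class, sorted.
#' @export
merge_regions <- function(cands, stat_col = NULL) {
  if (nrow(cands) == 0L)
    return(data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      n_windows = integer(0), peak = numeric(0)))
  dir <- if ("direction" %in% names(cands)) as.character(cands$direction)
         else rep(NA_character_, nrow(cands))
  dirkey <- ifelse(is.na(dir), ".", dir)
  stat <- if (!is.null(stat_col)) cands[[stat_col]] else rep(NA_real_,
                                                             nrow(cands))
  o <- order(cands$contig, dirkey, cands$start, cands$end)
  cands <- cands[o, ]; dir <- dir[o]; dirkey <- dirkey[o]; stat <- stat[o]
  out <- list()
  cur <- NULL
  flush <- function(cur) do.call(rbind, list(cur))
  for (i in seq_len(nrow(cands))) {
    row <- cands[i, ]
    if (!is.null(cur) && cur$contig == row$contig &&
        cur$dirkey == dirkey[i] && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
      cur$n_windows <- cur$n_windows + 1L
      if (!is.na(stat[i]) &&
          (is.na(cur$peak) || abs(stat[i]) > abs(cur$peak)))
        cur$peak <- stat[i]
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- list(contig = row$contig, start = row$start, end = row$end,
                  direction = dir[i], dirkey = dirkey[i], n_windows = 1L,
                  peak = stat[i])
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, lapply(out, function(u)
    data.frame(contig = u$contig, start = u$start, end = u$end,
               direction = u$direction, n_windows = u$n_windows,
               peak = u$peak)))
  res <- res[order(res$contig, res$start, res$end), ]
  rownames(res) <- NULL
  res
}
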