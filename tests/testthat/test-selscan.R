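# Pooled heterozygosity, EHH/iHH/XP-EHH, empirical P-values, candidate
# calling, intersection and region merging.

test_that("pooled heterozygosity: bounds and direct arithmetic", {
  expect_equal(pooled_heterozygosity(c(10, 8, 12), c(0, 0, 0)), 0)
  expect_equal(pooled_heterozygosity(c(10, 10), c(10, 10)), 0.5)
  expect_equal(pooled_heterozygosity(30, 10), 2 * 30 * 10 / 40^2)
  # algebraic bound 2xy/(x+y)^2 <= 1/2 on random counts
  set.seed(51)
  for (i in 1:50) {
    nm <- sample(1:50, 5, replace = TRUE)
    nn <- pmin(nm, sample(0:50, 5, replace = TRUE))
    hp <- pooled_heterozygosity(nm, nn)
    expect_gte(hp, 0); expect_lte(hp, 0.5)
  }
})

test_that("hp_scan standardizes genome-wide and flags ZHp <= threshold", {
  set.seed(52)
  gm <- random_panel(10, 600, seed = 52,
                     positions = sort(sample(1:99999, 600)))
  gm$contig_lengths <- c(chr1 = 1e5)
  w <- make_windows(c(chr1 = 1e5))
  out <- hp_scan(gm, w, scan_config(min_snps = 5))
  z <- out$zhp[!is.na(out$zhp)]
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  # degenerate: identical Hp in all windows cannot be standardized
  gmc <- gm_from_haps(matrix(rep(c(0L, 1L), 300), 2, 300),
                      positions = sort(sample(1:39999, 300)))
  gmc$contig_lengths <- c(chr1 = 4e4)
  expect_error(hp_scan(gmc, make_windows(c(chr1 = 4e4)),
                       scan_config(min_snps = 2)),
               "identical Hp")
})

test_that("hp_scan finds a planted low-diversity window", {
  set.seed(53)
  hits <- 0
  for (rep in 1:5) {
    pos <- sort(sample(1:199999, 1200))
    hap <- sapply(runif(1200, .1, .9), function(p) rbinom(20, 1, p))
    hap <- matrix(as.integer(hap), 20, 1200)
    # wipe variation in [100kb, 120kb)
    inwin <- pos > 1e5 & pos <= 1.2e5
    hap[, inwin] <- rep(hap[1, inwin], each = 20)
    gm <- gm_from_haps(hap, positions = pos)
    gm$contig_lengths <- c(chr1 = 2e5)
    out <- hp_scan(gm, make_windows(c(chr1 = 2e5)), scan_config())
    if (out$start[which.min(out$zhp)] %in% c(1e5, 1.1e5)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("EHH: identical, all-distinct, and the 4-haplotype worked table", {
  pos <- c(0, 100, 250)
  # all identical -> EHH stays 1 to the end of the span
  h <- matrix(1L, 5, 3)
  cv <- ehh(h, pos, 1, "right")
  expect_true(all(cv$ehh == 1))
  expect_equal(max(cv$distance), 250)
  # all haplotypes distinct over the adjacent sites -> EHH 0 there
  h2 <- cbind(rep(0L, 4), c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  cv2 <- ehh(h2, c(0, 50, 120), 1, "right")
  expect_equal(cv2$ehh[cv2$distance == 120], 0)
  # haplotypes AAB, AAB, ABA, BBB: after the core site classes are (3, 1)
  h3 <- rbind(c(0L, 0L, 1L), c(0L, 0L, 1L), c(0L, 1L, 0L), c(1L, 1L, 1L))
  cv3 <- ehh(h3, c(0, 10, 20), 1, "right")
  expect_equal(cv3$ehh[1:2], c(1, (choose(3, 2) + choose(1, 2)) / choose(4, 2)))
  expect_equal(cv3$ehh[2], 0.5)
  # monotone non-increasing on random complete panels
  set.seed(54)
  for (i in 1:20) {
    hp <- matrix(rbinom(8 * 30, 1, 0.5), 8, 30)
    p <- sort(sample(1:5000, 30))
    core <- sample(30, 1)
    for (dir in c("left", "right")) {
      cv <- ehh(hp, p, core, dir, cutoff = 0)
      expect_true(all(diff(cv$ehh) <= 1e-12))
      expect_equal(cv$ehh[1], 1)
    }
  }
})

test_that("iHH: rectangle, triangle, additivity, quadrature oracle", {
  rect <- data.frame(distance = c(0, 300), ehh = c(1, 1))
  expect_equal(ihh(rect, rect), 600)
  tri <- data.frame(distance = c(0, 200), ehh = c(1, 0))
  zero <- data.frame(distance = 0, ehh = 1)
  expect_equal(ihh(tri, zero), 100)
  # additive over abutting segments
  seg1 <- data.frame(distance = c(0, 50, 100), ehh = c(1, .8, .6))
  seg2a <- data.frame(distance = c(0, 50), ehh = c(1, .8))
  expect_equal(ihh(seg1, NULL),
               ihh(seg2a, NULL) + sum(diff(c(50, 100)) * (.8 + .6) / 2))
  # random curves against pracma::trapz
  skip_if_not_installed("pracma")
  set.seed(55)
  for (i in 1:20) {
    d <- sort(runif(15, 0, 1e4))
    e <- sort(runif(15, 0, 1), decreasing = TRUE)
    cv <- data.frame(distance = c(0, d), ehh = c(1, e))
    expect_equal(ihh(cv, NULL), pracma::trapz(cv$distance, cv$ehh),
                 tolerance = 1e-9)
  }
})

test_that("XP-EHH: zero for identical panels, sign, antisymmetry", {
  set.seed(56)
  h <- matrix(rbinom(10 * 40, 1, 0.5), 10, 40)
  p <- sort(sample(1:20000, 40))
  expect_equal(xpehh_site(h, h, p, 20), 0)
  # homogeneous A panel vs maximally diverse B panel -> positive
  hA <- matrix(rep(rbinom(40, 1, .5), each = 6), 6, 40)
  hB <- matrix(rbinom(6 * 40, 1, 0.5), 6, 40)
  expect_gt(xpehh_site(hA, hB, p, 20), 0)
  # antisymmetry on random panels
  for (i in 1:25) {
    hA <- matrix(rbinom(8 * 30, 1, runif(1, .3, .7)), 8, 30)
    hB <- matrix(rbinom(8 * 30, 1, runif(1, .3, .7)), 8, 30)
    pp <- sort(sample(1:9999, 30))
    core <- sample(30, 1)
    ab <- xpehh_site(hA, hB, pp, core)
    ba <- xpehh_site(hB, hA, pp, core)
    if (!is.na(ab)) expect_equal(ab, -ba, tolerance = 1e-12)
  }
})

test_that("xpehh_scan: A = B gives zero scores; standardization identity;
           pair engine equals the site-wise ehh/ihh route", {
  gmA <- random_panel(6, 150, seed = 57,
                      positions = sort(sample(1:49999, 150)))
  gmA$contig_lengths <- c(chr1 = 5e4)
  gmB <- gmA
  w <- make_windows(c(chr1 = 5e4))
  cfg <- scan_config(min_snps = 3)
  out0 <- xpehh_scan(gmA, gmB, w, cfg)
  snp0 <- attr(out0, "snp_scores")
  expect_true(all(snp0$xpehh_raw == 0))
  expect_equal(sum(out0$candidate), 0)
  # distinct panels: per-SNP standardized scores have mean 0 sd 1
  gmB2 <- random_panel(6, 150, seed = 58, positions = gmA$variants$pos)
  out <- xpehh_scan(gmA, gmB2, w, cfg)
  snp <- attr(out, "snp_scores")
  expect_equal(mean(snp$xpehh_std), 0, tolerance = 1e-9)
  expect_equal(sd(snp$xpehh_std), 1, tolerance = 1e-9)
  # n_pos + n_neg accounting
  expect_true(all(out$n_pos + out$n_neg <= out$n_snps, na.rm = TRUE))
  # cross-check the pair-based genome engine against ehh()/ihh() per SNP
  idx <- order(gmA$variants$pos)
  pos0 <- gmA$variants$pos[idx] - 1L
  HA <- gmA$hap[, idx]; HB <- gmB2$hap[, idx]
  set.seed(59)
  for (k in sort(sample(length(idx), 12))) {
    iA <- ihh(ehh(HA, pos0, k, "left"), ehh(HA, pos0, k, "right"))
    iB <- ihh(ehh(HB, pos0, k, "left"), ehh(HB, pos0, k, "right"))
    expect_equal(snp$xpehh_raw[k], log(iA / iB), tolerance = 1e-12)
  }
  # group-swap antisymmetry at window level
  out_sw <- xpehh_scan(gmB2, gmA, w, cfg)
  expect_equal(out$mean_xpehh_std, -out_sw$mean_xpehh_std, tolerance = 1e-9)
  expect_equal(out$mean_abs_xpehh_std, out_sw$mean_abs_xpehh_std,
               tolerance = 1e-9)
})

test_that("fst_scan standardization and a planted fixed-difference window", {
  set.seed(60)
  pos <- sort(sample(1:199999, 900))
  mkhap <- function() {
    h <- sapply(runif(900, .2, .8), function(p) rbinom(16, 1, p))
    matrix(as.integer(h), 16, 900)
  }
  hA <- mkhap(); hB <- mkhap()
  inwin <- pos > 1e5 & pos <= 1.2e5
  hA[, inwin] <- 0L; hB[, inwin] <- 1L
  gmA <- gm_from_haps(hA, positions = pos); gmB <- gm_from_haps(hB, positions = pos)
  gmA$contig_lengths <- gmB$contig_lengths <- c(chr1 = 2e5)
  w <- make_windows(c(chr1 = 2e5))
  out <- fst_scan(gmA, gmB, w, scan_config())
  z <- out$zfst[!is.na(out$zfst)]
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_true(out$start[which.max(out$zfst)] %in% c(1e5, 1.1e5))
  # identical groups -> no candidate
  out_same <- fst_scan(gmA, gmA, w, scan_config())
  expect_equal(sum(out_same$candidate), 0)
})

test_that("empirical P-values: rank properties and ties", {
  x <- c(5, 3, 8, 1, 9)
  p <- empirical_pvalues(x, "upper")
  expect_equal(p[x == 9], 1 / 5)
  expect_equal(p[x == 1], 1)
  expect_equal(empirical_pvalues(rep(2, 7), "upper"), rep(1, 7))
  expect_equal(empirical_pvalues(rep(2, 7), "lower"), rep(1, 7))
  set.seed(61)
  x <- rnorm(500)
  p <- empirical_pvalues(x, "upper")
  # with distinct values, ranks 1..k have p = k/N; strictly below 0.01
  # leaves the top 4 of 500 (rank 5 sits exactly at 0.01)
  expect_equal(sum(p < 0.01), sum(seq_len(500) / 500 < 0.01))
  expect_equal(sort(p)[1], 1 / 500)
  pl <- empirical_pvalues(x, "lower")
  expect_equal(pl[which.min(x)], 1 / 500)
  # upper+lower relationship on distinct values
  expect_true(all(abs(p + pl - 1 - 1 / 500) < 1e-12))
})

test_that("candidate calling: boundaries, directionality, predicate oracle", {
  cfg <- scan_config()
  # ZHp boundary: exactly -4 is called (<=)
  hp_tab <- data.frame(zhp = c(-4, -3.999, -5, NA))
  expect_equal(call_candidates(hp_tab, cfg, "hp"), c(TRUE, FALSE, TRUE, FALSE))
  # mixed-sign XP-EHH window rejected even above threshold
  xp_tab <- data.frame(mean_abs_xpehh_std = c(3, 3, 3),
                       emp_p = c(0.005, 0.005, 0.005),
                       n_pos = c(4, 0, 2), n_neg = c(0, 4, 2))
  expect_equal(call_candidates(xp_tab, cfg, "xpehh"), c(TRUE, TRUE, FALSE))
  # randomized predicate oracle across the three scans
  set.seed(62)
  tab <- data.frame(zhp = rnorm(200, 0, 2), zfst = rnorm(200, 0, 2),
                    emp_p = runif(200), mean_abs_xpehh_std = abs(rnorm(200, 0, 2)),
                    n_pos = rpois(200, 1), n_neg = rpois(200, 1))
  expect_equal(call_candidates(tab, cfg, "fst"),
               tab$zfst > 3.7 & tab$emp_p < 0.01)
  expect_equal(call_candidates(tab, cfg, "xpehh"),
               tab$mean_abs_xpehh_std > 2.6 & tab$emp_p < 0.01 &
                 (tab$n_pos == 0 | tab$n_neg == 0))
})

test_that("intersect_candidates equals the set-intersection oracle", {
  w <- make_windows(c(chr1 = 3e5))
  set.seed(63)
  f <- w; f$fst <- runif(nrow(w)); f$zfst <- rnorm(nrow(w))
  f$emp_p <- runif(nrow(w)); f$candidate <- runif(nrow(w)) < 0.3
  x <- w; x$mean_xpehh_std <- rnorm(nrow(w))
  x$mean_abs_xpehh_std <- abs(x$mean_xpehh_std)
  x$emp_p <- runif(nrow(w)); x$candidate <- runif(nrow(w)) < 0.3
  x$n_pos <- 1; x$n_neg <- 0
  x$direction <- ifelse(x$candidate, "groupA", NA)
  common <- intersect_candidates(f, x)
  oracle <- which(f$candidate & x$candidate)
  expect_equal(common$start, w$start[oracle])
  expect_true(all(common$direction == "groupA"))
  # disjoint and identical sets
  x2 <- x; x2$candidate <- !f$candidate & x$candidate
  expect_equal(nrow(intersect_candidates(f, x2)),
               sum(f$candidate & x2$candidate))
})

test_that("merge_regions: bedtools semantics and sweep-line oracle", {
  cands <- data.frame(contig = "chr1", start = c(0, 10000), end = c(20000, 30000))
  out <- merge_regions(cands)
  expect_equal(out[, c("start", "end")], data.frame(start = 0, end = 30000))
  # book-ended intervals merge; separated ones do not
  cands2 <- data.frame(contig = "chr1", start = c(0, 20000, 50000),
                       end = c(20000, 30000, 60000))
  out2 <- merge_regions(cands2)
  expect_equal(out2$start, c(0, 50000))
  expect_equal(out2$end, c(30000, 60000))
  # direction classes never merge together
  cands3 <- data.frame(contig = "chr1", start = c(0, 10000),
                       end = c(20000, 30000),
                       direction = c("groupA", "groupB"))
  expect_equal(nrow(merge_regions(cands3)), 2L)
  # randomized: equals sweep-line oracle and GenomicRanges::reduce
  set.seed(64)
  for (i in 1:10) {
    n <- sample(3:25, 1)
    st <- sample(seq(0, 1e5, 5000), n, replace = TRUE)
    df <- data.frame(contig = sample(c("c1", "c2"), n, replace = TRUE),
                     start = st, end = st + sample(c(10000, 20000), n, TRUE))
    df <- df[!duplicated(df), ]
    got <- merge_regions(df)
    ora <- oracle_merge(df)
    expect_equal(got$start, ora$start)
    expect_equal(got$end, ora$end)
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      factor(df$contig, levels = sort(unique(df$contig))),
      IRanges::IRanges(df$start + 1, df$end)))
    gr <- GenomicRanges::sort(gr)
    expect_equal(got$start, GenomicRanges::start(gr) - 1)
    expect_equal(got$end, GenomicRanges::end(gr))
  }
  # peak statistic carries the largest |value|
  cands4 <- data.frame(contig = "chr1", start = c(0, 10000), end = c(20000, 30000),
                       zfst = c(4.2, 5.1))
  expect_equal(merge_regions(cands4, stat_col = "zfst")$peak, 5.1)
})
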