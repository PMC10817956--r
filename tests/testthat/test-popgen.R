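# Window construction, diversity, Weir-Cockerham Fst, LD and PCA.

test_that("make_windows follows the sliding-truncation geometry", {
  w <- make_windows(c(chr1 = 50000))
  expect_equal(nrow(w), 5L)
  expect_equal(w$start, c(0, 10000, 20000, 30000, 40000))
  expect_equal(w$end, c(20000, 30000, 40000, 50000, 50000))
  w2 <- make_windows(c(chr1 = 15000))
  expect_equal(w2$start, c(0, 10000))
  expect_equal(w2$end, c(15000, 15000))
  w3 <- make_windows(c(chr1 = 8000))
  expect_equal(nrow(w3), 1L)
  expect_error(make_windows(c(chr1 = 5e4), size = 100, step = 200))
})

test_that("nucleotide diversity matches the direct arithmetic and the
           brute-force pairwise oracle", {
  # one site, 2 samples, allele counts (2,2) in a 20 kb window
  hap <- matrix(c(0L, 0L, 1L, 1L), 4, 1)
  gm <- gm_from_haps(hap, positions = 100L, contig_len = 20000)
  w <- data.frame(contig = "chr1", start = 0, end = 20000)
  out <- nucleotide_diversity(gm, w)
  expect_equal(out$pi, (2 * 2 / choose(4, 2)) / 20000)
  # windows with no segregating site
  gm0 <- gm_from_haps(matrix(0L, 4, 2), positions = c(100L, 30000L),
                      contig_len = 40000)
  out0 <- nucleotide_diversity(gm0, make_windows(c(chr1 = 40000)))
  expect_true(all(out0$pi == 0))
  # random panels against the brute-force oracle
  for (seed in 1:3) {
    gm <- random_panel(6, 40, seed = seed,
                       positions = sort(sample(1:19999, 40)))
    gm$contig_lengths <- c(chr1 = 20000)
    w <- make_windows(c(chr1 = 20000))
    out <- nucleotide_diversity(gm, w)
    for (k in seq_len(nrow(w)))
      expect_equal(out$pi[k],
                   oracle_pi(gm$hap, gm$variants$pos, w$start[k], w$end[k]),
                   tolerance = 1e-12)
  }
  # pi scales with the window span for identical variant content
  gm$contig_lengths <- c(chr1 = 40000)
  wbig <- data.frame(contig = "chr1", start = 0, end = 40000)
  wsmall <- data.frame(contig = "chr1", start = 0, end = 20000)
  expect_equal(nucleotide_diversity(gm, wbig)$pi,
               nucleotide_diversity(gm, wsmall)$pi / 2)
})

test_that("inbreeding F: fully homozygous sample and random-mating mean", {
  set.seed(9)
  hap <- sapply(runif(60, 0.2, 0.8), function(p) rbinom(20, 1, p))
  hap <- matrix(as.integer(hap), 20, 60)
  # make sample 1 homozygous everywhere
  hap[2, ] <- hap[1, ]
  gm <- gm_from_haps(hap)
  fh <- inbreeding_f(gm)
  expect_equal(fh$f[1], 1, tolerance = 1e-12)
  expect_equal(fh$o_hom[1], fh$n_sites[1])
  # a simulated random-mating population has mean F near 0
  tr <- cached_sim("default1", wf_simulate(sim_config(seed = 5)))
  gmp <- gm_from_haps(tr$haps$pop1, positions = tr$positions + 1L)
  fh2 <- inbreeding_f(gmp)
  expect_lt(abs(mean(fh2$f)), 0.1)
  # determinism
  expect_identical(fh2, inbreeding_f(gmp))
})

test_that("Weir-Cockerham site components: fixed difference, identity and
           the independent textbook oracle", {
  full <- wc_fst_components(c(10, 0, 0), c(0, 0, 10))
  expect_equal(full$fst, 1)
  same <- wc_fst_components(c(3, 4, 3), c(3, 4, 3))
  expect_lte(same$a, 0)
  expect_lte(same$fst, 0)
  mono <- wc_fst_components(c(10, 0, 0), c(8, 0, 0))
  expect_true(is.na(mono$fst))
  set.seed(21)
  for (i in 1:200) {
    cA <- as.vector(rmultinom(1, sample(2:30, 1), runif(3, 0.05, 1)))
    cB <- as.vector(rmultinom(1, sample(2:30, 1), runif(3, 0.05, 1)))
    got <- wc_fst_components(cA, cB)
    ora <- oracle_wc(list(cA, cB))
    if (is.na(got$fst)) {
      expect_true(!is.finite(ora$fst) || ora$a + ora$b + ora$c == 0)
    } else {
      expect_equal(got$a, ora$a, tolerance = 1e-10)
      expect_equal(got$b, ora$b, tolerance = 1e-10)
      expect_equal(got$c, ora$c, tolerance = 1e-10)
      expect_equal(got$fst, ora$fst, tolerance = 1e-10)
    }
  }
})

test_that("windowed weighted Fst is the ratio of sums over usable sites", {
  set.seed(22)
  gmA <- random_panel(8, 120, seed = 31, positions = sort(sample(1:19999, 120)))
  gmB <- random_panel(8, 120, seed = 32, positions = gmA$variants$pos)
  w <- data.frame(contig = "chr1", start = 0, end = 20000)
  out <- windowed_weighted_fst(gmA, gmB, w)
  # oracle: per-site components from the textbook implementation
  cntA <- apply(gmA$dos, 2, function(d) c(sum(d == 0), sum(d == 1), sum(d == 2)))
  cntB <- apply(gmB$dos, 2, function(d) c(sum(d == 0), sum(d == 1), sum(d == 2)))
  comp <- lapply(seq_len(120), function(j)
    oracle_wc(list(cntA[, j], cntB[, j])))
  a <- vapply(comp, `[[`, 0, "a")
  tot <- vapply(comp, function(u) u$a + u$b + u$c, 0)
  ok <- is.finite(a) & is.finite(tot) & tot != 0
  expect_equal(out$fst, sum(a[ok]) / sum(tot[ok]), tolerance = 1e-10)
  # single usable site: window value equals that site's ratio
  gs <- gm_from_haps(matrix(c(0L, 0L, 1L, 1L, 0L, 1L, 1L, 0L), 4, 2),
                     positions = c(50L, 15000L))
  gs1 <- subset_samples(gs, 1:2)
  # fixed-opposite single pop pair
  gmA1 <- gm_from_haps(matrix(0L, 6, 1), positions = 100L)
  gmB1 <- gm_from_haps(matrix(1L, 6, 1), positions = 100L)
  out1 <- windowed_weighted_fst(gmA1, gmB1,
                                data.frame(contig = "chr1", start = 0,
                                           end = 20000))
  expect_equal(out1$fst, 1)
})

test_that("haplotype r2: coupled, independent, and the 1/9 hand example", {
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  h1 <- c(0, 0, 1, 1); h2 <- c(0, 1, 0, 1)
  expect_equal(ld_r2(h1, h2), 0)
  # haplotypes {00, 00, 01, 10, 11, 11}
  a <- c(0, 0, 0, 1, 1, 1); b <- c(0, 0, 1, 0, 1, 1)
  expect_equal(ld_r2(a, b), 1 / 9)
  # symmetry and allele-relabel invariance
  set.seed(33)
  for (i in 1:20) {
    x <- rbinom(12, 1, 0.5); y <- rbinom(12, 1, 0.5)
    expect_equal(ld_r2(x, y), ld_r2(y, x))
    expect_equal(ld_r2(x, y), ld_r2(1 - x, y))
    expect_equal(ld_r2(x, y), ld_r2(x, 1 - y))
  }
  expect_true(is.na(ld_r2(c(0, 0, 0, 0), c(0, 1, 0, 1))))
})

test_that("LD decay: degenerate inputs and duplicated-site bin", {
  gm1 <- gm_from_haps(matrix(c(0L, 1L, 0L, 1L), 4, 1), positions = 500L)
  out1 <- ld_decay(gm1, max_dist = 5000, bin_bp = 1000)
  expect_true(all(out1$n_pairs == 0))
  # duplicated site at distance 2500 -> its bin has mean r2 = 1
  h <- matrix(rep(c(0L, 1L, 1L, 0L, 0L, 1L), 2), 6, 2)
  gm2 <- gm_from_haps(h, positions = c(1000L, 3500L))
  out2 <- ld_decay(gm2, max_dist = 5000, bin_bp = 1000)
  expect_equal(out2$mean_r2[out2$bin_start == 2000], 1)
  expect_equal(sum(out2$n_pairs), 1L)
})

test_that("LD decay declines with distance on recombining simulated data", {
  tr <- cached_sim("default1", wf_simulate(sim_config(seed = 5)))
  gm <- gm_from_haps(tr$haps$pop1, positions = tr$positions + 1L)
  out <- ld_decay(gm, max_dist = 15000, bin_bp = 3000)
  expect_true(all(out$n_pairs > 0))
  expect_gt(out$mean_r2[1], out$mean_r2[5])
  expect_true(all(out$mean_r2 >= 0 & out$mean_r2 <= 1))
})

test_that("LD pruning: identity, duplicates, and brute-force audit", {
  # mutually independent sites survive
  set.seed(41)
  gm <- random_panel(30, 20, seed = 41)
  # independent columns have low r2 at n = 30; use a lenient threshold
  kept <- ld_prune(gm, window_snps = 10, step_snps = 2, r2_max = 0.9)
  expect_equal(kept, seq_len(20))
  # two adjacent duplicate sites: exactly one removed (the later one)
  h <- sapply(runif(5, .3, .7), function(p) rbinom(20, 1, p))
  h <- matrix(as.integer(h), 20, 5)
  h <- cbind(h[, 1:3], h[, 3], h[, 4:5])
  gmd <- gm_from_haps(h)
  keptd <- ld_prune(gmd)
  expect_false(4L %in% keptd)
  expect_true(3L %in% keptd)
  # post-condition audit: no surviving pair within any scanned window
  # exceeds the threshold (brute force over every window position)
  gmr <- random_panel(15, 80, seed = 42)
  # add correlated blocks
  gmr$dos[, seq(5, 80, 7)] <- gmr$dos[, seq(4, 79, 7)]
  keptr <- ld_prune(gmr, window_snps = 20, step_snps = 4, r2_max = 0.5)
  for (i0 in seq(1, 80 - 19, 4)) {
    win <- intersect(i0:(i0 + 19), keptr)
    if (length(win) < 2) next
    r2 <- suppressWarnings(cor(gmr$dos[, win]))^2
    diag(r2) <- 0
    expect_lte(max(r2, na.rm = TRUE), 0.5)
  }
})

test_that("PCA: separation, duplicated samples, variance conservation", {
  tr <- cached_sim("split200",
                   wf_simulate(sim_config(seed = 6, split_gen = 200,
                                          L = 2e5)))
  gm <- gm_from_haps(rbind(tr$haps$pop1, tr$haps$pop2),
                     positions = tr$positions + 1L)
  pc <- pca_genotypes(gm, n_components = 4)
  # PC1 separates the two diverged populations with a margin
  g1 <- pc$coords[1:10, 1]; g2 <- pc$coords[11:20, 1]
  expect_true(max(g1) < min(g2) || max(g2) < min(g1))
  # eigenvalues non-increasing and conserve total variance
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))
  p <- colSums(gm$dos) / (2 * nrow(gm$dos))
  use <- p > 0 & p < 1
  X <- sweep(gm$dos[, use], 2, 2 * p[use])
  X <- sweep(X, 2, sqrt(p[use] * (1 - p[use])), `/`)
  expect_equal(sum(pc$eigenvalues), sum(diag(tcrossprod(X) / sum(use))),
               tolerance = 1e-8)
  # duplicated sample gets identical coordinates
  gm2 <- gm_from_haps(rbind(gm$hap, gm$hap[1:2, , drop = FALSE]),
                      positions = tr$positions + 1L)
  pc2 <- pca_genotypes(gm2, n_components = 3)
  expect_equal(unname(pc2$coords[21, ]), unname(pc2$coords[1, ]),
               tolerance = 1e-8)
})
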