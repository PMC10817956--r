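# Shared fixture builders and independent oracle implementations used across
# the suite. Oracles are deliberately coded from first principles (brute
# force, enumeration, textbook formulas) and never call the package routines
# they check.

# Build a geno_matrix directly from a phased haplotype matrix
# (2*samples x sites, 0/1/NA), bypassing VCF I/O.
gm_from_haps <- function(hap, positions = NULL, contig = "chr1",
                         contig_len = NULL, samples = NULL) {
  ns <- nrow(hap) %/% 2L
  S <- ncol(hap)
  if (is.null(positions)) positions <- seq_len(S) * 100L
  if (is.null(contig_len)) contig_len <- max(positions) + 100
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ns))
  dos <- hap[seq(1L, 2L * ns, 2L), , drop = FALSE] +
         hap[seq(2L, 2L * ns, 2L), , drop = FALSE]
  rownames(dos) <- samples
  variants <- data.frame(contig = contig, pos = as.integer(positions),
                         ref = "A", alt = "C", biallelic = TRUE)
  cl <- stats::setNames(contig_len, contig)
  geno_matrix(variants, dos, hap, contig_lengths = cl)
}

# Random phased panel: ns samples, S sites, allele freqs drawn uniformly.
random_panel <- function(ns, S, seed = 1, positions = NULL) {
  set.seed(seed)
  p <- runif(S, 0.1, 0.9)
  hap <- sapply(p, function(pp) rbinom(2L * ns, 1L, pp))
  gm_from_haps(matrix(as.integer(hap), 2L * ns, S), positions = positions)
}

# Cached default simulations shared across test files (built lazily once).
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(name, expr) {
  if (is.null(.sim_cache[[name]])) .sim_cache[[name]] <- force(expr)
  .sim_cache[[name]]
}

# ---- independent oracles ----------------------------------------------------

# HWE exact-test oracle: full enumeration of the conditional distribution of
# the heterozygote count via exact multinomial probabilities computed with
# choose() ratios (no shared code with hwe_exact_test()).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)
  rare <- min(nA, 2 * n - nA)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (2 * n - nA - h) / 2
    exp(lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
          h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) -
          lgamma(2 * n + 1))
  }, 0)
  obs <- pr[match(n_Aa, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)]) / sum(pr)
}

# Weir & Cockerham (1984) variance components, general-r textbook form,
# coded independently of wc_fst_components(). counts_list: per-population
# genotype count vectors c(n0, n1, n2).
oracle_wc <- function(counts_list) {
  r <- length(counts_list)
  n <- vapply(counts_list, sum, 0)
  p <- vapply(counts_list, function(cc) (cc[2] + 2 * cc[3]) / (2 * sum(cc)), 0)
  h <- vapply(counts_list, function(cc) cc[2] / sum(cc), 0)
  nbar <- mean(n)
  C2 <- sum((n - nbar)^2) / ((r - 1) * nbar^2)   # squared CV of sample sizes
  nc <- nbar * (1 - C2 * (r - 1) / r)            # equals (r*nbar - sum(n^2)/(r*nbar))/(r-1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# Brute-force nucleotide diversity for one window: mean proportion of
# differing pairs over all haplotype pairs, site by site, divided by span.
oracle_pi <- function(hap, positions, start, end) {
  S <- ncol(hap)
  tot <- 0
  for (j in seq_len(S)) {
    if (positions[j] - 1 < start || positions[j] - 1 >= end) next
    a <- hap[!is.na(hap[, j]), j]
    n <- length(a)
    if (n < 2) next
    diffs <- 0
    for (x in seq_len(n - 1)) for (y in seq(x + 1, n))
      diffs <- diffs + (a[x] != a[y])
    tot <- tot + diffs / choose(n, 2)
  }
  tot / (end - start)
}

# Sweep-line interval merge oracle (bedtools semantics, book-ended merge).
oracle_merge <- function(df) {
  if (nrow(df) == 0) return(df[, c("contig", "start", "end")])
  out <- NULL
  for (ctg in sort(unique(df$contig))) {
    d <- df[df$contig == ctg, ]
    d <- d[order(d$start, d$end), ]
    cs <- d$start[1]; ce <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= ce) ce <- max(ce, d$end[i])
      else { out <- rbind(out, data.frame(contig = ctg, start = cs, end = ce))
             cs <- d$start[i]; ce <- d$end[i] }
    }
    out <- rbind(out, data.frame(contig = ctg, start = cs, end = ce))
  }
  out[order(out$contig, out$start), , drop = FALSE]
}

# Write a minimal valid VCF from explicit genotype strings.
# gts: variants x samples character matrix like "0|1"; pos: 1-based.
write_mini_vcf <- function(path, gts, pos, contig = "chr1",
                           contig_len = 100000, ref = "A", alt = "C",
                           samples = NULL, format = "GT", extra = NULL) {
  nv <- nrow(gts); ns <- ncol(gts)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ns))
  ref <- rep_len(ref, nv); alt <- rep_len(alt, nv)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  cells <- gts
  if (!is.null(extra)) cells <- matrix(paste0(gts, extra), nv, ns)
  body <- paste(contig, pos, ".", ref, alt, ".", "PASS", ".", format,
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  path
}
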