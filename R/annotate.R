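# Mapping sweep regions to overlapping and nearby genes and writing the
# candidate-region report. Gene coordinates are held 0-based half-open
# internally (BED convention); GFF3 input is converted on read.

#' Read gene models from BED or GFF3
#'
#' BED input is taken as-is (0-based half-open; column 4 as gene ID, column 6
#' as strand when present). GFF3 input keeps `gene` features only and is
#' converted from 1-based inclusive coordinates; the gene ID comes from the
#' `ID`/`gene_id` attribute, the name from `Name`.
#'
#' @param path Input file.
#' @param format `"bed"`, `"gff3"`, or `"auto"` (from the extension).
#' @return data.frame of class `gene_set`: `gene_id`, `gene_name`, `contig`,
#'   `start`, `end`, `strand`. Duplicate gene IDs are rejected.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff3\\.gz)$", path, ignore.case = TRUE))
      "gff3" else if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else stop("cannot infer format from extension; pass format=")
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
    out <- data.frame(gene_id = ids, gene_name = ids,
                      contig = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    if (!length(gr)) stop("no 'gene' features in GFF3 input")
    ids <- if (!is.null(gr$ID)) as.character(gr$ID)
           else if (!is.null(gr$gene_id)) as.character(gr$gene_id)
           else paste0("gene", seq_along(gr))
    nm <- if (!is.null(gr$Name)) as.character(gr$Name) else ids
    nm[is.na(nm)] <- ids[is.na(nm)]
    out <- data.frame(gene_id = ids, gene_name = nm,
                      contig = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene_id in annotation input")
  if (any(out$start >= out$end)) stop("gene with start >= end")
  out$strand[!out$strand %in% c("+", "-")] <- "*"
  rownames(out) <- NULL
  class(out) <- c("gene_set", "data.frame")
  out
}

#' Write a gene set back to BED
#'
#' @param genes A `gene_set`.
#' @param path Output path.
#' @export
write_genes_bed <- function(genes, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$contig,
                     as.integer(genes$start), as.integer(genes$end),
                     genes$gene_id, genes$strand), path)
  invisible(path)
}

as_granges0 <- function(contig, start, end) {
  GenomicRanges::GRanges(contig,
                         IRanges::IRanges(start = start + 1, end = end))
}

#' Genes overlapping sweep regions
#'
#' Any intersection of at least 1 bp counts (half-open coordinates: a gene
#' ending where a region starts does not overlap). Regions overlapping no
#' gene are labelled gene-void.
#'
#' @param regions data.frame with `contig`, `start`, `end` (0-based
#'   half-open), e.g. from [merge_regions()].
#' @param genes A `gene_set` from [read_genes()].
#' @return `list(overlaps =, gene_void =)`: a data.frame of (region, gene)
#'   pairs and a logical vector over regions.
#' @export
overlap_genes <- function(regions, genes) {
  if (nrow(regions) == 0L)
    return(list(overlaps = data.frame(region = integer(0),
                                      gene_id = character(0)),
                gene_void = logical(0)))
  gr_r <- as_granges0(regions$contig, regions$start, regions$end)
  gr_g <- as_granges0(genes$contig, genes$start, genes$end)
  hits <- GenomicRanges::findOverlaps(gr_r, gr_g)
  ov <- data.frame(region = S4Vectors::queryHits(hits),
                   gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
                   gene_name = genes$gene_name[S4Vectors::subjectHits(hits)])
  ov <- ov[order(ov$region, ov$gene_id), , drop = FALSE]
  rownames(ov) <- NULL
  gene_void <- !(seq_len(nrow(regions)) %in% ov$region)
  list(overlaps = ov, gene_void = gene_void)
}

#' Genes near (but not overlapping) sweep regions
#'
#' Reports genes within `flank_bp` of a region edge, with the gap distance
#' and the region's side relative to the gene: `"upstream"` when the region
#' lies on the gene's 5' side (strand-aware; for strandless genes, upstream
#' means lower coordinates). Book-ended genes have distance 0.
#'
#' @inheritParams overlap_genes
#' @param flank_bp Maximum gap in bp (default 30 kb).
#' @return data.frame of (region, gene_id, gene_name, distance, side) rows.
#' @export
nearby_genes <- function(regions, genes, flank_bp = 30000) {
  out <- data.frame(region = integer(0), gene_id = character(0),
                    gene_name = character(0), distance = numeric(0),
                    side = character(0))
  if (nrow(regions) == 0L || nrow(genes) == 0L) return(out)
  for (i in seq_len(nrow(regions))) {
    same <- genes$contig == regions$contig[i]
    if (!any(same)) next
    g <- genes[same, , drop = FALSE]
    gap_left <- regions$start[i] - g$end    # gene entirely before region
    gap_right <- g$start - regions$end[i]   # gene entirely after region
    gap <- pmax(gap_left, gap_right)
    near <- gap >= 0 & gap <= flank_bp
    if (!any(near)) next
    g <- g[near, , drop = FALSE]
    gap <- gap[near]
    region_after_gene <- (regions$start[i] - g$end) >= 0
    side <- ifelse(g$strand == "-",
                   ifelse(region_after_gene, "upstream", "downstream"),
                   ifelse(region_after_gene, "downstream", "upstream"))
    out <- rbind(out, data.frame(region = i, gene_id = g$gene_id,
                                 gene_name = g$gene_name, distance = gap,
                                 side = side))
  }
  rownames(out) <- NULL
  out
}

#' Write the annotated sweep-region report
#'
#' One row per region: coordinates, source scan, direction, peak statistic,
#' overlapping genes (comma-joined; `gene_void` when none) and nearby genes
#' with distances. A companion BED file carries the plain intervals.
#'
#' @param regions Region data.frame (e.g. from [merge_regions()]), with
#'   optional `source`, `direction`, `peak` columns.
#' @param genes Optional `gene_set`; when NULL the gene columns are empty.
#' @param path Output TSV path; the BED goes to the same path with `.bed`
#'   substituted for `.tsv`.
#' @param flank_bp Passed to [nearby_genes()].
#' @return Invisibly, the report data.frame.
#' @export
write_report <- function(regions, genes = NULL, path, flank_bp = 30000) {
  n <- nrow(regions)
  rep_df <- data.frame(
    contig = regions$contig %||% character(0),
    start = regions$start %||% numeric(0),
    end = regions$end %||% numeric(0),
    source = if ("source" %in% names(regions)) regions$source
             else rep(NA_character_, n),
    direction = if ("direction" %in% names(regions)) regions$direction
                else rep(NA_character_, n),
    peak = if ("peak" %in% names(regions)) regions$peak
           else rep(NA_real_, n))
  if (!is.null(genes) && n > 0L) {
    ov <- overlap_genes(regions, genes)
    nb <- nearby_genes(regions, genes, flank_bp)
    rep_df$genes <- vapply(seq_len(n), function(i) {
      g <- ov$overlaps$gene_name[ov$overlaps$region == i]
      if (length(g)) paste(g, collapse = ",") else "gene_void"
    }, "")
    rep_df$nearby_genes <- vapply(seq_len(n), function(i) {
      j <- nb$region == i
      if (!any(j)) return("")
      paste(sprintf("%s(%d bp %s)", nb$gene_name[j], as.integer(nb$distance[j]),
                    nb$side[j]), collapse = ",")
    }, "")
  } else {
    rep_df$genes <- rep("", n)
    rep_df$nearby_genes <- rep("", n)
  }
  utils::write.table(rep_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed_path <- sub("\\.tsv$", ".bed", path)
  if (identical(bed_path, path)) bed_path <- paste0(path, ".bed")
  writeLines(if (n > 0L)
    sprintf("%s\t%d\t%d\t%s", rep_df$contig, as.integer(rep_df$start),
            as.integer(rep_df$end),
            ifelse(is.na(rep_df$direction), ".", rep_df$direction))
    else character(0), bed_path)
  invisible(rep_df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
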