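# Gene annotation parsing: GTF -> GeneRegion list.

#' Parse gene phenotyping regions from a GTF file
#'
#' Reads gene and exon records, keeps genes of the requested biotypes, and
#' builds one [gene_region()] per gene: the gene span extended by `flank_bp`
#' on each side (clipped at position 0 and, when chromosome lengths are known,
#' at the chromosome end), plus the union of exons of all *other* genes in the
#' annotation (any biotype) that intersect the extended region.
#'
#' GTF 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention. The biotype attribute is read from `gene_type`
#' (GENCODE) or `gene_biotype` (Ensembl), whichever is present.
#'
#' @param gtf_path path to a GTF file.
#' @param flank_bp non-negative flank added on each side of the gene span
#'   (default 1000).
#' @param biotypes biotypes to phenotype (default protein-coding and lncRNA).
#' @param chrom_sizes optional named vector of chromosome lengths used to clip
#'   regions at the right end.
#' @return Named list of `GeneRegion` objects (name = gene_id), in file order.
#' @export
parse_gene_regions <- function(gtf_path, flank_bp = 1000L,
                               biotypes = c("protein_coding", "lncRNA"),
                               chrom_sizes = NULL) {
  stopifnot(flank_bp >= 0)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$type) || is.null(mc$gene_id))
    stop("GTF is missing 'type' or 'gene_id' attributes: ", gtf_path)

  bt <- mc$gene_type %||% mc$gene_biotype
  if (is.null(bt))
    stop("GTF has neither 'gene_type' nor 'gene_biotype' attributes: ", gtf_path)

  is_gene <- as.character(mc$type) == "gene"
  is_exon <- as.character(mc$type) == "exon"
  if (!any(is_gene) || !any(is_exon))
    stop("GTF must contain both gene and exon records: ", gtf_path)

  genes <- gr[is_gene]
  gene_bt <- bt[is_gene]
  bad <- which(is.na(S4Vectors::mcols(genes)$gene_id) | is.na(gene_bt))
  if (length(bad))
    stop("gene record ", bad[1], " (", as.character(GenomicRanges::seqnames(genes))[bad[1]],
         ":", GenomicRanges::start(genes)[bad[1]],
         ") is missing gene_id or biotype attribute")

  exons <- gr[is_exon]
  exon_gene <- as.character(S4Vectors::mcols(exons)$gene_id)
  if (anyNA(exon_gene)) stop("exon record without gene_id attribute")

  keep <- gene_bt %in% biotypes
  kept_genes <- genes[keep]
  gid <- as.character(S4Vectors::mcols(kept_genes)$gene_id)
  if (anyDuplicated(gid)) stop("duplicate gene_id in GTF: ", gid[duplicated(gid)][1])

  # flanked regions (1-based for overlap queries, converted below)
  g_start1 <- GenomicRanges::start(kept_genes)
  g_end1 <- GenomicRanges::end(kept_genes)
  chroms <- as.character(GenomicRanges::seqnames(kept_genes))
  r_start1 <- pmax(1L, g_start1 - flank_bp)
  r_end1 <- g_end1 + flank_bp
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[chroms]
    r_end1 <- ifelse(is.na(lim), r_end1, pmin(r_end1, lim))
  }
  region_gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(r_start1, r_end1))

  hits <- GenomicRanges::findOverlaps(region_gr, exons, ignore.strand = TRUE)
  out <- vector("list", length(kept_genes))
  names(out) <- gid
  for (i in seq_along(kept_genes)) {
    ex_i <- exons[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
    ex_i <- ex_i[as.character(S4Vectors::mcols(ex_i)$gene_id) != gid[i]]
    fe <- matrix(numeric(0), ncol = 2L)
    if (length(ex_i)) {
      red <- IRanges::reduce(IRanges::ranges(ex_i))
      fe <- cbind(start = IRanges::start(red) - 1, end = IRanges::end(red))
      fe <- fe[order(fe[, 1]), , drop = FALSE]
    }
    out[[i]] <- gene_region(
      gene_id = gid[i], chrom = chroms[i],
      strand = as.character(GenomicRanges::strand(kept_genes))[i],
      gene_start = g_start1[i] - 1, gene_end = g_end1[i],
      region_start = r_start1[i] - 1, region_end = r_end1[i],
      biotype = gene_bt[keep][i], foreign_exons = fe)
  }
  out
}

#' Transcription start site of a gene region
#'
#' `gene_start` for + strand genes, `gene_end - 1` for - strand genes
#' (0-based position of the first transcribed base).
#'
#' @param region a `GeneRegion`.
#' @return integer position (0-based).
#' @export
tss_of <- function(region) {
  if (region$strand == "+") region$gene_start else region$gene_end - 1
}
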