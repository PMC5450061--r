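#' Read a gene annotation from BED or GTF
#'
#' Coordinates are converted to 1-based closed intervals internally (BED
#' input is 0-based half-open on disk; `rtracklayer` performs the shift).
#' For GTF input, records of type `gene` are used when present, otherwise
#' the span of each `gene_id` is taken.  Duplicated gene ids keep their
#' first record (after sorting by chromosome and start) and the number
#' dropped is reported.
#'
#' @param path path to a BED6 or GTF file.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gtf"
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "bed") {
    ids <- as.character(gr$name)
  } else {
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene", na.rm = TRUE))
      gr <- gr[!is.na(gr$type) & gr$type == "gene"]
    ids <- as.character(gr$gene_id)
  }
  ann <- data.frame(gene_id = ids,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  ann$strand[!ann$strand %in% c("+", "-")] <- "."
  bad <- ann$start >= ann$end
  if (any(bad)) stop(sprintf("%d annotation record(s) with start >= end", sum(bad)))
  ann <- ann[order(match(ann$chrom, natural_chrom_order(ann$chrom)),
                   ann$start, ann$gene_id), , drop = FALSE]
  dup <- duplicated(ann$gene_id)
  if (any(dup)) {
    message(sprintf("dropping %d duplicate annotation record(s)", sum(dup)))
    ann <- ann[!dup, , drop = FALSE]
  }
  rownames(ann) <- NULL
  ann
}

#' Order measured genes along the genome
#'
#' Produces, per chromosome, the genes of an expression matrix sorted by
#' annotated start coordinate (ties broken by gene id, strand ignored).
#' This ordering defines "adjacent genes" for the sliding-window CNV
#' profile.  Genes missing from the annotation are excluded and counted.
#'
#' @param ann annotation data.frame from [read_annotation()].
#' @param genes character vector of measured gene ids.
#' @param chrom_order optional explicit chromosome order; defaults to
#'   [natural_chrom_order()] of the annotated chromosomes.
#' @return named list (one element per chromosome, in order) of gene-id
#'   vectors; attribute `n_unannotated` counts the excluded genes.
#' @export
order_genes <- function(ann, genes, chrom_order = NULL) {
  keep <- ann[ann$gene_id %in% genes, , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("annotation shares no genes with the expression matrix")
  chroms <- chrom_order %||% natural_chrom_order(keep$chrom)
  chroms <- chroms[chroms %in% keep$chrom]
  out <- lapply(chroms, function(ch) {
    sub <- keep[keep$chrom == ch, , drop = FALSE]
    sub$gene_id[order(sub$start, sub$gene_id)]
  })
  names(out) <- chroms
  attr(out, "n_unannotated") <- length(setdiff(genes, ann$gene_id))
  out
}
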