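#' Read SNV sites from a VCF
#'
#' Parses a VCF 4.x file and extracts one record per site with the blood
#' and tumor variant-allele frequencies carried in INFO fields (names
#' configurable; the simulator writes `VAF_BLOOD` and `VAF_TUMOR`).
#' Somatic and germline variants are supplied as separate files; `kind`
#' tags the records accordingly.
#'
#' @param path path to the VCF.
#' @param kind `"germline"` or `"somatic"`.
#' @param vaf_tumor_field,vaf_blood_field INFO keys holding the VAFs.
#' @return data.frame: `chrom`, `pos`, `ref`, `alt`, `kind`, `vaf_blood`,
#'   `vaf_tumor`.
#' @export
read_snv_vcf <- function(path, kind = c("germline", "somatic"),
                         vaf_tumor_field = "VAF_TUMOR",
                         vaf_blood_field = "VAF_BLOOD") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  vt <- suppressWarnings(as.numeric(vcfR::extract.info(v, vaf_tumor_field)))
  vb <- suppressWarnings(as.numeric(vcfR::extract.info(v, vaf_blood_field)))
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      kind = kind,
                      vaf_blood = vb, vaf_tumor = vt,
                      stringsAsFactors = FALSE)
  if (any(sites$ref == sites$alt))
    stop("VCF contains records with ref == alt")
  if (kind == "germline" && anyNA(sites$vaf_blood))
    stop("germline sites must carry ", vaf_blood_field, " in INFO")
  rownames(sites) <- NULL
  sites
}

#' Write SNV sites as a minimal VCF
#'
#' Serializes a site table produced by this package (e.g. by the
#' simulator) to VCF 4.2 with the VAFs in INFO.  The header is fixed text
#' with no timestamps so identical inputs yield byte-identical files.
#'
#' @param sites site data.frame as returned by [read_snv_vcf()].
#' @param path output path.
#' @export
write_snv_vcf <- function(sites, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=VAF_BLOOD,Number=1,Type=Float,Description=\"Variant allele frequency in blood exome-seq\">",
           "##INFO=<ID=VAF_TUMOR,Number=1,Type=Float,Description=\"Variant allele frequency in tumor exome-seq\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- ifelse(is.na(sites$vaf_blood),
                 sprintf("VAF_TUMOR=%.4f", sites$vaf_tumor),
                 sprintf("VAF_BLOOD=%.4f;VAF_TUMOR=%.4f",
                         sites$vaf_blood, sites$vaf_tumor))
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read per-cell allele counts at SNV sites
#'
#' TSV with columns `cell_id`, `chrom`, `pos`, `ref`, `alt`, `ref_count`,
#' `alt_count` — the per-cell pileup of reads supporting each allele at
#' exome-validated variant positions.
#'
#' @param path path to the TSV.
#' @return data.frame with the seven columns above.
#' @export
read_allele_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ac <- read_tsv_plain(path)
  need <- c("cell_id", "chrom", "pos", "ref", "alt", "ref_count", "alt_count")
  if (!all(need %in% names(ac)))
    stop("allele-count TSV needs columns ", paste(need, collapse = ", "))
  if (any(ac$ref_count < 0 | ac$alt_count < 0))
    stop("allele counts must be non-negative")
  ac[need]
}

#' @rdname read_allele_counts
#' @param counts allele-count data.frame.
#' @export
write_allele_counts <- function(counts, path) {
  write_tsv_plain(counts, path)
}
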