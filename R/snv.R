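#' Select informative germline SNV sites
#'
#' Keeps heterozygous germline sites whose tumor-exome VAF shifted away
#' from the 0.5 blood anchor and that lie inside an exome-defined CNV
#' segment.  In regions of copy-number loss such sites are expected to be
#' monoallelically expressed in cells that carry the loss; sites inside
#' gain segments are retained too (allelic imbalance rather than LOH) and
#' the containing segment's direction is recorded per site so downstream
#' logic can restrict the strict mono/biallelic argument to losses.
#'
#' @param sites germline site table from [read_snv_vcf()].
#' @param segments segment table from [call_exome_segments()].
#' @param het_tol maximum |blood VAF - 0.5| for a site to count as
#'   heterozygous (default 0.1).
#' @param shift_min minimum |tumor VAF - 0.5| (default 0.15).
#' @return the selected sites, ordered by chromosome and position, with
#'   added columns `segment_id` and `segment_direction`.
#' @export
select_informative_germline <- function(sites, segments,
                                        het_tol = 0.1, shift_min = 0.15) {
  empty <- cbind(sites[0, , drop = FALSE],
                 data.frame(segment_id = character(),
                            segment_direction = character()))
  if (is.null(segments) || nrow(segments) == 0L) {
    warning("no CNV segments supplied; no informative germline sites")
    return(empty)
  }
  g <- sites[sites$kind == "germline" & !is.na(sites$vaf_blood), , drop = FALSE]
  g <- g[abs(g$vaf_blood - 0.5) <= het_tol &
         abs(g$vaf_tumor - 0.5) >= shift_min, , drop = FALSE]
  if (nrow(g) == 0L) return(empty)
  seg_id <- rep(NA_character_, nrow(g))
  seg_dir <- rep(NA_character_, nrow(g))
  for (i in seq_len(nrow(g))) {
    hit <- which(segments$chrom == g$chrom[i] &
                 segments$start <= g$pos[i] & segments$end >= g$pos[i])
    if (length(hit)) {
      seg_id[i] <- segments$segment_id[hit[1L]]
      seg_dir[i] <- segments$direction[hit[1L]]
    }
  }
  g$segment_id <- seg_id
  g$segment_direction <- seg_dir
  g <- g[!is.na(g$segment_id), , drop = FALSE]
  g <- g[order(g$chrom, g$pos), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Call per-cell allele patterns at informative germline sites
#'
#' Classifies each covered cell x site as `ref_only`, `alt_only`,
#' `biallelic` (both alleles with at least `min_minor` reads) or
#' `no_coverage` (fewer than `min_reads` total reads), then summarizes per
#' cell: `biallelic_observed` if any site is biallelic (evidence against a
#' copy-number loss covering the site), `monoallelic_consistent` if at
#' least one site is covered and none is biallelic, `uninformative` with
#' no covered site.
#'
#' @param counts allele-count data.frame ([read_allele_counts()]) already
#'   restricted to the informative sites; rows at positions absent from
#'   `info_sites` are an error naming the offenders.
#' @param info_sites table from [select_informative_germline()].
#' @param min_reads minimum total reads for a site to count as covered
#'   (default 3).
#' @param min_minor minimum reads on each allele for a biallelic call
#'   (default 2, absorbing singleton sequencing errors).
#' @return list with `sites` (per cell x site calls, incl. the containing
#'   segment and its direction) and `cells` (per-cell summary with
#'   `n_covered`, `n_biallelic`, `summary`).
#' @export
call_allele_pattern <- function(counts, info_sites, min_reads = 3, min_minor = 2) {
  if (nrow(info_sites) == 0L) stop("no informative germline sites supplied")
  keys <- site_key(info_sites$chrom, info_sites$pos)
  ckeys <- site_key(counts$chrom, counts$pos)
  unknown <- setdiff(unique(ckeys), keys)
  if (length(unknown))
    stop("allele counts reference unknown sites: ",
         paste(unknown, collapse = ", "))
  idx <- match(ckeys, keys)
  cov <- counts$ref_count + counts$alt_count
  call <- ifelse(cov < min_reads, "no_coverage",
          ifelse(counts$ref_count >= min_minor & counts$alt_count >= min_minor,
                 "biallelic",
          ifelse(counts$ref_count >= counts$alt_count, "ref_only", "alt_only")))
  sites_out <- data.frame(cell_id = counts$cell_id,
                          chrom = counts$chrom, pos = counts$pos,
                          ref_count = counts$ref_count,
                          alt_count = counts$alt_count,
                          call = call,
                          segment_id = info_sites$segment_id[idx],
                          segment_direction = info_sites$segment_direction[idx],
                          stringsAsFactors = FALSE)
  per_cell <- split(sites_out, sites_out$cell_id)
  cells_out <- data.frame(
    cell_id = names(per_cell),
    n_covered = vapply(per_cell, function(d) sum(d$call != "no_coverage"), 0L),
    n_biallelic = vapply(per_cell, function(d) sum(d$call == "biallelic"), 0L),
    stringsAsFactors = FALSE)
  cells_out$summary <- ifelse(cells_out$n_biallelic > 0L, "biallelic_observed",
                       ifelse(cells_out$n_covered > 0L, "monoallelic_consistent",
                              "uninformative"))
  rownames(cells_out) <- NULL
  list(sites = sites_out, cells = cells_out)
}

#' Tally expressed somatic SNVs per cell
#'
#' A somatic site counts as detected in a cell when its alternate allele
#' has at least `min_alt` reads there.  A single detected exome-validated
#' somatic SNV is strong evidence that the cell is neoplastic.
#'
#' @param counts allele-count data.frame covering somatic sites.
#' @param somatic_sites somatic site table from [read_snv_vcf()].
#' @param min_alt minimum alt reads for detection (default 1).
#' @param cells optional vector of all cell ids, so cells with no counts
#'   appear with a tally of zero.
#' @return data.frame: `cell_id`, `n_somatic_expressed`, `sites_detected`
#'   (comma-separated `chrom:pos` keys).
#' @export
tally_somatic <- function(counts, somatic_sites, min_alt = 1, cells = NULL) {
  keys <- site_key(somatic_sites$chrom, somatic_sites$pos)
  ckeys <- site_key(counts$chrom, counts$pos)
  counts <- counts[ckeys %in% keys, , drop = FALSE]
  ckeys <- ckeys[ckeys %in% keys]
  det <- counts$alt_count >= min_alt
  cells <- cells %||% sort(unique(counts$cell_id))
  hits <- split(ckeys[det], factor(counts$cell_id[det], levels = cells))
  data.frame(cell_id = cells,
             n_somatic_expressed = vapply(hits, length, 0L),
             sites_detected = vapply(hits, paste, "", collapse = ","),
             stringsAsFactors = FALSE, row.names = NULL)
}
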