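`%||%` <- function(a, b) if (is.null(a)) b else a

#' Natural chromosome ordering
#'
#' Orders chromosome names the way a genome browser does: chr1..chr22 by
#' number, then chrX, chrY, chrM, then anything else lexicographically.
#'
#' @param chroms character vector of chromosome names (possibly repeated).
#' @return unique chromosome names in natural order.
#' @export
natural_chrom_order <- function(chroms) {
  u <- unique(as.character(chroms))
  key <- sub("^chr", "", u)
  num <- suppressWarnings(as.integer(key))
  rank <- ifelse(!is.na(num), num,
                 ifelse(key == "X", 1000L,
                 ifelse(key == "Y", 1001L,
                 ifelse(key %in% c("M", "MT"), 1002L, 2000L))))
  u[order(rank, key)]
}

# Fixed decimal formatting: integers render without decimals, everything else
# with 17 significant digits so a written TSV re-reads to the same double.
fmt_num <- function(x) {
  out <- character(length(x))
  int <- is.finite(x) & x == round(x) & abs(x) < 1e15
  out[int] <- sprintf("%.0f", x[int])
  out[!int] <- sprintf("%.17g", x[!int])
  out[is.na(x)] <- "NA"
  out
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

site_key <- function(chrom, pos) paste0(chrom, ":", pos)
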