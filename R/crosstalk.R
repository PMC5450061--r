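#' Prevalence and mean expression of a gene in a cell population
#'
#' @param m CPM [expression_matrix()].
#' @param cells cell ids of the population (nonempty).
#' @param gene gene id; a gene absent from the matrix yields `(0, 0)` with
#'   a message.
#' @param expressed_floor CPM above which a cell counts as expressing the
#'   gene (default 0: any nonzero expression).
#' @return named numeric vector `c(pct, mean)`: percentage of cells
#'   expressing the gene and mean CPM over all listed cells (zeros
#'   included).
#' @export
population_stats <- function(m, cells, gene, expressed_floor = 0) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "CPM") stop("population_stats requires a CPM matrix")
  if (length(cells) == 0L) stop("empty cell population")
  missing <- setdiff(cells, colnames(m$values))
  if (length(missing)) stop("unknown cells: ", paste(missing, collapse = ", "))
  if (!gene %in% rownames(m$values)) {
    message("gene ", gene, " absent from the matrix; stats (0, 0)")
    return(c(pct = 0, mean = 0))
  }
  v <- m$values[gene, cells]
  c(pct = 100 * sum(v > expressed_floor) / length(v), mean = mean(v))
}

#' Read a ligand-receptor pair database
#'
#' Two-column TSV (`ligand`, `receptor`); malformed rows (missing or empty
#' fields) are an error naming the line numbers.
#'
#' @param path path to the TSV.
#' @return data.frame `ligand`, `receptor`.
#' @export
read_lr_pairs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  db <- read_tsv_plain(path)
  if (!all(c("ligand", "receptor") %in% names(db)))
    stop("ligand-receptor database needs columns 'ligand' and 'receptor'")
  bad <- which(is.na(db$ligand) | is.na(db$receptor) |
               db$ligand == "" | db$receptor == "")
  if (length(bad))
    stop("malformed ligand-receptor rows at line(s): ",
         paste(bad + 1L, collapse = ", "))
  db[c("ligand", "receptor")]
}

#' Infer candidate ligand-receptor interactions between populations
#'
#' Screens a ligand-receptor database for pairs whose ligand is robustly
#' expressed by the sender population — prevalence of at least
#' `sender_pct_min` percent (inclusive) and mean expression strictly above
#' `sender_mean_min` CPM — and whose receptor passes the receiver rule.
#' By default the receiver rule mirrors the sender thresholds; with
#' `receiver_any_expression = TRUE` any nonzero receptor prevalence
#' suffices.  Boundary semantics are exact: prevalence is inclusive ("at
#' least 20%"), mean is strict (">2 CPM").
#'
#' @param sender_m,receiver_m CPM [expression_matrix()] objects for the
#'   two populations (e.g. TAMs and neoplastic cells).
#' @param lr_db pair data.frame from [read_lr_pairs()].
#' @param sender_pct_min,sender_mean_min sender thresholds (defaults 20
#'   percent and 2 CPM).
#' @param receiver_pct_min,receiver_mean_min receiver thresholds
#'   (defaults mirror the sender's).
#' @param receiver_any_expression relax the receiver rule to "expressed in
#'   any receiver cell".
#' @param expressed_floor CPM floor defining "expressing" (default 0).
#' @return data.frame of passing pairs sorted by ligand then receptor:
#'   `ligand`, `receptor`, `pct_sender`, `mean_sender`, `pct_receiver`,
#'   `mean_receiver`.
#' @export
infer_interactions <- function(sender_m, receiver_m, lr_db,
                               sender_pct_min = 20, sender_mean_min = 2,
                               receiver_pct_min = 20, receiver_mean_min = 2,
                               receiver_any_expression = FALSE,
                               expressed_floor = 0) {
  if (!all(c("ligand", "receptor") %in% names(lr_db)))
    stop("ligand-receptor database needs columns 'ligand' and 'receptor'")
  sender_cells <- colnames(sender_m$values)
  receiver_cells <- colnames(receiver_m$values)
  out <- list()
  for (i in seq_len(nrow(lr_db))) {
    lig <- lr_db$ligand[i]; rec <- lr_db$receptor[i]
    s <- suppressMessages(
      population_stats(sender_m, sender_cells, lig, expressed_floor))
    if (!(s["pct"] >= sender_pct_min && s["mean"] > sender_mean_min)) next
    r <- suppressMessages(
      population_stats(receiver_m, receiver_cells, rec, expressed_floor))
    rec_ok <- if (receiver_any_expression) r["pct"] > 0 else
      (r["pct"] >= receiver_pct_min && r["mean"] > receiver_mean_min)
    if (!rec_ok) next
    out[[length(out) + 1L]] <- data.frame(
      ligand = lig, receptor = rec,
      pct_sender = unname(s["pct"]), mean_sender = unname(s["mean"]),
      pct_receiver = unname(r["pct"]), mean_receiver = unname(r["mean"]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(ligand = character(), receptor = character(),
                      pct_sender = double(), mean_sender = double(),
                      pct_receiver = double(), mean_receiver = double(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$ligand, res$receptor), , drop = FALSE]
  rownames(res) <- NULL
  res
}
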