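#' Default G1/S and G2/M gene sets
#'
#' Editable defaults drawn from canonical replication (G1/S) and mitosis
#' (G2/M) programs used in glioma single-cell studies.  Replace with any
#' signature appropriate to the tissue.
#'
#' @return list with character vectors `g1s` and `g2m`.
#' @export
default_cycle_genes <- function() {
  list(g1s = c("MCM2", "PCNA", "RRM1", "RRM2", "MCM6", "CDC6", "UNG",
               "GINS2", "CCNE2", "CDC45", "MCM4", "E2F8"),
       g2m = c("CCNB1", "CCNB2", "CDK1", "TOP2A", "BUB1", "UBE2C",
               "AURKA", "AURKB", "PLK1", "MKI67", "CDC20", "CENPF"))
}

#' Gene-set program score per cell
#'
#' Expression is transformed to E = log2(CPM/10 + 1); a cell's score for a
#' gene set is the mean E over the set minus the mean E over all measured
#' genes.  The genome-wide centering makes the score invariant to adding
#' a constant to every gene's E, so the cycling threshold is comparable
#' across cells.  Set genes missing from the matrix are dropped and
#' reported.
#'
#' @param m CPM [expression_matrix()].
#' @param gene_set character vector of gene ids.
#' @param set_name label used in messages/errors.
#' @return named numeric vector of per-cell scores.
#' @export
phase_score <- function(m, gene_set, set_name = "gene set") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "CPM") stop("phase_score requires a CPM matrix")
  present <- intersect(gene_set, rownames(m$values))
  if (length(present) == 0L)
    stop("none of the genes in '", set_name, "' are present in the matrix")
  missing <- setdiff(gene_set, present)
  if (length(missing))
    message(sprintf("%s: %d gene(s) not in the matrix, dropped", set_name,
                    length(missing)))
  E <- log2(m$values / 10 + 1)
  colMeans(E[present, , drop = FALSE]) - colMeans(E)
}

#' Classify cycling cells from G1/S and G2/M scores
#'
#' A cell is cycling when the average of its two phase scores strictly
#' exceeds `threshold` (default 1.2).  Cycling cells are assigned phase
#' G1/S or G2/M when one score dominates by more than `margin`, otherwise
#' `intermediate`; non-cycling cells have phase `none`.
#'
#' @param g1s,g2m named numeric score vectors from [phase_score()].
#' @param threshold cycling threshold on the averaged score (default 1.2).
#' @param margin score difference needed to assign a dominant phase
#'   (default 0.3).
#' @return data.frame: `cell_id`, `g1s`, `g2m`, `avg`, `cycling`, `phase`.
#' @export
classify_cycling <- function(g1s, g2m, threshold = 1.2, margin = 0.3) {
  stopifnot(length(g1s) == length(g2m), all(is.finite(g1s)), all(is.finite(g2m)))
  avg <- (g1s + g2m) / 2
  cycling <- avg > threshold
  phase <- ifelse(!cycling, "none",
           ifelse(g1s - g2m > margin, "G1/S",
           ifelse(g2m - g1s > margin, "G2/M", "intermediate")))
  data.frame(cell_id = names(g1s) %||% as.character(seq_along(g1s)),
             g1s = unname(g1s), g2m = unname(g2m), avg = unname(avg),
             cycling = unname(cycling), phase = unname(phase),
             stringsAsFactors = FALSE)
}

#' Score and classify cycling cells in one call
#'
#' @param m CPM [expression_matrix()].
#' @param gene_sets list with `g1s` and `g2m` vectors
#'   (default [default_cycle_genes()]).
#' @inheritParams classify_cycling
#' @return see [classify_cycling()].
#' @export
cycle_scores <- function(m, gene_sets = default_cycle_genes(),
                         threshold = 1.2, margin = 0.3) {
  classify_cycling(phase_score(m, gene_sets$g1s, "G1/S"),
                   phase_score(m, gene_sets$g2m, "G2/M"),
                   threshold = threshold, margin = margin)
}
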