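#' Default tumor and immune marker gene lists
#'
#' Editable defaults for marker-space clustering: canonical glioblastoma
#' stem/tumor markers and a tumor-associated-macrophage/microglia panel.
#' Both lists are plain character vectors meant to be replaced for other
#' tumor types.
#'
#' @return list with elements `tumor` and `immune`.
#' @export
default_marker_genes <- function() {
  list(tumor = c("CD44", "PROM1", "NES", "KLF4", "MYC", "NANOG", "STAT3",
                 "SOX2", "MET"),
       immune = c("PTPRC", "ITGAM", "AIF1", "CD68", "CD14", "CSF1R",
                  "CX3CR1", "P2RY12", "TMEM119", "TYROBP"))
}

#' Hierarchical clustering of cells in marker space
#'
#' Agglomerative clustering (complete linkage, Euclidean distance) of
#' cells over log2(CPM + 1) marker-gene vectors, cut to `k` clusters.
#' Determinism follows from `stats::hclust`, whose merge order is fixed
#' for a given distance matrix.
#'
#' @param m CPM [expression_matrix()].
#' @param marker_genes character vector of marker gene ids (tumor and
#'   immune markers combined).
#' @param k number of clusters (default 2: tumor vs immune).
#' @return named integer vector of cluster labels, plus the `hclust` tree
#'   as attribute `tree`.
#' @export
cluster_cells <- function(m, marker_genes, k = 2) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "CPM") stop("cluster_cells requires a CPM matrix")
  if (k > ncol(m$values))
    stop(sprintf("k = %d exceeds the number of cells (%d)", k, ncol(m$values)))
  genes <- intersect(marker_genes, rownames(m$values))
  if (length(genes) == 0L) stop("no marker genes present in the matrix")
  E <- t(log2(m$values[genes, , drop = FALSE] + 1))
  tree <- stats::hclust(stats::dist(E, method = "euclidean"),
                        method = "complete")
  labels <- stats::cutree(tree, k = k)
  attr(labels, "tree") <- tree
  labels
}

#' Per-cell marker score and immune-majority cluster
#'
#' The marker score of a cell is its mean log2(CPM + 1) over the tumor
#' markers minus the mean over the immune markers.  The immune-majority
#' cluster is the cluster with the higher mean immune-marker expression;
#' assignment is automatic and deterministic.
#'
#' @param m CPM [expression_matrix()].
#' @param markers list with `tumor` and `immune` gene vectors.
#' @return named numeric vector of per-cell scores.
#' @export
marker_score <- function(m, markers = default_marker_genes()) {
  E <- log2_cpm1(m)
  tg <- intersect(markers$tumor, rownames(E))
  ig <- intersect(markers$immune, rownames(E))
  if (length(tg) == 0L || length(ig) == 0L)
    stop("marker lists share no genes with the matrix")
  colMeans(E[tg, , drop = FALSE]) - colMeans(E[ig, , drop = FALSE])
}

#' @rdname marker_score
#' @param labels cluster labels from [cluster_cells()].
#' @return `immune_majority_cluster`: the label of the cluster with the
#'   highest mean immune-marker expression.
#' @export
immune_majority_cluster <- function(m, labels, markers = default_marker_genes()) {
  E <- log2_cpm1(m)
  ig <- intersect(markers$immune, rownames(E))
  if (length(ig) == 0L) stop("no immune markers present in the matrix")
  imm <- colMeans(E[ig, , drop = FALSE])
  means <- tapply(imm[names(labels)], labels, mean)
  as.integer(names(means)[which.max(means)])
}

#' Integrate the four evidence sources into a per-cell verdict
#'
#' Applies a deterministic decision table to the four votes.  A cell is
#' \strong{neoplastic} when it carries mutational tumor evidence — a CNV
#' called present or at least one detected somatic SNV — and its germline
#' allele pattern does not contradict (no biallelic site inside a
#' copy-number-loss segment that was called present in that cell).  It is
#' \strong{non_neoplastic} when every CNV segment is cleanly absent, no
#' somatic SNV is detected, the germline pattern is biallelic or
#' uninformative, and the cell sits in the immune-majority cluster.
#' Everything else is \strong{ambiguous}.  Contradictory strong evidence
#' (a detected somatic SNV together with a biallelic site in a
#' present-called loss) is flagged as a conflict, never resolved silently.
#' Clustering is corroborative only: it can confirm non_neoplastic but
#' never alone makes a cell neoplastic, because expression clustering
#' mixes stochastically.
#'
#' @param evidence data.frame with one row per cell and columns
#'   `cell_id`, `cnv_vote` (`supports_tumor`/`supports_normal`/
#'   `uninformative`), `somatic_n` (integer), `germline_summary`
#'   (`biallelic_observed`/`monoallelic_consistent`/`uninformative`),
#'   `biallelic_in_present_loss` (logical), `in_immune_cluster` (logical).
#' @return data.frame: `cell_id`, `class`, the four votes, `conflict`,
#'   `rationale`.
#' @export
integrate_evidence <- function(evidence) {
  need <- c("cell_id", "cnv_vote", "somatic_n", "germline_summary",
            "biallelic_in_present_loss", "in_immune_cluster")
  if (!all(need %in% names(evidence)))
    stop("evidence needs columns ", paste(need, collapse = ", "))
  stopifnot(all(evidence$cnv_vote %in%
                  c("supports_tumor", "supports_normal", "uninformative")),
            all(evidence$germline_summary %in%
                  c("biallelic_observed", "monoallelic_consistent",
                    "uninformative")))
  n <- nrow(evidence)
  class <- character(n); conflict <- logical(n); rationale <- character(n)
  for (i in seq_len(n)) {
    e <- evidence[i, ]
    mut_tumor <- e$cnv_vote == "supports_tumor" || e$somatic_n >= 1
    contradicts <- isTRUE(e$biallelic_in_present_loss)
    if (e$somatic_n >= 1 && contradicts) {
      class[i] <- "ambiguous"; conflict[i] <- TRUE
      rationale[i] <- "conflict: somatic SNV detected but both germline alleles expressed in a loss segment called present"
    } else if (mut_tumor && !contradicts) {
      class[i] <- "neoplastic"
      rationale[i] <- paste0(
        if (e$cnv_vote == "supports_tumor") "CNV present" else NULL,
        if (e$cnv_vote == "supports_tumor" && e$somatic_n >= 1) "; " else "",
        if (e$somatic_n >= 1)
          sprintf("%d expressed somatic SNV(s)", e$somatic_n) else "")
    } else if (e$cnv_vote == "supports_normal" && e$somatic_n == 0 &&
               e$germline_summary %in% c("biallelic_observed", "uninformative") &&
               isTRUE(e$in_immune_cluster)) {
      class[i] <- "non_neoplastic"
      rationale[i] <- "all CNV segments absent; no somatic SNV; germline pattern compatible; immune-majority cluster"
    } else {
      class[i] <- "ambiguous"
      conflict[i] <- contradicts
      rationale[i] <- if (contradicts)
        "CNV called present but both germline alleles expressed in the loss segment"
      else "evidence insufficient or mixed"
    }
  }
  data.frame(cell_id = evidence$cell_id, class = class,
             cnv_vote = evidence$cnv_vote,
             germline_vote = evidence$germline_summary,
             somatic_vote = evidence$somatic_n,
             cluster_vote = ifelse(evidence$in_immune_cluster, "immune", "tumor"),
             conflict = conflict, rationale = rationale,
             stringsAsFactors = FALSE)
}
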