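#' Set similarity for ranked-list comparison
#'
#' The overlap coefficient `|X ∩ Y| / min(|X|, |Y|)` corrects the
#' Jaccard index `|X ∩ Y| / |X ∪ Y|` for set-size imbalance, which
#' matters when methods report very different numbers of interactions.
#' Both are 0 when the relevant denominator is empty.
#'
#' @param x,y vectors treated as sets (duplicates ignored).
#' @param kind `"overlap"` or `"jaccard"`.
#' @return value in \[0, 1\].
#' @export
set_similarity <- function(x, y, kind = c("overlap", "jaccard")) {
  kind <- match.arg(kind)
  x <- unique(x); y <- unique(y)
  inter <- length(intersect(x, y))
  if (kind == "overlap") {
    denom <- min(length(x), length(y))
  } else {
    denom <- length(union(x, y))
  }
  if (denom == 0) return(0)
  inter / denom
}

#' Pairwise overlap coefficients of top-N list heads
#'
#' Each named ranked list is truncated to its first `top_n` elements
#' and all pairs are compared with the overlap coefficient. Symmetric;
#' diagonal 1 for nonempty lists.
#'
#' @param ranked_lists named list of ordered vectors (e.g.
#'   "cell type|receptor" keys, best first).
#' @param top_n truncation depth (>= 1).
#' @return named square matrix.
#' @export
overlap_matrix <- function(ranked_lists, top_n) {
  stopifnot(top_n >= 1, length(ranked_lists) >= 1)
  heads <- lapply(ranked_lists, function(l) utils::head(l, top_n))
  k <- length(heads)
  out <- matrix(0, k, k, dimnames = list(names(heads), names(heads)))
  for (i in seq_len(k)) for (j in seq_len(k))
    out[i, j] <- set_similarity(heads[[i]], heads[[j]], "overlap")
  out
}

#' Connectivity score of a gene set against a ranked reference
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment: walking down the
#' reference ranking, the sum gains `1/|hits|` at each member of
#' `up_genes` and loses `1/|misses|` elsewhere; the score is the signed
#' maximum deviation, positive when the gene set concentrates at the
#' top of the ranking. Used to ask whether genes upregulated in one
#' response list are also upregulated in another without distributional
#' assumptions.
#'
#' @param up_genes character vector of genes of interest.
#' @param reference_ranking ordered gene vector (most upregulated
#'   first).
#' @return score in \[-1, 1\]; `NA` (with a warning) when the sets do
#'   not overlap.
#' @export
connectivity_score <- function(up_genes, reference_ranking) {
  hits <- reference_ranking %in% up_genes
  nh <- sum(hits)
  nm <- length(reference_ranking) - nh
  if (nh == 0 || nm == 0) {
    warning("gene set and reference ranking do not usefully overlap")
    return(NA_real_)
  }
  step <- ifelse(hits, 1 / nh, -1 / nm)
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

#' Compare matched vs all connectivity scores
#'
#' One-sided Mann-Whitney (Wilcoxon rank-sum) test that the matched
#' subgroup's scores are stochastically larger than the full
#' distribution.
#'
#' @param scores_all numeric vector (all comparisons).
#' @param scores_matched numeric vector (receptor- and cell-type-matched
#'   subset).
#' @return list: `p` (one-sided), `median_all`, `median_matched`,
#'   `degenerate` (TRUE when both groups are identical constants).
#' @export
matched_vs_all <- function(scores_all, scores_matched) {
  stopifnot(length(scores_all) > 0, length(scores_matched) > 0)
  degenerate <- length(unique(c(scores_all, scores_matched))) == 1
  p <- if (degenerate) 0.5 else
    suppressWarnings(stats::wilcox.test(scores_matched, scores_all,
                                        alternative = "greater")$p.value)
  list(p = p, median_all = stats::median(scores_all),
       median_matched = stats::median(scores_matched),
       degenerate = degenerate)
}

#' Cell-type matching groups for external response validation
#'
#' Lineage-level groups used to call a predicted response and an
#' external cytokine-response experiment "roughly matched": two cell
#' types match when they fall in the same group. Editable via the
#' `groups` argument of [is_matched_cell_type()].
#'
#' @return named list of character vectors.
#' @export
default_matching_groups <- function() {
  list(
    epithelial_stromal = c("tumour", "tumor", "epithelial", "fibroblast"),
    myeloid = c("macrophage", "mMDSC", "pDC", "cDC", "PMN", "Gr-MDSC",
                "monocyte", "neutrophil"),
    lymphoid = c("T cell", "B cell", "NK cell"))
}

#' Are two cell types in the same lineage group?
#'
#' @param a,b cell type labels.
#' @param groups named list of label vectors; default
#'   [default_matching_groups()]. Matching is case-insensitive.
#' @return logical.
#' @export
is_matched_cell_type <- function(a, b, groups = default_matching_groups()) {
  for (g in groups) {
    gl <- tolower(g)
    if (tolower(a) %in% gl && tolower(b) %in% gl) return(TRUE)
  }
  FALSE
}

#' Upregulated response genes for external validation
#'
#' The gene set compared against external cytokine-response rankings:
#' genes with a positive target-test log2FC that are also
#' condition-specific (interaction-test FDR below `fdr_cut`).
#'
#' @param target_slice [target_test()] rows for one
#'   (receptor, cell type).
#' @param inter_slice matching [interaction_test()] rows.
#' @param fdr_cut interaction FDR threshold (default 0.05).
#' @return character vector of gene ids.
#' @export
upregulated_response_genes <- function(target_slice, inter_slice,
                                       fdr_cut = 0.05) {
  sig <- inter_slice$gene[!is.na(inter_slice$fdr) &
                            inter_slice$fdr < fdr_cut]
  up <- target_slice$gene[!is.na(target_slice$log2fc) &
                            target_slice$log2fc > 0]
  intersect(up, sig)
}
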