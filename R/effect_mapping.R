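#' One-vs-rest subcluster markers
#'
#' For each subcluster of a cell type, a hurdle LRT of every gene on a
#' membership indicator (`Y ~ CDR + member` vs `Y ~ CDR`), yielding the
#' per-subcluster log2 fold change and BH FDR used to map inferred
#' ligand effects onto subpopulations. Singleton subclusters are
#' skipped with a warning.
#'
#' @param ds [ExpressionDataset()] with a `subcluster` annotation.
#' @param cell_type cell type whose subclusters are profiled.
#' @param genes genes to test; default all genes detected in at least
#'   `min_detect_frac` of the cell type's cells.
#' @param min_detect_frac detection filter (default 0.01).
#' @param log2fc_mode passed to [hurdle_log2fc()].
#' @return data.frame: `cell_type`, `subcluster`, `gene`, `chisq`,
#'   `df`, `p`, `log2fc`, `fdr`, `status`.
#' @export
cluster_markers <- function(ds, cell_type, genes = NULL,
                            min_detect_frac = 0.01,
                            log2fc_mode = "combined") {
  idx <- which(ds$cells$cell_type == cell_type)
  subs <- ds$cells$subcluster[idx]
  if (length(unique(subs)) < 2)
    stop("need >= 2 subclusters in ", cell_type)
  if (is.null(genes)) genes <- .testable_genes(ds, idx, min_detect_frac)
  sub_ln <- as.matrix(ds$lognorm[idx, genes, drop = FALSE])
  out <- list()
  for (s in sort(unique(subs))) {
    member <- as.numeric(subs == s)
    if (sum(member) < 2) {
      warning("subcluster ", s, " has fewer than 2 cells; skipped")
      next
    }
    cov <- data.frame(cdr = ds$cells$cdr[idx], member = member)
    X_full <- stats::model.matrix(~ cdr + member, cov)
    X_red <- stats::model.matrix(~ cdr, cov)
    res <- .hurdle_test_genes(sub_ln, genes, X_full, X_red,
                              contrast_col = "member",
                              log2fc_mode = log2fc_mode)
    out[[s]] <- cbind(data.frame(cell_type = cell_type, subcluster = s,
                                 stringsAsFactors = FALSE), res)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Map a transcriptional response onto subclusters
#'
#' Dot product between a response-score row and each subcluster's
#' marker log2FC vector, with marker log2FCs zeroed when not
#' significant (FDR > `fdr_cut`). Raw dot products are standardized by
#' the maximum over subclusters; subclusters with standardized score
#' strictly greater than `assign_cut` are assigned (several may be).
#' When no raw dot product is positive, nothing is assigned.
#'
#' @param score_row named numeric vector of response scores (one
#'   response-matrix row).
#' @param markers [cluster_markers()] table for the target cell type.
#' @param fdr_cut marker significance mask (default 0.15).
#' @param assign_cut assignment threshold on the standardized score
#'   (default 0.5, strict inequality).
#' @return data.frame: `subcluster`, `raw`, `standardized`, `assigned`.
#' @export
map_response_to_subclusters <- function(score_row, markers, fdr_cut = 0.15,
                                        assign_cut = 0.5) {
  genes <- intersect(names(score_row), unique(markers$gene))
  subs <- sort(unique(markers$subcluster))
  raw <- vapply(subs, function(s) {
    sl <- markers[markers$subcluster == s, , drop = FALSE]
    l2fc <- sl$log2fc[match(genes, sl$gene)]
    l2fc[is.na(l2fc)] <- 0
    fdr <- sl$fdr[match(genes, sl$gene)]
    l2fc[is.na(fdr) | fdr > fdr_cut] <- 0
    sum(score_row[genes] * l2fc)
  }, numeric(1))
  mx <- max(raw)
  if (mx > 0) {
    std <- raw / mx
    assigned <- std > assign_cut
  } else {
    std <- rep(NA_real_, length(raw))
    assigned <- rep(FALSE, length(raw))
  }
  data.frame(subcluster = subs, raw = raw, standardized = std,
             assigned = assigned, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Assign a ligand to donor subclusters
#'
#' A ligand belongs to the subclusters in which it is positively
#' enriched against the rest of the donor cell type: one-vs-rest
#' log2FC > 0 at FDR < `fdr_cut`.
#'
#' @param ligand gene id.
#' @param markers [cluster_markers()] table for the donor cell type.
#' @param fdr_cut enrichment threshold (default 0.15).
#' @return character vector of subcluster ids (possibly empty).
#' @export
assign_ligand_to_subclusters <- function(ligand, markers, fdr_cut = 0.15) {
  sl <- markers[markers$gene == ligand, , drop = FALSE]
  if (!nrow(sl)) {
    warning("ligand not in marker table: ", ligand)
    return(character(0))
  }
  sort(sl$subcluster[!is.na(sl$fdr) & sl$fdr < fdr_cut & sl$log2fc > 0])
}
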