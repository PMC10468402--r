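#' @title Condition-dependent interaction testing
#' @description
#' The inference core: every putative ligand-receptor interaction is
#' decomposed into per-gene hurdle likelihood-ratio tests run within the
#' receptor-expressing ("target") cell type. The *target test* asks
#' whether a gene's expression differs between receptor-detected
#' (target+) and receptor-null cells; the *interaction test* asks
#' whether that difference is itself condition-specific, which is what
#' separates genuine ligand effects from genes merely co-expressed with
#' the receptor; the *ligand condition test* asks whether the cognate
#' ligand is differentially available across conditions in a donor cell
#' type.
#' @name interaction-tests
NULL

# Genes testable in a cell subset: detected in >= min_detect_frac of it.
.testable_genes <- function(ds, idx, min_detect_frac) {
  sub <- ds$counts[idx, , drop = FALSE]
  frac <- as.numeric(Matrix::colSums(sub > 0)) / nrow(sub)
  ds$genes[frac >= min_detect_frac]
}

.condition_factor <- function(x) factor(x, levels = sort(unique(x)))

#' Target test: receptor-conditioned differential expression
#'
#' Within one cell type, fits for every gene the hurdle model
#' `Y ~ CDR + condition + target` against the reduced
#' `Y ~ CDR + condition`, where `target` indicates cells with at least
#' one receptor molecule detected. Significant genes differ between
#' receptor-expressing and receptor-null cells; the condition covariate
#' uses all levels present. FDR is Benjamini-Hochberg within the slice.
#'
#' @param ds [ExpressionDataset()].
#' @param receptor gene (or complex pseudo-gene) id defining target
#'   status.
#' @param target_cell_type cell type to test within.
#' @param genes genes to test; default all genes detected in at least
#'   `min_detect_frac` of the cell type's cells.
#' @param min_cells minimum cells in the cell type (default 20).
#' @param min_detect_frac per-slice gene detection filter (default 0.01).
#' @param log2fc_mode passed to [hurdle_log2fc()].
#' @return data.frame: `receptor`, `cell_type`, `gene`, `chisq`, `df`,
#'   `p`, `log2fc`, `fdr`, `status`; zero rows (with a warning) when all
#'   cells are target+ or all target-.
#' @export
target_test <- function(ds, receptor, target_cell_type, genes = NULL,
                        min_cells = 20, min_detect_frac = 0.01,
                        log2fc_mode = "combined") {
  idx <- which(ds$cells$cell_type == target_cell_type)
  empty <- data.frame(receptor = character(), cell_type = character(),
                      gene = character(), chisq = numeric(), df = integer(),
                      p = numeric(), log2fc = numeric(), fdr = numeric(),
                      status = character(), stringsAsFactors = FALSE)
  if (length(idx) < min_cells) {
    warning("fewer than ", min_cells, " cells of type ", target_cell_type)
    return(empty)
  }
  if (!receptor %in% ds$genes) stop("receptor not in dataset: ", receptor)
  tgt <- as.numeric(ds$counts[idx, receptor] > 0)
  if (all(tgt == 1) || all(tgt == 0)) {
    warning("all cells are target", if (all(tgt == 1)) "+" else "-",
            " for ", receptor, " in ", target_cell_type, "; test skipped")
    return(empty)
  }
  if (is.null(genes)) genes <- .testable_genes(ds, idx, min_detect_frac)
  cov <- data.frame(cdr = ds$cells$cdr[idx],
                    condition = .condition_factor(ds$cells$condition[idx]),
                    target = tgt)
  f_full <- if (nlevels(cov$condition) > 1) ~ cdr + condition + target
            else ~ cdr + target
  f_red <- if (nlevels(cov$condition) > 1) ~ cdr + condition else ~ cdr
  X_full <- stats::model.matrix(f_full, cov)
  X_red <- stats::model.matrix(f_red, cov)
  sub <- as.matrix(ds$lognorm[idx, genes, drop = FALSE])
  res <- .hurdle_test_genes(sub, genes, X_full, X_red,
                            contrast_col = "target",
                            log2fc_mode = log2fc_mode)
  cbind(data.frame(receptor = receptor, cell_type = target_cell_type,
                   stringsAsFactors = FALSE), res)
}

#' Ligand condition test: differential ligand availability
#'
#' Tests, within a donor cell type, whether each candidate ligand is
#' differentially expressed between the two levels of a contrast, with
#' the hurdle model `Y ~ CDR + condition` against `Y ~ CDR`. Reported
#' log2 fold changes are signed so positive means higher in the first
#' (numerator) contrast level. FDR is computed across the ligands
#' tested together in this donor type.
#'
#' @param ds [ExpressionDataset()].
#' @param ligands character vector of ligand gene ids to test.
#' @param donor_cell_type donor cell type.
#' @param contrast length-2 character: `c(numerator_level,
#'   denominator_level)`.
#' @param min_cells minimum donor cells (default 20).
#' @param log2fc_mode passed to [hurdle_log2fc()].
#' @return data.frame: `ligand`, `cell_type`, `level_hi`, `level_lo`,
#'   `chisq`, `df`, `p`, `log2fc`, `fdr`, `status`.
#' @export
ligand_condition_test <- function(ds, ligands, donor_cell_type, contrast,
                                  min_cells = 20, log2fc_mode = "combined") {
  stopifnot(length(contrast) == 2)
  present <- unique(ds$cells$condition[ds$cells$cell_type == donor_cell_type])
  missing_lvl <- setdiff(contrast, present)
  if (length(missing_lvl))
    stop("condition level(s) absent in ", donor_cell_type, ": ",
         paste(missing_lvl, collapse = ", "))
  idx <- which(ds$cells$cell_type == donor_cell_type &
               ds$cells$condition %in% contrast)
  ligands <- intersect(ligands, ds$genes)
  if (length(idx) < min_cells || length(ligands) == 0)
    return(data.frame(ligand = character(), cell_type = character(),
                      level_hi = character(), level_lo = character(),
                      chisq = numeric(), df = integer(), p = numeric(),
                      log2fc = numeric(), fdr = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  # indicator coding: 1 = numerator level, so log2fc > 0 means higher there
  cov <- data.frame(cdr = ds$cells$cdr[idx],
                    hi = as.numeric(ds$cells$condition[idx] == contrast[1]))
  X_full <- stats::model.matrix(~ cdr + hi, cov)
  X_red <- stats::model.matrix(~ cdr, cov)
  sub <- as.matrix(ds$lognorm[idx, ligands, drop = FALSE])
  res <- .hurdle_test_genes(sub, ligands, X_full, X_red, contrast_col = "hi",
                            log2fc_mode = log2fc_mode)
  names(res)[names(res) == "gene"] <- "ligand"
  cbind(data.frame(cell_type = donor_cell_type, level_hi = contrast[1],
                   level_lo = contrast[2], stringsAsFactors = FALSE),
        res)[, c("ligand", "cell_type", "level_hi", "level_lo", "chisq",
                 "df", "p", "log2fc", "fdr", "status")]
}

#' Interaction test: condition-specific response to receptor engagement
#'
#' Restricted to the two levels of one contrast, fits for every gene
#' `Y ~ CDR + condition + target + target:condition_of_interest`
#' against the model without the interaction indicator, where the
#' indicator marks cells that are both target+ and from
#' `condition_of_interest`. A significant gene responds to receptor
#' engagement differently across conditions — the signature of a
#' ligand effect under condition-specific ligand availability, and the
#' property receptor-correlated confounders lack.
#'
#' @param ds [ExpressionDataset()].
#' @param receptor receptor gene id.
#' @param target_cell_type cell type to test within.
#' @param contrast length-2 character `c(condition_of_interest, other)`;
#'   cells from other conditions are excluded.
#' @param genes,min_cells,min_detect_frac,log2fc_mode as [target_test()].
#' @return data.frame: `receptor`, `cell_type`, `condition_of_interest`,
#'   `level_lo`, `gene`, `chisq`, `df`, `p`, `log2fc`, `fdr`, `status`.
#' @export
interaction_test <- function(ds, receptor, target_cell_type, contrast,
                             genes = NULL, min_cells = 20,
                             min_detect_frac = 0.01,
                             log2fc_mode = "combined") {
  stopifnot(length(contrast) == 2)
  if (contrast[1] == contrast[2])
    stop("condition_of_interest must differ from the comparison level")
  idx <- which(ds$cells$cell_type == target_cell_type &
               ds$cells$condition %in% contrast)
  empty <- data.frame(receptor = character(), cell_type = character(),
                      condition_of_interest = character(),
                      level_lo = character(), gene = character(),
                      chisq = numeric(), df = integer(), p = numeric(),
                      log2fc = numeric(), fdr = numeric(),
                      status = character(), stringsAsFactors = FALSE)
  if (length(idx) < min_cells) {
    warning("fewer than ", min_cells, " cells for ", target_cell_type)
    return(empty)
  }
  cond <- ds$cells$condition[idx]
  if (length(unique(cond)) < 2)
    stop("only one condition level present (", unique(cond),
         "); the interaction indicator would be aliased with target")
  if (!receptor %in% ds$genes) stop("receptor not in dataset: ", receptor)
  tgt <- as.numeric(ds$counts[idx, receptor] > 0)
  if (all(tgt == 1) || all(tgt == 0)) {
    warning("all cells share target status for ", receptor, "; test skipped")
    return(empty)
  }
  if (is.null(genes)) genes <- .testable_genes(ds, idx, min_detect_frac)
  cov <- data.frame(cdr = ds$cells$cdr[idx],
                    condition = .condition_factor(cond),
                    target = tgt)
  cov$inter <- as.numeric(cov$target == 1 & cond == contrast[1])
  X_full <- stats::model.matrix(~ cdr + condition + target + inter, cov)
  X_red <- stats::model.matrix(~ cdr + condition + target, cov)
  sub <- as.matrix(ds$lognorm[idx, genes, drop = FALSE])
  res <- .hurdle_test_genes(sub, genes, X_full, X_red, contrast_col = "inter",
                            log2fc_mode = log2fc_mode)
  cbind(data.frame(receptor = receptor, cell_type = target_cell_type,
                   condition_of_interest = contrast[1],
                   level_lo = contrast[2], stringsAsFactors = FALSE), res)
}

#' Summarize interactions against the significance rule
#'
#' Combines the three test families into one row per
#' (ligand, donor cell type, receptor, target cell type) tuple and
#' applies the combined significance rule: the interaction is called
#' significant when, for every configured contrast, (1) at least
#' `min_effects` genes pass the interaction test at
#' `fdr_interaction`, (2) the ligand passes the condition test at
#' `fdr_ligand` with `|log2FC| > min_ligand_l2fc` in the donor type,
#' and (3) the ligand log2FC has the same sign in all contrasts. The
#' receptor gene itself is excluded from all effect/DEG counts.
#'
#' @param db [InteractionDatabase()].
#' @param target_res rbind-ed [target_test()] results.
#' @param inter_res rbind-ed [interaction_test()] results; contrasts are
#'   identified by their `condition_of_interest`/`level_lo` columns.
#' @param ligand_res rbind-ed [ligand_condition_test()] results.
#' @param contrasts named list of length-2 character vectors, e.g.
#'   `list(CIN = c("CINhigh", "CINlow"), STING = c("CINhigh", "STINGkd"))`.
#' @param min_effects,fdr_interaction,fdr_ligand,min_ligand_l2fc,fdr_deg
#'   rule thresholds; defaults 10, 0.25, 0.05, 0.12, 0.05.
#' @return data.frame with one row per interaction tuple tested:
#'   identifier columns, per-contrast `n_eff_*`, `lig_l2fc_*`,
#'   `lig_fdr_*`, plus `n_effects` (max over contrasts), `n_degs`
#'   (target-test DEGs) and logical `significant`.
#' @export
summarize_interactions <- function(db, target_res, inter_res, ligand_res,
                                   contrasts, min_effects = 10,
                                   fdr_interaction = 0.25, fdr_ligand = 0.05,
                                   min_ligand_l2fc = 0.12, fdr_deg = 0.05) {
  cn <- names(contrasts)
  rows <- list()
  for (r in seq_len(nrow(db$pairs))) {
    lig <- db$pairs$ligand[r]; rec <- db$pairs$receptor[r]
    donor_types <- unique(ligand_res$cell_type[ligand_res$ligand == lig])
    target_types <- unique(target_res$cell_type[target_res$receptor == rec])
    for (dt in donor_types) for (tt in target_types) {
      row <- list(ligand = lig, donor_type = dt, receptor = rec,
                  target_type = tt)
      ok_all <- length(cn) > 0
      signs <- numeric(0)
      for (nm in cn) {
        hi <- contrasts[[nm]][1]; lo <- contrasts[[nm]][2]
        it <- inter_res[inter_res$receptor == rec &
                        inter_res$cell_type == tt &
                        inter_res$condition_of_interest == hi &
                        inter_res$level_lo == lo, , drop = FALSE]
        n_eff <- sum(it$fdr < fdr_interaction & it$gene != rec,
                     na.rm = TRUE)
        lt <- ligand_res[ligand_res$ligand == lig &
                         ligand_res$cell_type == dt &
                         ligand_res$level_hi == hi &
                         ligand_res$level_lo == lo, , drop = FALSE]
        l2fc <- if (nrow(lt)) lt$log2fc[1] else NA_real_
        lfdr <- if (nrow(lt)) lt$fdr[1] else NA_real_
        row[[paste0("n_eff_", nm)]] <- n_eff
        row[[paste0("lig_l2fc_", nm)]] <- l2fc
        row[[paste0("lig_fdr_", nm)]] <- lfdr
        ok_all <- ok_all && n_eff >= min_effects &&
          isTRUE(lfdr < fdr_ligand) && isTRUE(abs(l2fc) > min_ligand_l2fc)
        signs <- c(signs, sign(l2fc))
      }
      tr <- target_res[target_res$receptor == rec &
                       target_res$cell_type == tt, , drop = FALSE]
      row$n_degs <- sum(tr$fdr < fdr_deg & tr$gene != rec, na.rm = TRUE)
      row$n_effects <- max(c(0, unlist(row[paste0("n_eff_", cn)])))
      row$significant <- ok_all && length(unique(signs[!is.na(signs)])) <= 1 &&
        !anyNA(signs)
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Rank interaction summaries
#'
#' Stable descending sort on the number of significant interaction
#' effects (max over contrasts), ties broken by the number of
#' target-test DEGs, then by the lexicographic interaction key for
#' determinism.
#'
#' @param summaries output of [summarize_interactions()].
#' @return the same data.frame, reordered; a `rank` column is added.
#' @export
rank_interactions <- function(summaries) {
  if (!nrow(summaries)) return(summaries)
  key <- paste(summaries$ligand, summaries$donor_type, summaries$receptor,
               summaries$target_type)
  ord <- order(-summaries$n_effects, -summaries$n_degs, key,
               method = "radix")
  out <- summaries[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Build the transcriptional response matrix
#'
#' One row per (receptor, target cell type) slice of the target test;
#' one column per gene. Entries are the signed response score
#' `-log10(P_bonf) x log2FC`, where `P_bonf` is the Bonferroni-adjusted
#' target-test p-value within the slice's tested-gene family. Untested
#' genes and genes with adjusted p = 1 score zero.
#'
#' @param target_res rbind-ed [target_test()] results.
#' @param genes column universe; default the union of tested genes.
#' @return object of class `ResponseScoreMatrix`: list with `scores`
#'   (rows x genes matrix, rownames `receptor|cell_type`), `row_info`
#'   (receptor, cell_type, all_zero flag), and `pc_embedding`, `dc1`,
#'   `n_pcs` slots filled by [embed_responses()].
#' @export
build_response_matrix <- function(target_res, genes = NULL) {
  stopifnot(nrow(target_res) > 0)
  if (is.null(genes)) genes <- sort(unique(target_res$gene))
  keys <- unique(target_res[c("receptor", "cell_type")])
  scores <- matrix(0, nrow(keys), length(genes),
                   dimnames = list(paste(keys$receptor, keys$cell_type,
                                         sep = "|"), genes))
  for (i in seq_len(nrow(keys))) {
    sl <- target_res[target_res$receptor == keys$receptor[i] &
                     target_res$cell_type == keys$cell_type[i], , drop = FALSE]
    pb <- adjust_pvalues(sl$p, "bonferroni")
    sc <- -log10(pmax(pb, 1e-300)) * sl$log2fc
    sc[is.na(sc)] <- 0
    scores[i, match(sl$gene, genes)] <- sc
  }
  keys$all_zero <- apply(scores, 1, function(r) all(r == 0))
  rownames(keys) <- NULL
  structure(list(scores = scores, row_info = keys, pc_embedding = NULL,
                 dc1 = NULL, n_pcs = NA_integer_),
            class = "ResponseScoreMatrix")
}

#' @export
print.ResponseScoreMatrix <- function(x, ...) {
  cat(sprintf("ResponseScoreMatrix: %d (receptor, cell type) rows x %d genes",
              nrow(x$scores), ncol(x$scores)),
      if (!is.na(x$n_pcs)) sprintf("; %d PCs, DC1 %s", x$n_pcs,
        if (is.null(x$dc1)) "absent" else "present") else "", "\n", sep = "")
  invisible(x)
}

#' Kneepoint of a cumulative-variance curve
#'
#' The index maximizing the perpendicular distance between the curve
#' `(i, c_i)` and the chord joining its endpoints — the standard elbow
#' rule used to pick the PCA dimensionality.
#'
#' @param cumvar nondecreasing numeric vector of cumulative variance
#'   fractions.
#' @return integer index of the knee (1 for curves of length <= 2).
#' @export
kneepoint <- function(cumvar) {
  m <- length(cumvar)
  if (m <= 2) return(1L)
  x <- seq_len(m); y <- cumvar
  dx <- m - 1; dy <- y[m] - y[1]
  # distance from (x,y) to the chord through (1,y1) and (m,ym)
  d <- abs(dy * x - dx * y + dx * y[1] - dy * 1) / sqrt(dx^2 + dy^2)
  which.max(d)
}

#' Embed response-matrix rows (PCA + first diffusion component)
#'
#' Rows are centred and projected onto principal components; the number
#' of components kept is the [kneepoint()] of the cumulative-variance
#' curve. The first diffusion component (DC1) is the leading nontrivial
#' eigenvector of the row-normalized affinity matrix built from a
#' k-nearest-neighbour Gaussian kernel on the PC embedding with
#' per-point adaptive bandwidth (the distance to the ceiling(k/2)-th
#' neighbour). DC1 orders the (receptor, cell type) response states
#' along their principal axis of variation; its sign is fixed so the
#' row with the largest response-score L2 norm is non-negative.
#'
#' @param m [build_response_matrix()] output.
#' @param knn neighbourhood size; default `min(15, rows - 1)`.
#' @return `m` with `pc_embedding`, `n_pcs` and (given >= 3 rows) `dc1`
#'   filled.
#' @export
embed_responses <- function(m, knn = NULL) {
  stopifnot(inherits(m, "ResponseScoreMatrix"))
  S <- m$scores
  nonzero_cols <- colSums(S != 0) > 0
  if (nrow(S) < 3 || sum(nonzero_cols) < 2) {
    warning("need >= 3 rows and >= 2 nonzero columns; embedding skipped")
    return(m)
  }
  pc <- stats::prcomp(S, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  vars <- vars[vars > 1e-12 * vars[1]]
  cumvar <- cumsum(vars) / sum(vars)
  n_pcs <- max(2L, min(kneepoint(cumvar), length(vars)))
  n_pcs <- min(n_pcs, ncol(pc$x))
  E <- pc$x[, seq_len(n_pcs), drop = FALSE]
  m$pc_embedding <- E
  m$n_pcs <- n_pcs

  n <- nrow(E)
  if (is.null(knn)) knn <- min(15L, n - 1L)
  knn <- max(1L, min(knn, n - 1L))
  D <- as.matrix(stats::dist(E))
  sigma <- apply(D, 1, function(d) {
    s <- sort(d[-which.min(d)])[ceiling(knn / 2)]
    max(s, 1e-12)
  })
  W <- exp(-D^2 / outer(sigma, sigma))
  # restrict to the kNN graph (mutualized by symmetrization)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(knn + 1L)]   # self included
    keep[i, nb] <- TRUE
  }
  keep <- keep | t(keep)
  W[!keep] <- 0
  deg <- rowSums(W)
  deg[deg == 0] <- 1
  # symmetric conjugate of the Markov matrix D^-1 W
  Sm <- W / sqrt(outer(deg, deg))
  eg <- eigen(Sm, symmetric = TRUE)
  dc1 <- eg$vectors[, 2] / sqrt(deg)
  ref <- which.max(rowSums(S^2))
  if (dc1[ref] < 0) dc1 <- -dc1
  names(dc1) <- rownames(S)
  m$dc1 <- dc1
  m
}
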