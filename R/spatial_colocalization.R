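#' Construct a spatial dataset
#'
#' Spot-level transcriptomics with per-spot cell-type composition:
#' coordinates in micrometres, a spots x genes expression matrix, and a
#' spots x cell-types probability matrix whose rows sum to one
#' (tolerance 1e-6).
#'
#' @param spots data.frame with `spot_id`, `x_um`, `y_um`.
#' @param expr spots x genes non-negative matrix (rownames = spot ids).
#' @param celltype_prob spots x cell-types matrix of deconvolution
#'   probabilities.
#' @return object of class `SpatialDataset`.
#' @export
SpatialDataset <- function(spots, expr, celltype_prob) {
  stopifnot(all(c("spot_id", "x_um", "y_um") %in% names(spots)),
            nrow(expr) == nrow(spots), nrow(celltype_prob) == nrow(spots))
  if (!all(is.finite(spots$x_um)) || !all(is.finite(spots$y_um)))
    stop("spot coordinates must be finite")
  if (any(celltype_prob < -1e-12) || any(celltype_prob > 1 + 1e-12))
    stop("cell-type probabilities must lie in [0, 1]")
  rs <- rowSums(celltype_prob)
  if (any(abs(rs - 1) > 1e-6))
    stop("cell-type probability rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  expr <- as.matrix(expr)
  celltype_prob <- as.matrix(celltype_prob)
  rownames(expr) <- rownames(celltype_prob) <- spots$spot_id
  structure(list(spots = as.data.frame(spots), expr = expr,
                 celltype_prob = celltype_prob),
            class = "SpatialDataset")
}

#' @export
print.SpatialDataset <- function(x, ...) {
  cat(sprintf("SpatialDataset: %d spots, %d genes, %d cell types\n",
              nrow(x$expr), ncol(x$expr), ncol(x$celltype_prob)))
  invisible(x)
}

# Optionally pool each spot's ligand signal over its radius-neighbourhood
# (inclusive of the focal spot, Euclidean distance on micron coordinates).
.ligand_vector <- function(sp, ligand, radius = NULL) {
  v <- sp$expr[, ligand]
  if (is.null(radius) || radius <= 0) return(v)
  D <- as.matrix(stats::dist(sp$spots[, c("x_um", "y_um")]))
  as.numeric((D <= radius) %*% v)
}

#' Spatial colocalization statistic
#'
#' For an interaction (ligand, receptor, target cell type), the sum
#' over spots of `log1p(ligand expression) x Pr(target cell type) x
#' 1[receptor expressed]`. Large values mean the ligand is abundant
#' exactly where receptor-expressing target cells sit.
#'
#' @param sp [SpatialDataset()].
#' @param ligand,receptor gene ids (columns of `sp$expr`).
#' @param target_cell_type column of `sp$celltype_prob`.
#' @param radius optional pooling radius in micrometres: each spot's
#'   ligand signal is first summed over all spots within `radius`
#'   (inclusive) before scoring.
#' @return non-negative scalar.
#' @export
coloc_statistic <- function(sp, ligand, receptor, target_cell_type,
                            radius = NULL) {
  stopifnot(inherits(sp, "SpatialDataset"))
  for (g in c(ligand, receptor))
    if (!g %in% colnames(sp$expr)) stop("gene not in spatial data: ", g)
  if (!target_cell_type %in% colnames(sp$celltype_prob))
    stop("cell type not in spatial data: ", target_cell_type)
  lig <- .ligand_vector(sp, ligand, radius)
  sum(log1p(lig) * sp$celltype_prob[, target_cell_type] *
        (sp$expr[, receptor] > 0))
}

#' Permutation test for spatial colocalization
#'
#' The ligand expression vector is permuted across spots `n_perm` times
#' (receptor indicator and cell-type probabilities fixed) and the
#' statistic recomputed; the one-sided p-value uses the add-one
#' convention `(1 + #{perm >= observed}) / (1 + n_perm)`, so p is never
#' exactly zero. Deterministic given `seed`. When a pooling radius is
#' used, permutation precedes pooling so the null preserves the
#' neighbourhood structure.
#'
#' @inheritParams coloc_statistic
#' @param n_perm number of permutations (default 100).
#' @param seed integer RNG seed.
#' @return list: `stat` (observed), `p`.
#' @export
permutation_pvalue <- function(sp, ligand, receptor, target_cell_type,
                               n_perm = 100, seed = 1, radius = NULL) {
  stopifnot(n_perm >= 1, nrow(sp$expr) >= 2)
  obs <- coloc_statistic(sp, ligand, receptor, target_cell_type, radius)
  lig0 <- sp$expr[, ligand]
  pool <- NULL
  if (!is.null(radius) && radius > 0) {
    D <- as.matrix(stats::dist(sp$spots[, c("x_um", "y_um")]))
    pool <- (D <= radius) * 1
  }
  w <- sp$celltype_prob[, target_cell_type] * (sp$expr[, receptor] > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    lp <- lig0[sample.int(length(lig0))]
    if (!is.null(pool)) lp <- as.numeric(pool %*% lp)
    if (sum(log1p(lp) * w) >= obs) ge <- ge + 1L
  }
  list(stat = obs, p = (1 + ge) / (1 + n_perm))
}

# Save/restore the global RNG state so seeded internals do not disturb
# the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fraction of top-ranked interactions that colocalize
#'
#' For each N in `top_n_grid`, the fraction of the top-N interactions
#' whose permutation p-value falls below `alpha`.
#'
#' @param sp [SpatialDataset()].
#' @param ranked_interactions data.frame with columns `ligand`,
#'   `receptor`, `target_type`, best first.
#' @param top_n_grid integer vector of list depths.
#' @param radius optional pooling radius (micrometres).
#' @param alpha significance level (default 0.05).
#' @param n_perm,seed passed to [permutation_pvalue()]; interaction i
#'   uses `seed + i` so permutations are independent across
#'   interactions yet reproducible.
#' @return data.frame: `top_n`, `fraction_colocalized`.
#' @export
fraction_colocalized <- function(sp, ranked_interactions, top_n_grid,
                                 radius = NULL, alpha = 0.05, n_perm = 100,
                                 seed = 1) {
  stopifnot(nrow(ranked_interactions) > 0)
  nmax <- min(max(top_n_grid), nrow(ranked_interactions))
  pvals <- vapply(seq_len(nmax), function(i) {
    permutation_pvalue(sp, ranked_interactions$ligand[i],
                       ranked_interactions$receptor[i],
                       ranked_interactions$target_type[i],
                       n_perm = n_perm, seed = seed + i,
                       radius = radius)$p
  }, numeric(1))
  data.frame(
    top_n = top_n_grid,
    fraction_colocalized = vapply(top_n_grid, function(N) {
      N <- min(N, nmax)
      mean(pvals[seq_len(N)] < alpha)
    }, numeric(1)))
}

#' Read a spatial dataset from disk
#'
#' @param spots_path TSV with `spot_id`, `x_um`, `y_um`.
#' @param expr_path CSV, spots x genes, spot ids in the first column.
#' @param prob_path CSV, spots x cell types, spot ids in the first
#'   column.
#' @return [SpatialDataset()].
#' @export
read_spatial <- function(spots_path, expr_path, prob_path) {
  spots <- utils::read.delim(spots_path, stringsAsFactors = FALSE)
  expr <- as.matrix(utils::read.csv(expr_path, row.names = 1,
                                    check.names = FALSE))
  prob <- as.matrix(utils::read.csv(prob_path, row.names = 1,
                                    check.names = FALSE))
  expr <- expr[match(spots$spot_id, rownames(expr)), , drop = FALSE]
  prob <- prob[match(spots$spot_id, rownames(prob)), , drop = FALSE]
  SpatialDataset(spots, expr, prob)
}
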