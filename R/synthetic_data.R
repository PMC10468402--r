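#' Default planted interactions for the synthetic microenvironment
#'
#' Three condition-dependent interactions (the ligand is available only
#' in the first condition, and effect genes respond only there) and
#' three condition-independent ones (the ligand is uniformly available
#' and the associated genes are receptor-correlated confounders present
#' in every condition).
#'
#' @param donor_type,target_type cell type labels.
#' @param n_dependent,n_independent how many of each class.
#' @return data.frame: `ligand`, `donor_type`, `receptor`,
#'   `target_type`, `condition_dependent`.
#' @export
default_interactions <- function(donor_type = "Tumor",
                                 target_type = "Macrophage",
                                 n_dependent = 3, n_independent = 3) {
  k <- n_dependent + n_independent
  data.frame(
    ligand = sprintf("LIG%d", seq_len(k)),
    donor_type = donor_type,
    receptor = sprintf("REC%d", seq_len(k)),
    target_type = target_type,
    condition_dependent = rep(c(TRUE, FALSE), c(n_dependent, n_independent)),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-condition tumour microenvironment
#'
#' Generates negative-binomial counts for several cell types under
#' several conditions, with the statistical structure the interaction
#' tests are designed to detect:
#' \itemize{
#'   \item per-cell size factors (log-normal) produce cellular
#'     detection-rate heterogeneity;
#'   \item each receptor is detected in a configurable fraction of its
#'     target-type cells (bimodal detection), defining target+ status;
#'   \item each condition-dependent interaction's ligand is upregulated
#'     in the donor type under the ligand-available condition (the
#'     first condition by default), and its effect genes are shifted by
#'     `effect_log2fc` only in target+ cells of that condition;
#'   \item condition-independent interactions carry receptor-correlated
#'     confounder genes shifted in target+ cells of every condition,
#'     with a uniformly expressed ligand;
#'   \item every interaction additionally gets `n_confounders`
#'     confounder genes, so the target/interaction contrast is
#'     exercised for dependent interactions too.
#' }
#' Counts are a pure function of the configuration and `seed`.
#'
#' @param conditions condition labels; the first is the
#'   ligand-available condition (default `CINhigh`, `CINlow`,
#'   `STINGkd`).
#' @param cell_types cell type labels (default donor `Tumor`, target
#'   `Macrophage`).
#' @param n_cells cells per (cell type, condition) (default 500, i.e.
#'   1500 cells per type across three conditions).
#' @param n_genes background genes (default 1000); planted genes are a
#'   small fraction of the transcriptome so that library-size
#'   normalization does not absorb the planted shifts, as in real
#'   tissue.
#' @param interactions planted interactions; default
#'   [default_interactions()]. May have zero rows for a pure null
#'   dataset.
#' @param receptor_detect_prob fraction of target-type cells detecting
#'   each receptor (default 0.5).
#' @param ligand_log2fc donor-type ligand fold change (log2) in the
#'   ligand-available condition (default 1.5).
#' @param effect_log2fc planted response fold change (log2) for effect
#'   and confounder genes (default 1).
#' @param n_effect_genes effect genes per condition-dependent
#'   interaction (default 15).
#' @param n_confounders confounder genes per interaction (default 15).
#' @param mean_log_mu,mean_log_sd log-normal parameters of gene base
#'   means (defaults `log(0.5)`, 1.2).
#' @param dispersion negative-binomial dispersion (1/size; default 0.5).
#' @param cdr_sdlog sd of log size factors (default 0.35).
#' @param n_subclusters subclusters assigned (uniformly) within each
#'   cell type (default 2).
#' @param seed integer seed.
#' @return list: `dataset` ([ExpressionDataset()]), `db`
#'   ([InteractionDatabase()] of the planted pairs), `truth` (list with
#'   the interaction table, per-interaction `effect_genes` and
#'   `confounder_genes`, the ligand-available condition and the seed).
#' @export
simulate_tme <- function(conditions = c("CINhigh", "CINlow", "STINGkd"),
                         cell_types = c("Tumor", "Macrophage"),
                         n_cells = 500, n_genes = 1000,
                         interactions = default_interactions(),
                         receptor_detect_prob = 0.5,
                         ligand_log2fc = 1.5, effect_log2fc = 1,
                         n_effect_genes = 15, n_confounders = 15,
                         mean_log_mu = log(0.5), mean_log_sd = 1.2,
                         dispersion = 0.5, cdr_sdlog = 0.35,
                         n_subclusters = 2, seed = 1) {
  stopifnot(length(conditions) >= 2, length(cell_types) >= 2, n_cells >= 10)
  if (nrow(interactions) * (n_effect_genes + n_confounders) > 50 * n_genes)
    stop("planted gene demand inconsistent with n_genes")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  lig_cond <- conditions[1]
  k <- nrow(interactions)
  eff_genes <- list(); cnf_genes <- list()
  gene_ids <- sprintf("BG%04d", seq_len(n_genes))
  for (i in seq_len(k)) {
    id <- paste0(interactions$ligand[i], "_", interactions$receptor[i])
    if (interactions$condition_dependent[i] && n_effect_genes > 0)
      eff_genes[[id]] <- sprintf("EFF%d_%02d", i, seq_len(n_effect_genes))
    if (n_confounders > 0)
      cnf_genes[[id]] <- sprintf("CNF%d_%02d", i, seq_len(n_confounders))
  }
  special <- c(unlist(eff_genes), unlist(cnf_genes),
               unique(interactions$ligand), unique(interactions$receptor))
  genes <- c(gene_ids, special)

  cells <- expand.grid(condition = conditions, cell_type = cell_types,
                       rep = seq_len(n_cells), stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  n <- nrow(cells)
  cells$cell_id <- sprintf("cell%05d", seq_len(n))
  cells$sample_id <- paste0(cells$condition, "_s1")
  cells$subcluster <- paste0("s", 1 + (seq_len(n) %% n_subclusters))

  sf <- exp(stats::rnorm(n, 0, cdr_sdlog))
  base_mu <- exp(stats::rnorm(length(genes), mean_log_mu, mean_log_sd))
  names(base_mu) <- genes
  # planted effect/confounder genes are drawn from the detectable part of
  # the mean distribution: a response planted in a silent gene is not a
  # response any expression-based method could see
  planted <- c(unlist(eff_genes), unlist(cnf_genes))
  base_mu[planted] <- pmin(pmax(base_mu[planted], 0.5), 8)
  size <- 1 / dispersion

  # per-cell x per-gene fold-change factors on top of base means
  fc <- matrix(1, n, length(genes), dimnames = list(NULL, genes))

  # receptors: structural bimodal detection in the target type, silent
  # elsewhere (their counts are drawn separately below)
  receptor_of <- unique(interactions$receptor)

  target_pos <- list()
  rec_counts <- matrix(0L, n, length(receptor_of),
                       dimnames = list(NULL, receptor_of))
  for (r in receptor_of) {
    tt <- interactions$target_type[match(r, interactions$receptor)]
    in_tt <- cells$cell_type == tt
    det <- in_tt & (stats::runif(n) < receptor_detect_prob)
    rec_counts[det, r] <- 1L + stats::rpois(sum(det), 1.5)
    target_pos[[r]] <- det
  }

  for (i in seq_len(k)) {
    id <- paste0(interactions$ligand[i], "_", interactions$receptor[i])
    lig <- interactions$ligand[i]
    rec <- interactions$receptor[i]
    dt <- interactions$donor_type[i]
    in_donor <- cells$cell_type == dt
    # ligands get a healthy base mean so the condition test is informative
    base_mu[lig] <- 2
    fc[!in_donor, lig] <- 0.05          # ligand largely donor-restricted
    if (interactions$condition_dependent[i]) {
      fc[in_donor & cells$condition == lig_cond, lig] <-
        fc[in_donor & cells$condition == lig_cond, lig] * 2^ligand_log2fc
      for (g in eff_genes[[id]]) {
        on <- target_pos[[rec]] & cells$condition == lig_cond
        fc[on, g] <- fc[on, g] * 2^effect_log2fc
      }
    }
    for (g in cnf_genes[[id]])
      fc[target_pos[[rec]], g] <- fc[target_pos[[rec]], g] * 2^effect_log2fc
  }

  mu <- sweep(fc, 2, base_mu, "*") * sf
  counts <- matrix(stats::rnbinom(n * length(genes), mu = mu, size = size),
                   n, length(genes), dimnames = list(cells$cell_id, genes))
  counts[, receptor_of] <- rec_counts
  # guard against all-zero cells (possible at tiny n_genes)
  zero <- rowSums(counts) == 0
  if (any(zero)) counts[zero, 1] <- 1L

  ds <- ExpressionDataset(
    counts,
    cells[, c("cell_id", "cell_type", "condition", "sample_id",
              "subcluster")])
  db <- InteractionDatabase(data.frame(
    ligand = interactions$ligand, receptor = interactions$receptor,
    sources = "synthetic", stringsAsFactors = FALSE))
  truth <- list(interactions = interactions, effect_genes = eff_genes,
                confounder_genes = cnf_genes,
                ligand_available_condition = lig_cond, seed = seed)
  list(dataset = ds, db = db, truth = truth)
}

#' Simulate a spatial transcriptomics layout
#'
#' Spots on a regular grid with micron coordinates. Each colocalized
#' interaction concentrates ligand expression, receptor detection and
#' target cell-type probability inside a randomly placed circular
#' patch; background interactions spread their ligand and receptor
#' uniformly. Cell-type probabilities are Dirichlet draws whose
#' concentration is boosted for the patch's target type, so rows sum
#' to one exactly.
#'
#' @param grid integer 2-vector of grid dimensions (default 12 x 12).
#' @param spacing_um centre-to-centre spot spacing (default 100).
#' @param colocalized data.frame(`ligand`, `receptor`, `target_type`)
#'   of planted colocalized triples.
#' @param background same shape; spatially unstructured triples.
#' @param patch_radius_um patch radius (default 250).
#' @param seed integer seed.
#' @return list: `spatial` ([SpatialDataset()]), `truth` (triples with
#'   a `colocalized` flag).
#' @export
simulate_spatial <- function(grid = c(12, 12), spacing_um = 100,
                             colocalized = data.frame(
                               ligand = "LIG1", receptor = "REC1",
                               target_type = "Macrophage",
                               stringsAsFactors = FALSE),
                             background = data.frame(
                               ligand = "LIG2", receptor = "REC2",
                               target_type = "Tcell",
                               stringsAsFactors = FALSE),
                             patch_radius_um = 250, seed = 1) {
  stopifnot(all(grid >= 2))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  xy <- expand.grid(x_um = (seq_len(grid[1]) - 1) * spacing_um,
                    y_um = (seq_len(grid[2]) - 1) * spacing_um,
                    KEEP.OUT.ATTRS = FALSE)
  n <- nrow(xy)
  spots <- data.frame(spot_id = sprintf("spot%04d", seq_len(n)), xy,
                      stringsAsFactors = FALSE)
  triples <- rbind(cbind(colocalized, colocalized = TRUE),
                   cbind(background, colocalized = FALSE))
  genes <- unique(c(triples$ligand, triples$receptor))
  types <- unique(c(triples$target_type, "Other"))
  expr <- matrix(stats::rpois(n * length(genes), 0.3), n, length(genes),
                 dimnames = list(spots$spot_id, genes))
  alpha <- matrix(1, n, length(types), dimnames = list(NULL, types))
  for (i in seq_len(nrow(triples))) {
    if (triples$colocalized[i]) {
      centre <- xy[sample.int(n, 1), ]
      d <- sqrt((xy$x_um - centre$x_um)^2 + (xy$y_um - centre$y_um)^2)
      inpatch <- d <= patch_radius_um
      expr[inpatch, triples$ligand[i]] <-
        expr[inpatch, triples$ligand[i]] + stats::rpois(sum(inpatch), 5)
      expr[inpatch, triples$receptor[i]] <-
        expr[inpatch, triples$receptor[i]] + 1L +
        stats::rpois(sum(inpatch), 2)
      alpha[inpatch, triples$target_type[i]] <-
        alpha[inpatch, triples$target_type[i]] + 8
    } else {
      expr[, triples$ligand[i]] <- stats::rpois(n, 0.8)
      expr[, triples$receptor[i]] <- stats::rpois(n, 0.8)
    }
  }
  # row-wise Dirichlet via normalized gammas
  g <- matrix(stats::rgamma(n * length(types), shape = alpha), n,
              length(types), dimnames = list(NULL, types))
  prob <- g / rowSums(g)
  list(spatial = SpatialDataset(spots, expr, prob),
       truth = triples)
}

#' Simulate CNV variant profiles
#'
#' Builds per-variant profiles with exactly the requested frequencies
#' and alteration magnitudes. When `deltas` is supplied, per-bin state
#' vectors realizing each delta around the neutral state are
#' constructed; when `states` is supplied, deltas are derived from it.
#'
#' @param freqs variant frequencies (must sum to 1).
#' @param deltas per-variant alteration magnitudes (non-negative
#'   integers), or `NULL` if `states` given.
#' @param states optional list of per-bin state vectors.
#' @param n_bins genomic bins per constructed state vector (default
#'   20).
#' @param neutral_state neutral copy-number state (default 3).
#' @param seed integer seed (used only for the placement of altered
#'   bins).
#' @return [cnv_profiles()] data.frame with a `states` attribute.
#' @export
simulate_cnv <- function(freqs, deltas = NULL, states = NULL, n_bins = 20,
                         neutral_state = 3L, seed = 1) {
  if (abs(sum(freqs) - 1) > 1e-6)
    stop("frequencies must sum to 1 (got ", format(sum(freqs)), ")")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ids <- sprintf("variant%02d", seq_along(freqs))
  if (is.null(states)) {
    stopifnot(!is.null(deltas), length(deltas) == length(freqs))
    states <- lapply(deltas, function(d) {
      dev <- rep(0, n_bins)
      remaining <- d
      b <- 1
      while (remaining > 0) {          # spread the deviation over bins
        step <- min(remaining, 2)
        dev[b] <- dev[b] + step
        remaining <- remaining - step
        b <- b %% n_bins + 1
      }
      sgn <- sample(c(-1, 1), n_bins, replace = TRUE)
      sgn[neutral_state - dev < 0] <- 1   # keep states non-negative
      rep(neutral_state, n_bins) + sgn * dev
    })
  }
  prof <- cnv_profiles(ids, freqs, states = states,
                       neutral_state = neutral_state)
  attr(prof, "states") <- stats::setNames(states, ids)
  prof
}
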