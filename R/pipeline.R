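#' Run the full interaction-testing stage
#'
#' Loops the target, interaction and ligand-condition tests over every
#' receptor and ligand of a database crossed with the dataset's cell
#' types, then summarizes and ranks the interactions. Slices that are
#' untestable (too few cells, receptor never/always detected, ligand
#' absent) are skipped and counted.
#'
#' @param ds [ExpressionDataset()] (after [apply_complex_rule()] when
#'   the database carries complexes).
#' @param db [InteractionDatabase()].
#' @param contrasts named list of length-2 condition vectors, numerator
#'   (condition of interest) first.
#' @param target_types cell types to consider as targets; default all.
#' @param donor_types cell types to consider as donors; default all.
#' @param min_cells,min_detect_frac,log2fc_mode test settings.
#' @param min_effects,fdr_interaction,fdr_ligand,min_ligand_l2fc,fdr_deg
#'   summary-rule thresholds (see [summarize_interactions()]).
#' @return list: `target`, `interaction`, `ligand` result tables,
#'   `summaries`, `ranked`, and `skipped` (count of untestable
#'   slices).
#' @export
run_contact_tracing <- function(ds, db, contrasts,
                                target_types = NULL, donor_types = NULL,
                                min_cells = 20, min_detect_frac = 0.01,
                                log2fc_mode = "combined", min_effects = 10,
                                fdr_interaction = 0.25, fdr_ligand = 0.05,
                                min_ligand_l2fc = 0.12, fdr_deg = 0.05) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            inherits(db, "InteractionDatabase"), length(contrasts) >= 1)
  all_types <- sort(unique(ds$cells$cell_type))
  if (is.null(target_types)) target_types <- all_types
  if (is.null(donor_types)) donor_types <- all_types
  receptors <- intersect(unique(db$pairs$receptor), ds$genes)
  ligands <- intersect(unique(db$pairs$ligand), ds$genes)
  skipped <- 0L

  tgt <- list(); itx <- list(); lig <- list()
  for (tt in target_types) for (r in receptors) {
    res <- withCallingHandlers(
      target_test(ds, r, tt, min_cells = min_cells,
                  min_detect_frac = min_detect_frac,
                  log2fc_mode = log2fc_mode),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!nrow(res)) { skipped <- skipped + 1L; next }
    tgt[[paste(r, tt)]] <- res
    for (nm in names(contrasts)) {
      ir <- withCallingHandlers(
        interaction_test(ds, r, tt, contrasts[[nm]], min_cells = min_cells,
                         min_detect_frac = min_detect_frac,
                         log2fc_mode = log2fc_mode),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!nrow(ir)) { skipped <- skipped + 1L; next }
      itx[[paste(r, tt, nm)]] <- ir
    }
  }
  for (dt in donor_types) for (nm in names(contrasts)) {
    lr <- withCallingHandlers(
      ligand_condition_test(ds, ligands, dt, contrasts[[nm]],
                            min_cells = min_cells,
                            log2fc_mode = log2fc_mode),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!nrow(lr)) { skipped <- skipped + 1L; next }
    lig[[paste(dt, nm)]] <- lr
  }
  target_res <- do.call(rbind, c(tgt, list(make.row.names = FALSE)))
  inter_res <- do.call(rbind, c(itx, list(make.row.names = FALSE)))
  ligand_res <- do.call(rbind, c(lig, list(make.row.names = FALSE)))
  summaries <- summarize_interactions(
    db, target_res, inter_res, ligand_res, contrasts,
    min_effects = min_effects, fdr_interaction = fdr_interaction,
    fdr_ligand = fdr_ligand, min_ligand_l2fc = min_ligand_l2fc,
    fdr_deg = fdr_deg)
  list(target = target_res, interaction = inter_res, ligand = ligand_res,
       summaries = summaries, ranked = rank_interactions(summaries),
       skipped = skipped)
}

#' Export the Circos-style interaction link table
#'
#' One row per interaction passing the link rule (the combined
#' significance rule of [summarize_interactions()]): identifiers, the
#' per-contrast effect counts and ligand fold changes, the DC1
#' coordinates of the receptor and (when present among the response
#' rows) the ligand, the ribbon weight (max effect count over
#' contrasts) and the ribbon colour value (the ligand log2FC of the
#' contrast with the larger |log2FC|). With no significant interaction
#' the table has its columns and zero rows.
#'
#' @param summaries [summarize_interactions()] output.
#' @param response embedded [ResponseScoreMatrix()] (for DC1); may be
#'   `NULL`.
#' @param contrasts the contrast names used in `summaries`.
#' @return data.frame.
#' @export
export_circos_table <- function(summaries, response = NULL, contrasts) {
  cn <- names(contrasts)
  base_cols <- c("ligand", "donor_type", "receptor", "target_type",
                 paste0("n_eff_", cn), paste0("lig_l2fc_", cn),
                 "dc1_ligand", "dc1_receptor", "ribbon_weight",
                 "ribbon_color_value")
  sig <- summaries[which(summaries$significant), , drop = FALSE]
  if (!nrow(sig)) {
    out <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(base_cols)), base_cols))
    out$ligand <- character(0)
    return(out[, base_cols])
  }
  dc1 <- if (!is.null(response)) response$dc1 else NULL
  get_dc1 <- function(gene, type) {
    key <- paste(gene, type, sep = "|")
    if (!is.null(dc1) && key %in% names(dc1)) unname(dc1[key]) else NA_real_
  }
  l2fc_cols <- paste0("lig_l2fc_", cn)
  sig$dc1_ligand <- mapply(get_dc1, sig$ligand, sig$donor_type)
  sig$dc1_receptor <- mapply(get_dc1, sig$receptor, sig$target_type)
  sig$ribbon_weight <- apply(sig[, paste0("n_eff_", cn), drop = FALSE], 1,
                             max)
  sig$ribbon_color_value <- apply(sig[, l2fc_cols, drop = FALSE], 1,
                                  function(v) v[which.max(abs(v))])
  rownames(sig) <- NULL
  sig[, base_cols]
}

#' Run the pipeline end to end from a configuration
#'
#' Executes simulate/load, database filtering, all tests, summaries,
#' response-matrix embedding and the Circos export in order, writing
#' TSV/CSV outputs and a YAML run manifest (seed, thresholds, counts
#' of tests run and skipped) into the output directory. Any stage
#' failure aborts with the stage name.
#'
#' @param config either a YAML file path or an equivalent nested list.
#'   Recognized blocks: `simulate` (arguments of [simulate_tme()]),
#'   or `inputs` (`matrix`, `genes`, `cells`, `annotations`, and
#'   `db`/`db_dialect` paths); `contrasts` (named list of 2-vectors);
#'   `thresholds` (any of `min_effects`, `fdr_interaction`,
#'   `fdr_ligand`, `min_ligand_l2fc`, `fdr_deg`, `min_cells`,
#'   `min_detect_frac`); `out_dir`.
#' @param seed overrides the config's seed when not `NULL`.
#' @return the output directory, invisibly; the manifest is
#'   `manifest.yaml` inside it.
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must name an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  contrasts <- lapply(config$contrasts, unlist)
  if (!length(contrasts)) stop("config must define contrasts")
  th <- config$thresholds
  thv <- function(nm, default) if (!is.null(th[[nm]])) th[[nm]] else default

  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (!is.null(seed)) args$seed <- seed
    conds <- if (!is.null(args$conditions)) args$conditions else
      formals(simulate_tme)$conditions
    bad <- setdiff(unique(unlist(contrasts)), eval(conds))
    if (length(bad))
      stop("contrast level(s) not in configured conditions: ",
           paste(bad, collapse = ", "))
    sim <- stage("simulate", do.call(simulate_tme, args))
    ds <- sim$dataset; db <- sim$db
    used_seed <- if (!is.null(args$seed)) args$seed else
      formals(simulate_tme)$seed
  } else {
    inp <- config$inputs
    ds <- stage("load-expression", read_expression(
      inp$matrix, inp$genes, inp$cells, inp$annotations))
    bad <- setdiff(unique(unlist(contrasts)), unique(ds$cells$condition))
    if (length(bad))
      stop("contrast level(s) not present in the data: ",
           paste(bad, collapse = ", "))
    db <- stage("load-db", load_pair_table(
      inp$db, dialect = if (is.null(inp$db_dialect)) "simple" else
        inp$db_dialect,
      complex_path = inp$db_complexes))
    used_seed <- seed
  }
  if (length(db$complexes))
    ds <- stage("complexes", apply_complex_rule(ds, db$complexes))
  db <- stage("filter-db", filter_interactions(
    db, ds, min_detect_frac = thv("min_detect_frac", 0.01)))

  res <- stage("tests", run_contact_tracing(
    ds, db, contrasts,
    min_cells = thv("min_cells", 20),
    min_detect_frac = thv("min_detect_frac", 0.01),
    min_effects = thv("min_effects", 10),
    fdr_interaction = thv("fdr_interaction", 0.25),
    fdr_ligand = thv("fdr_ligand", 0.05),
    min_ligand_l2fc = thv("min_ligand_l2fc", 0.12),
    fdr_deg = thv("fdr_deg", 0.05)))

  response <- NULL
  if (!is.null(res$target) && nrow(res$target)) {
    response <- stage("response-matrix", {
      m <- build_response_matrix(res$target)
      if (nrow(m$scores) >= 3) m <- embed_responses(m)
      m
    })
  }
  circos <- stage("export", export_circos_table(res$summaries, response,
                                                contrasts))

  wt <- function(x, f) if (!is.null(x))
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(res$target, "target_tests.tsv")
  wt(res$interaction, "interaction_tests.tsv")
  wt(res$ligand, "ligand_tests.tsv")
  wt(res$ranked, "interaction_summary.tsv")
  wt(circos, "circos_links.tsv")
  if (!is.null(response)) {
    utils::write.csv(response$scores,
                     file.path(out_dir, "response_matrix.csv"))
    if (!is.null(response$dc1))
      wt(data.frame(row = names(response$dc1), dc1 = response$dc1),
         "dc1.tsv")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ligandfx")),
    seed = if (is.null(used_seed)) NA else used_seed,
    contrasts = lapply(contrasts, as.list),
    thresholds = list(
      min_cells = thv("min_cells", 20),
      min_detect_frac = thv("min_detect_frac", 0.01),
      min_effects = thv("min_effects", 10),
      fdr_interaction = thv("fdr_interaction", 0.25),
      fdr_ligand = thv("fdr_ligand", 0.05),
      min_ligand_l2fc = thv("min_ligand_l2fc", 0.12),
      fdr_deg = thv("fdr_deg", 0.05)),
    n_interactions_tested = if (is.null(res$summaries)) 0L else
      nrow(res$summaries),
    n_significant = if (is.null(res$summaries) || !nrow(res$summaries)) 0L
      else sum(res$summaries$significant),
    n_skipped_slices = res$skipped)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
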