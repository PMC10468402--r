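#' Construct a ligand-receptor interaction database
#'
#' Records are keyed by the ordered (ligand, receptor) pair; the same
#' genes in reversed roles are a distinct record because directionality
#' matters for the donor/target tests downstream. Ligands or receptors
#' may be multi-gene complexes; complex definitions ride along and are
#' materialized as pseudo-genes by [apply_complex_rule()].
#'
#' @param pairs data.frame with columns `ligand`, `receptor`, `sources`
#'   (comma-separated tag string). Duplicated (ligand, receptor) keys are
#'   merged and their source tags unioned.
#' @param complexes named list: `complex_id -> character vector of >= 2
#'   component genes`.
#' @return object of class `InteractionDatabase`.
#' @export
InteractionDatabase <- function(pairs, complexes = list()) {
  stopifnot(all(c("ligand", "receptor") %in% names(pairs)))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!"sources" %in% names(pairs)) pairs$sources <- ""
  if (nrow(pairs) > 0 &&
      (any(is.na(pairs$ligand)) || any(pairs$ligand == "") ||
       any(is.na(pairs$receptor)) || any(pairs$receptor == "")))
    stop("ligand and receptor identifiers must be non-empty")
  for (cx in names(complexes)) {
    comp <- complexes[[cx]]
    if (anyDuplicated(comp)) stop("complex ", cx, " has duplicate components")
  }
  # dedup on the ordered pair, unioning source tags
  key <- paste(pairs$ligand, pairs$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    src <- vapply(split(pairs$sources, key), function(s)
      paste(sort(unique(unlist(strsplit(s, ",")))), collapse = ","), "")
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    pairs$sources <- unname(src[paste(pairs$ligand, pairs$receptor, sep = "\r")])
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, complexes = complexes),
            class = "InteractionDatabase")
}

#' @export
print.InteractionDatabase <- function(x, ...) {
  cat(sprintf("InteractionDatabase: %d interactions, %d complex definitions\n",
              nrow(x$pairs), length(x$complexes)))
  invisible(x)
}

#' @export
length.InteractionDatabase <- function(x) nrow(x$pairs)

#' Load a ligand-receptor pair table
#'
#' Two dialects are understood. `simple`: a TSV with columns
#' `ligand_gene_symbol` and `receptor_gene_symbol`, one gene per role.
#' `complex`: a CSV with columns `partner_a` (ligand side) and
#' `partner_b` (receptor side) where either partner may name a
#' multi-gene complex defined in a companion composition CSV
#' (`complex_name`, `component_1`, `component_2`, ...).
#'
#' @param path pair table path.
#' @param dialect `"simple"` or `"complex"`.
#' @param complex_path composition CSV (complex dialect only).
#' @param source tag recorded on every loaded record; defaults to the
#'   file name without extension.
#' @return [InteractionDatabase()] with deduplicated records.
#' @export
load_pair_table <- function(path, dialect = c("simple", "complex"),
                            complex_path = NULL, source = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(source)) source <- sub("\\.[^.]+$", "", basename(path))
  if (dialect == "simple") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("ligand_gene_symbol", "receptor_gene_symbol")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("pair table missing column(s): ",
                           paste(miss, collapse = ", "))
    if (nrow(tab) == 0) stop("pair table is empty: ", path)
    if (any(is.na(tab[need])) || any(tab[need] == ""))
      stop("pair table has empty ligand/receptor values")
    pairs <- data.frame(ligand = tab$ligand_gene_symbol,
                        receptor = tab$receptor_gene_symbol,
                        sources = source, stringsAsFactors = FALSE)
    InteractionDatabase(pairs)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(c("partner_a", "partner_b"), names(tab))
    if (length(miss)) stop("pair table missing column(s): ",
                           paste(miss, collapse = ", "))
    if (nrow(tab) == 0) stop("pair table is empty: ", path)
    if (any(is.na(tab[c("partner_a", "partner_b")])) ||
        any(tab[c("partner_a", "partner_b")] == ""))
      stop("pair table has empty ligand/receptor values")
    complexes <- list()
    if (!is.null(complex_path)) {
      comp <- utils::read.csv(complex_path, stringsAsFactors = FALSE)
      if (!"complex_name" %in% names(comp))
        stop("complex composition table missing column: complex_name")
      compcols <- grep("^component_", names(comp), value = TRUE)
      for (r in seq_len(nrow(comp))) {
        members <- unlist(comp[r, compcols], use.names = FALSE)
        members <- members[!is.na(members) & members != ""]
        if (length(members) >= 2)
          complexes[[comp$complex_name[r]]] <- as.character(members)
      }
    }
    pairs <- data.frame(ligand = tab$partner_a, receptor = tab$partner_b,
                        sources = source, stringsAsFactors = FALSE)
    InteractionDatabase(pairs, complexes)
  }
}

#' Merge two interaction databases
#'
#' Set union on the ordered (ligand, receptor) key; records present in
#' both inputs carry the union of source tags. Commutative and
#' associative in the key set, and
#' `|merge(a, b)| = |a| + |b| - |a intersect b|`.
#'
#' @param a,b [InteractionDatabase()] objects over the same gene
#'   namespace.
#' @return merged [InteractionDatabase()]; complex definitions are
#'   combined (first definition wins on collision).
#' @export
merge_databases <- function(a, b) {
  stopifnot(inherits(a, "InteractionDatabase"),
            inherits(b, "InteractionDatabase"))
  pairs <- rbind(a$pairs, b$pairs)
  complexes <- c(a$complexes, b$complexes[setdiff(names(b$complexes),
                                                  names(a$complexes))])
  InteractionDatabase(pairs, complexes)
}

#' Construct an ortholog map
#'
#' @param pairs data.frame with columns `source_symbol`, `dest_symbol`.
#'   Several sources mapping to one destination are permitted; see
#'   `drop_dests`.
#' @param drop_dests destination symbols whose multi-mapped sources are
#'   excluded entirely (interactions removed) instead of averaged.
#' @return object of class `OrthologMap`.
#' @export
OrthologMap <- function(pairs, drop_dests = character()) {
  stopifnot(all(c("source_symbol", "dest_symbol") %in% names(pairs)))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pairs[c("source_symbol", "dest_symbol")]), ,
                 drop = FALSE]
  structure(list(pairs = pairs, drop_dests = as.character(drop_dests)),
            class = "OrthologMap")
}

#' Read an ortholog map from TSV
#'
#' @param path TSV with columns `source_symbol`, `dest_symbol`.
#' @param drop_dests see [OrthologMap()].
#' @return [OrthologMap()].
#' @export
read_ortholog_map <- function(path, drop_dests = character()) {
  OrthologMap(utils::read.delim(path, stringsAsFactors = FALSE), drop_dests)
}

#' Map database genes across species
#'
#' Gene symbols with a one-to-one ortholog entry are renamed to the
#' destination symbol. Symbols without an entry fall back to plain
#' capitalization matching against the expression gene set (the
#' mouse-to-human convention, e.g. Lgals9 -> LGALS9). When several
#' source genes map to one destination, the destination is represented
#' by an averaged pseudo-gene named `avg:<dest>` (its expression is the
#' mean log-normalized expression over the sources, materialized by
#' [apply_ortholog_averages()]) unless the destination is on the map's
#' drop list, in which case every interaction touching it is removed.
#' Genes resolvable by neither route drop their interactions with a
#' warning.
#'
#' @param db [InteractionDatabase()] in the source namespace.
#' @param map [OrthologMap()].
#' @param expression_gene_set character vector of gene ids present in
#'   the destination expression data (used for the capitalization
#'   fallback).
#' @return [InteractionDatabase()] in the destination namespace, with a
#'   `mapping_report` attribute counting genes per mapping class
#'   (`one_to_one`, `capitalized`, `averaged`, `dropped_multi`,
#'   `unmapped`) and an `averages` attribute (named list
#'   `avg:<dest> -> source genes`) for [apply_ortholog_averages()].
#' @export
map_orthologs <- function(db, map, expression_gene_set) {
  stopifnot(inherits(db, "InteractionDatabase"), inherits(map, "OrthologMap"),
            length(expression_gene_set) > 0)
  genes <- unique(c(db$pairs$ligand, db$pairs$receptor))
  genes <- setdiff(genes, names(db$complexes))
  n_sources <- table(map$pairs$dest_symbol)
  multi_dests <- names(n_sources)[n_sources >= 2]
  src_count <- table(map$pairs$source_symbol)

  lookup <- character(0)   # old symbol -> new symbol ("" = drop)
  class_of <- character(0)
  averages <- list()
  for (g in genes) {
    hits <- map$pairs$dest_symbol[map$pairs$source_symbol == g]
    if (length(hits) == 1 && !(hits %in% multi_dests)) {
      lookup[g] <- hits; class_of[g] <- "one_to_one"
    } else if (length(hits) >= 1) {
      # source participates in a multi-mapping (or maps to several dests):
      # route through the first destination's policy
      d <- hits[1]
      if (d %in% map$drop_dests) {
        lookup[g] <- ""; class_of[g] <- "dropped_multi"
      } else {
        pg <- paste0("avg:", d)
        averages[[pg]] <- unique(c(averages[[pg]],
          map$pairs$source_symbol[map$pairs$dest_symbol == d]))
        lookup[g] <- pg; class_of[g] <- "averaged"
      }
    } else if (toupper(g) %in% expression_gene_set) {
      lookup[g] <- toupper(g); class_of[g] <- "capitalized"
    } else {
      lookup[g] <- ""; class_of[g] <- "unmapped"
    }
  }
  if (any(class_of == "unmapped"))
    warning(sum(class_of == "unmapped"),
            " gene(s) had no ortholog or capitalization match; ",
            "their interactions were dropped")

  rename <- function(x) ifelse(x %in% names(lookup), lookup[x], x)
  pairs <- db$pairs
  pairs$ligand <- rename(pairs$ligand)
  pairs$receptor <- rename(pairs$receptor)
  keep <- pairs$ligand != "" & pairs$receptor != ""
  out <- InteractionDatabase(pairs[keep, , drop = FALSE], db$complexes)
  attr(out, "mapping_report") <- table(factor(class_of,
    levels = c("one_to_one", "capitalized", "averaged", "dropped_multi",
               "unmapped")))
  attr(out, "averages") <- averages
  out
}

#' Materialize averaged ortholog pseudo-genes
#'
#' Appends, for each `avg:<dest>` pseudo-gene produced by
#' [map_orthologs()], a column whose log-normalized expression is the
#' arithmetic mean of the source genes' log-normalized expression (and
#' whose counts column is the rounded mean of counts, kept for detection
#' calls).
#'
#' @param ds [ExpressionDataset()].
#' @param averages named list `avg:<dest> -> source genes`, from the
#'   `averages` attribute of [map_orthologs()].
#' @return [ExpressionDataset()] with pseudo-gene columns appended.
#' @export
apply_ortholog_averages <- function(ds, averages) {
  for (pg in names(averages)) {
    comp <- intersect(averages[[pg]], ds$genes)
    if (length(comp) == 0) { warning("no source genes for ", pg); next }
    ln <- Matrix::rowMeans(ds$lognorm[, comp, drop = FALSE])
    ct <- round(Matrix::rowMeans(ds$counts[, comp, drop = FALSE]))
    ds$counts <- cbind(ds$counts, Matrix::Matrix(ct, ncol = 1, sparse = TRUE,
      dimnames = list(NULL, pg)))
    ds$lognorm <- cbind(ds$lognorm, Matrix::Matrix(ln, ncol = 1, sparse = TRUE,
      dimnames = list(NULL, pg)))
  }
  ds$genes <- colnames(ds$counts)
  ds
}

#' Append complex pseudo-genes to an expression dataset
#'
#' A multi-gene complex is scored per cell as the minimum over its
#' component genes, on both the count and log-normalized matrices; a
#' complex is therefore detected in a cell only when every component is.
#' Original gene columns are untouched. Complexes with fewer than two
#' components present in the data are skipped with a warning.
#'
#' @param ds [ExpressionDataset()].
#' @param complexes named list `complex_id -> component genes` (e.g. the
#'   `complexes` element of an [InteractionDatabase()]).
#' @return [ExpressionDataset()] with one pseudo-gene column per usable
#'   complex.
#' @export
apply_complex_rule <- function(ds, complexes) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  for (cx in names(complexes)) {
    comp <- intersect(complexes[[cx]], ds$genes)
    if (length(comp) < 2) {
      warning("complex ", cx, " has <2 resolvable components; skipped")
      next
    }
    if (cx %in% ds$genes) stop("complex id collides with a gene: ", cx)
    cmin <- function(m) {
      v <- m[, comp[1]]
      for (g in comp[-1]) v <- pmin(v, m[, g])
      v
    }
    ds$counts <- cbind(ds$counts, Matrix::Matrix(cmin(ds$counts), ncol = 1,
      sparse = TRUE, dimnames = list(NULL, cx)))
    ds$lognorm <- cbind(ds$lognorm, Matrix::Matrix(cmin(ds$lognorm), ncol = 1,
      sparse = TRUE, dimnames = list(NULL, cx)))
  }
  ds$genes <- colnames(ds$counts)
  ds
}

#' Drop interactions with lowly detected partners
#'
#' Removes every interaction whose ligand or receptor (after complex
#' materialization) is detected in fewer than `min_detect_frac` of all
#' cells. The boundary is inclusive: a gene detected in exactly
#' `min_detect_frac` of cells is retained. Partners absent from the
#' dataset count as undetected.
#'
#' @param db [InteractionDatabase()].
#' @param ds [ExpressionDataset()] (after [apply_complex_rule()] if the
#'   database has complexes).
#' @param min_detect_frac fraction in \[0, 1\]; default 0.01.
#' @return filtered [InteractionDatabase()].
#' @export
filter_interactions <- function(db, ds, min_detect_frac = 0.01) {
  stopifnot(min_detect_frac >= 0, min_detect_frac <= 1)
  detect <- as.numeric(Matrix::colSums(ds$counts > 0)) / nrow(ds$counts)
  names(detect) <- colnames(ds$counts)
  frac <- function(g) ifelse(g %in% names(detect), detect[g], 0)
  keep <- frac(db$pairs$ligand) >= min_detect_frac &
          frac(db$pairs$receptor) >= min_detect_frac
  InteractionDatabase(db$pairs[keep, , drop = FALSE], db$complexes)
}

#' Write an interaction database as TSV
#'
#' @param db [InteractionDatabase()].
#' @param path output TSV (columns ligand, receptor, sources).
#' @return `path`, invisibly.
#' @export
write_interaction_db <- function(db, path) {
  utils::write.table(db$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
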