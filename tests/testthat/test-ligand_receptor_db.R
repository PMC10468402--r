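test_that("simple pair tables load with deduplication and schema checks", {
  tab <- data.frame(ligand_gene_symbol = c("L1", "L2", "L1"),
                    receptor_gene_symbol = c("R1", "R2", "R1"))
  db <- load_pair_table(write_tsv_tmp(tab), "simple", source = "src1")
  expect_equal(length(db), 2L)
  expect_setequal(db$pairs$sources, "src1")

  bad <- data.frame(ligand_gene_symbol = c("L1"), wrong = "R1")
  expect_error(load_pair_table(write_tsv_tmp(bad), "simple"),
               "receptor_gene_symbol")
  empty <- tab[0, ]
  expect_error(load_pair_table(write_tsv_tmp(empty), "simple"), "empty")
})

test_that("complex-aware tables carry complex definitions through", {
  pairs <- data.frame(partner_a = "IFNA1", partner_b = "IFNAR")
  comp <- data.frame(complex_name = "IFNAR", component_1 = "IFNAR1",
                     component_2 = "IFNAR2")
  db <- load_pair_table(write_csv_tmp(pairs), "complex",
                        complex_path = write_csv_tmp(comp), source = "cpdb")
  expect_equal(length(db), 1L)
  expect_equal(db$complexes$IFNAR, c("IFNAR1", "IFNAR2"))
})

test_that("merge is a tag-unioning set union with the printed cardinalities", {
  # synthetic source databases with the sizes and overlap of the mouse
  # and human releases: 1261 + 917 with 293 shared -> 1885;
  # 2348 + 846 with 260 shared -> 2934
  mk <- function(n_a, n_b, n_shared, tag_a, tag_b) {
    shared <- data.frame(ligand = sprintf("SL%d", seq_len(n_shared)),
                         receptor = sprintf("SR%d", seq_len(n_shared)))
    only_a <- data.frame(ligand = sprintf("AL%d", seq_len(n_a - n_shared)),
                         receptor = sprintf("AR%d", seq_len(n_a - n_shared)))
    only_b <- data.frame(ligand = sprintf("BL%d", seq_len(n_b - n_shared)),
                         receptor = sprintf("BR%d", seq_len(n_b - n_shared)))
    a <- InteractionDatabase(cbind(rbind(shared, only_a), sources = tag_a))
    b <- InteractionDatabase(cbind(rbind(shared, only_b), sources = tag_b))
    list(a = a, b = b)
  }
  mouse <- mk(1261, 917, 293, "celltalk", "cellphone")
  expect_equal(length(merge_databases(mouse$a, mouse$b)), 1885L)
  human <- mk(2348, 846, 260, "celltalk", "cellphone")
  expect_equal(length(merge_databases(human$a, human$b)), 2934L)

  m <- merge_databases(mouse$a, mouse$b)
  shared_rows <- m$pairs[startsWith(m$pairs$ligand, "SL"), ]
  expect_true(all(grepl("celltalk", shared_rows$sources) &
                    grepl("cellphone", shared_rows$sources)))
})

test_that("merge is commutative, associative and obeys inclusion-exclusion", {
  set.seed(42)
  mk_rand <- function(tag, n) {
    InteractionDatabase(data.frame(
      ligand = sample(sprintf("L%d", 1:12), n, replace = TRUE),
      receptor = sample(sprintf("R%d", 1:12), n, replace = TRUE),
      sources = tag))
  }
  for (i in 1:5) {
    a <- mk_rand("a", 30); b <- mk_rand("b", 30); c <- mk_rand("c", 30)
    key <- function(db) sort(paste(db$pairs$ligand, db$pairs$receptor))
    expect_equal(key(merge_databases(a, b)), key(merge_databases(b, a)))
    expect_equal(key(merge_databases(merge_databases(a, b), c)),
                 key(merge_databases(a, merge_databases(b, c))))
    n_shared <- length(intersect(key(a), key(b)))
    expect_equal(length(merge_databases(a, b)) + n_shared,
                 length(a) + length(b))
  }
  a <- mk_rand("a", 20)
  self <- merge_databases(a, a)
  expect_equal(length(self), length(a))
})

test_that("ortholog mapping renames, capitalizes, averages and drops", {
  db <- InteractionDatabase(data.frame(
    ligand = c("Lgals9", "Apoe", "H2-K1", "Saa1", "Ghost"),
    receptor = c("Ptprc", "Sdc4", "Cd8a", "Tlr2", "Tlr4"),
    sources = "m"))
  map <- OrthologMap(data.frame(
    source_symbol = c("Apoe", "Sdc4", "Ptprc", "Cd8a", "Tlr2", "Tlr4",
                      "H2-K1", "H2-D1", "Saa1", "Saa2"),
    dest_symbol = c("APOE", "SDC4", "PTPRC", "CD8A", "TLR2", "TLR4",
                    "HLA-A", "HLA-A", "SAA1", "SAA1")),
    drop_dests = "HLA-A")
  expr_genes <- c("LGALS9", "APOE", "SDC4", "PTPRC", "CD8A", "TLR2",
                  "TLR4", "SAA1")
  expect_warning(out <- map_orthologs(db, map, expr_genes), "dropped")
  # capitalization fallback for the unmapped symbol
  expect_true("LGALS9" %in% out$pairs$ligand)
  # drop-listed multi-mapped destination removes its interactions
  expect_false(any(grepl("HLA", out$pairs$ligand)))
  expect_false("Cd8a" %in% out$pairs$receptor)  # that pair is gone entirely
  # multi-mapped destination off the drop list becomes an averaged gene
  expect_true("avg:SAA1" %in% out$pairs$ligand)
  expect_setequal(attr(out, "averages")[["avg:SAA1"]], c("Saa1", "Saa2"))
  # no-ortholog, no-capitalization gene drops its interaction
  expect_false(any(out$pairs$ligand == "Ghost"))
  rep <- attr(out, "mapping_report")
  expect_equal(unname(rep["one_to_one"]), 6L)
  expect_equal(unname(rep["capitalized"]), 1L)
})

test_that("identity ortholog mapping is a no-op", {
  db <- InteractionDatabase(data.frame(ligand = c("A", "B"),
                                       receptor = c("C", "D"),
                                       sources = "s"))
  map <- OrthologMap(data.frame(source_symbol = c("A", "B", "C", "D"),
                                dest_symbol = c("A", "B", "C", "D")))
  out <- map_orthologs(db, map, c("A", "B", "C", "D"))
  expect_equal(out$pairs[order(out$pairs$ligand), c("ligand", "receptor")],
               db$pairs[order(db$pairs$ligand), c("ligand", "receptor")])
})

test_that("complex pseudo-genes take the cell-wise component minimum", {
  counts <- rbind(c(7, 1, 3), c(0, 5, 2), c(4, 4, 4))
  colnames(counts) <- c("IFNAR1", "IFNAR2", "other")
  ds <- make_ds(counts)
  out <- apply_complex_rule(ds, list(IFNAR = c("IFNAR1", "IFNAR2")))
  expect_true("IFNAR" %in% out$genes)
  expect_equal(as.numeric(out$counts[, "IFNAR"]), c(1, 0, 4))
  expect_equal(as.numeric(out$lognorm[, "IFNAR"]),
               pmin(as.numeric(ds$lognorm[, "IFNAR1"]),
                    as.numeric(ds$lognorm[, "IFNAR2"])))
  # single-gene components or unknown genes are skipped with warning
  expect_warning(apply_complex_rule(ds, list(bad = c("IFNAR1", "nope"))),
                 "skipped")
})

test_that("complex values never exceed any component, cell-wise", {
  for (seed in 1:5) {
    ds <- make_ds(rand_counts(20, 6, seed = seed))
    comp <- sample(ds$genes, 3)
    out <- apply_complex_rule(ds, list(CX = comp))
    for (g in comp) {
      expect_true(all(as.numeric(out$lognorm[, "CX"]) <=
                        as.numeric(out$lognorm[, g]) + 1e-12))
    }
  }
})

test_that("low-expression filter is inclusive at the boundary", {
  # gene detected in exactly 10% of 20 cells sits on a 0.1 threshold
  counts <- matrix(0, 20, 3, dimnames = list(NULL, c("L", "R", "pad")))
  counts[1:2, "L"] <- 5       # 2/20 = 0.1 exactly
  counts[, "R"] <- 1
  counts[, "pad"] <- 1
  ds <- make_ds(counts)
  db <- InteractionDatabase(data.frame(ligand = "L", receptor = "R",
                                       sources = "s"))
  expect_equal(length(filter_interactions(db, ds, 0.1)), 1L)
  expect_equal(length(filter_interactions(db, ds, 0.11)), 0L)
  expect_equal(length(filter_interactions(db, ds, 0)), 1L)
  # an absent or never-detected partner removes the interaction
  db2 <- InteractionDatabase(data.frame(ligand = "L", receptor = "gone",
                                        sources = "s"))
  expect_equal(length(filter_interactions(db2, ds, 0.01)), 0L)
})

test_that("mapping then filtering never leaves a gene outside the expression set", {
  set.seed(77)
  for (i in 1:5) {
    src <- sprintf("Gene%d", 1:12)
    db <- InteractionDatabase(data.frame(
      ligand = sample(src, 10, replace = TRUE),
      receptor = sample(src, 10, replace = TRUE), sources = "s"))
    mapped_src <- sample(src, 6)
    map <- OrthologMap(data.frame(source_symbol = mapped_src,
                                  dest_symbol = toupper(mapped_src)))
    expr_genes <- toupper(sample(src, 9))
    counts <- rand_counts(15, length(expr_genes), seed = i)
    colnames(counts) <- expr_genes
    ds <- make_ds(counts)
    out <- suppressWarnings(map_orthologs(db, map, expr_genes))
    out <- filter_interactions(out, ds, 0.01)
    genes_left <- unique(c(out$pairs$ligand, out$pairs$receptor))
    expect_true(all(genes_left %in% expr_genes))
  }
})
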