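# Small planted dataset shared by the slice tests: one dependent
# interaction, modest sizes so the suite stays fast.
local_sim <- local({
  sim <- NULL
  function() {
    if (is.null(sim))
      sim <<- simulate_tme(
        n_genes = 150, n_cells = 150,
        interactions = default_interactions(n_dependent = 1,
                                            n_independent = 0),
        n_effect_genes = 10, n_confounders = 10, seed = 401)
    sim
  }
})

test_that("the receptor itself is significant in its own target test", {
  sim <- local_sim()
  tr <- target_test(sim$dataset, "REC1", "Macrophage")
  self <- tr[tr$gene == "REC1", ]
  expect_equal(nrow(self), 1L)
  expect_lt(self$fdr, 1e-6)      # self-association by construction
  expect_gt(self$log2fc, 0)
})

test_that("target test recovers planted receptor-correlated genes", {
  sim <- local_sim()
  tr <- target_test(sim$dataset, "REC1", "Macrophage")
  cnf <- sim$truth$confounder_genes[["LIG1_REC1"]]
  expect_gt(mean(tr$fdr[match(cnf, tr$gene)] < 0.05, na.rm = TRUE), 0.7)
})

test_that("untestable target slices return empty with a warning", {
  sim <- local_sim()
  # receptors are silent in tumour cells: every cell is target-
  expect_warning(tr <- target_test(sim$dataset, "REC1", "Tumor"),
                 "target")
  expect_equal(nrow(tr), 0L)
})

test_that("ligand condition test signs fold changes toward the numerator", {
  sim <- local_sim()
  lt1 <- ligand_condition_test(sim$dataset, "LIG1", "Tumor",
                               c("CINhigh", "CINlow"))
  expect_lt(lt1$fdr, 0.05)
  expect_gt(lt1$log2fc, 0)
  # flipping the contrast flips the sign
  lt2 <- ligand_condition_test(sim$dataset, "LIG1", "Tumor",
                               c("CINlow", "CINhigh"))
  expect_lt(lt2$log2fc, 0)
  expect_error(ligand_condition_test(sim$dataset, "LIG1", "Tumor",
                                     c("CINhigh", "nope")), "nope")
})

test_that("interaction test needs two condition levels", {
  sim <- local_sim()
  expect_error(interaction_test(sim$dataset, "REC1", "Macrophage",
                                c("CINhigh", "CINhigh")), "differ")
})

test_that("summary rule applies every clause of the significance call", {
  db <- InteractionDatabase(data.frame(ligand = "L", receptor = "R",
                                       sources = "s"))
  mk_inter <- function(n_sig, contrast_hi, contrast_lo) {
    data.frame(receptor = "R", cell_type = "T",
               condition_of_interest = contrast_hi, level_lo = contrast_lo,
               gene = sprintf("g%d", 1:20), chisq = 5, df = 2, p = 0.01,
               log2fc = 1,
               fdr = c(rep(0.01, n_sig), rep(0.9, 20 - n_sig)),
               status = "ok")
  }
  mk_lig <- function(l2fc_cin, l2fc_sting, fdr = 0.01) {
    rbind(data.frame(ligand = "L", cell_type = "D", level_hi = "hi",
                     level_lo = "lo1", chisq = 9, df = 2, p = 1e-4,
                     log2fc = l2fc_cin, fdr = fdr, status = "ok"),
          data.frame(ligand = "L", cell_type = "D", level_hi = "hi",
                     level_lo = "lo2", chisq = 9, df = 2, p = 1e-4,
                     log2fc = l2fc_sting, fdr = fdr, status = "ok"))
  }
  tgt <- data.frame(receptor = "R", cell_type = "T",
                    gene = sprintf("g%d", 1:20), chisq = 5, df = 2,
                    p = 0.01, log2fc = 1, fdr = 0.01, status = "ok")
  contrasts <- list(CIN = c("hi", "lo1"), STING = c("hi", "lo2"))
  inter <- rbind(mk_inter(12, "hi", "lo1"), mk_inter(12, "hi", "lo2"))

  # 12 effects per contrast, ligand +0.5/+0.3 at FDR 0.01 -> significant
  s <- summarize_interactions(db, tgt, inter, mk_lig(0.5, 0.3), contrasts)
  expect_true(s$significant)
  expect_equal(s$n_eff_CIN, 12)

  # 9 effects in one contrast -> below the >=10 clause
  inter9 <- rbind(mk_inter(9, "hi", "lo1"), mk_inter(12, "hi", "lo2"))
  s9 <- summarize_interactions(db, tgt, inter9, mk_lig(0.5, 0.3), contrasts)
  expect_false(s9$significant)

  # opposite ligand signs across contrasts -> rejected
  sflip <- summarize_interactions(db, tgt, inter, mk_lig(0.5, -0.5),
                                  contrasts)
  expect_false(sflip$significant)

  # ligand fold change under the |log2FC| > 0.12 clause -> rejected
  ssmall <- summarize_interactions(db, tgt, inter, mk_lig(0.1, 0.1),
                                   contrasts)
  expect_false(ssmall$significant)

  # ligand not significant -> rejected
  sns <- summarize_interactions(db, tgt, inter,
                                mk_lig(0.5, 0.3, fdr = 0.5), contrasts)
  expect_false(sns$significant)
})

test_that("interactions are ranked by effects, then DEGs, stably", {
  base <- data.frame(
    ligand = c("L1", "L2", "L3", "L4"), donor_type = "D",
    receptor = c("R1", "R2", "R3", "R4"), target_type = "T",
    n_effects = c(15, 12, 12, 3), n_degs = c(100, 50, 80, 10),
    significant = TRUE)
  r <- rank_interactions(base)
  expect_equal(r$receptor, c("R1", "R3", "R2", "R4"))
  # all-equal keys keep input order (stable sort)
  same <- base; same$n_effects <- 5; same$n_degs <- 5
  same$ligand <- "L"; same$receptor <- "R"
  expect_equal(rank_interactions(same)$rank, 1:4)
  one <- base[2, ]
  expect_equal(rank_interactions(one)$receptor, "R2")
})

test_that("response scores multiply -log10 Bonferroni p by log2FC", {
  tgt <- data.frame(
    receptor = "R", cell_type = "T", gene = c("a", "b", "c"),
    chisq = 1, df = 2, p = c(1, 0.005, NA), log2fc = c(3, 2, 5),
    fdr = 0.5, status = c("ok", "ok", "degenerate"))
  m <- build_response_matrix(tgt)
  # p = 1 and untested genes score 0; 0.005 * 2 (Bonferroni, family of
  # 2 non-missing) = 0.01 -> -log10 = 2, times log2FC 2 -> 4
  expect_equal(unname(m$scores[1, c("a", "b", "c")]), c(0, 4, 0))
  # sign flip of log2FC flips the score
  tgt2 <- tgt; tgt2$log2fc <- -tgt2$log2fc
  m2 <- build_response_matrix(tgt2)
  expect_equal(m2$scores, -m$scores)
})

test_that("disjoint per-receptor effects give block-diagonal support", {
  mk <- function(rec, genes_hit) {
    data.frame(receptor = rec, cell_type = "T",
               gene = sprintf("g%d", 1:9), chisq = 1, df = 2,
               p = ifelse(sprintf("g%d", 1:9) %in% genes_hit, 1e-6, 1),
               log2fc = 1, fdr = 0.5, status = "ok")
  }
  tgt <- rbind(mk("R1", c("g1", "g2", "g3")),
               mk("R2", c("g4", "g5", "g6")),
               mk("R3", c("g7", "g8", "g9")))
  m <- build_response_matrix(tgt)
  support <- m$scores != 0
  blocks <- list(1:3, 4:6, 7:9)
  for (i in 1:3) {
    expect_true(all(support[i, blocks[[i]]]))
    expect_false(any(support[i, -blocks[[i]]]))
  }
})

test_that("kneepoint maximizes distance to the chord", {
  cumvar <- c(0.5, 0.8, 0.9, 0.95, 0.98, 1.0)
  k <- kneepoint(cumvar)
  # independent geometric oracle: project each point onto the chord
  m <- length(cumvar)
  p1 <- c(1, cumvar[1]); p2 <- c(m, cumvar[m])
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  d <- vapply(seq_len(m), function(i) {
    v <- c(i, cumvar[i]) - p1
    sqrt(max(sum(v^2) - sum(v * u)^2, 0))
  }, numeric(1))
  expect_equal(d[k], max(d), tolerance = 1e-12)
  expect_equal(kneepoint(c(0.9, 1)), 1L)
})

test_that("embedding separates planted row clusters along DC1", {
  set.seed(5)
  a <- matrix(rnorm(10 * 30, mean = 3), 10, 30)
  b <- matrix(rnorm(10 * 30, mean = -3), 10, 30)
  S <- rbind(a, b) + rnorm(20 * 30, sd = 0.2)
  rownames(S) <- sprintf("R%d|T", 1:20)
  colnames(S) <- sprintf("g%d", 1:30)
  m <- structure(list(scores = S,
                      row_info = data.frame(receptor = sprintf("R%d", 1:20),
                                            cell_type = "T"),
                      pc_embedding = NULL, dc1 = NULL,
                      n_pcs = NA_integer_),
                 class = "ResponseScoreMatrix")
  m <- embed_responses(m)
  expect_false(is.null(m$dc1))
  expect_true(all(sign(m$dc1[1:10]) != sign(m$dc1[11:20])) ||
                max(m$dc1[1:10]) < min(m$dc1[11:20]) ||
                min(m$dc1[1:10]) > max(m$dc1[11:20]))
  # duplicated rows land on identical DC1 coordinates
  S2 <- S; S2[2, ] <- S2[1, ]
  m2 <- m; m2$scores <- S2; m2$pc_embedding <- NULL; m2$dc1 <- NULL
  m2 <- embed_responses(m2)
  expect_equal(unname(m2$dc1[1]), unname(m2$dc1[2]), tolerance = 1e-6)
  # fewer than 3 rows: flagged, no DC1
  m3 <- structure(list(scores = S[1:2, ],
                       row_info = m$row_info[1:2, ],
                       pc_embedding = NULL, dc1 = NULL,
                       n_pcs = NA_integer_),
                  class = "ResponseScoreMatrix")
  expect_warning(m3 <- embed_responses(m3), "3 rows")
  expect_null(m3$dc1)
})

test_that("receptor-associated DEGs replicate across conditions but ligand effects do not", {
  sim <- simulate_tme(
    n_genes = 200, n_cells = 300,
    interactions = default_interactions(n_dependent = 1,
                                        n_independent = 0),
    n_effect_genes = 15, n_confounders = 15, seed = 409)
  ds <- sim$dataset
  eff <- sim$truth$effect_genes[["LIG1_REC1"]]
  cnf <- sim$truth$confounder_genes[["LIG1_REC1"]]
  genes <- c(eff, cnf)
  tr_hi <- target_test(subset_cells(ds, ds$cells$condition == "CINhigh"),
                       "REC1", "Macrophage", genes = genes)
  tr_lo <- target_test(subset_cells(ds, ds$cells$condition == "CINlow"),
                       "REC1", "Macrophage", genes = genes)
  p_hi <- tr_hi$p[match(genes, tr_hi$gene)]
  p_lo <- tr_lo$p[match(genes, tr_lo$gene)]
  # confounders are receptor-associated in every condition
  expect_gt(mean(p_hi[match(cnf, genes)] < 0.05, na.rm = TRUE), 0.7)
  expect_gt(mean(p_lo[match(cnf, genes)] < 0.05, na.rm = TRUE), 0.7)
  # planted ligand effects respond only where the ligand is available
  expect_gt(mean(p_hi[match(eff, genes)] < 0.05, na.rm = TRUE), 0.7)
  expect_lt(mean(p_lo[match(eff, genes)] < 0.05, na.rm = TRUE), 0.3)
})
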