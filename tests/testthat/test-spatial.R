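make_spatial <- function(expr, prob, spacing = 100) {
  n <- nrow(expr)
  side <- ceiling(sqrt(n))
  xy <- expand.grid(x_um = (seq_len(side) - 1) * spacing,
                    y_um = (seq_len(side) - 1) * spacing)[seq_len(n), ]
  SpatialDataset(data.frame(spot_id = sprintf("s%d", seq_len(n)), xy),
                 expr, prob)
}

test_that("the colocalization statistic multiplies its three factors", {
  expr <- cbind(L = exp(1) - 1, R = 2)
  prob <- cbind(T = 0.5, Other = 0.5)
  sp <- make_spatial(expr, prob)
  expect_equal(coloc_statistic(sp, "L", "R", "T"), 0.5)   # log1p(e-1) = 1
  # receptor absent everywhere -> 0
  expr0 <- cbind(L = c(3, 3), R = c(0, 0))
  prob0 <- cbind(T = c(1, 1))
  expect_equal(coloc_statistic(make_spatial(expr0, prob0), "L", "R", "T"), 0)
  # duplicated spots double the statistic
  expr2 <- rbind(expr, expr)
  prob2 <- rbind(prob, prob)
  expect_equal(coloc_statistic(make_spatial(expr2, prob2), "L", "R", "T"),
               2 * coloc_statistic(sp, "L", "R", "T"))
  expect_error(coloc_statistic(sp, "nope", "R", "T"), "nope")
  expect_error(coloc_statistic(sp, "L", "R", "Missing"), "Missing")
})

test_that("the statistic ignores spot ordering", {
  set.seed(2)
  n <- 25
  expr <- cbind(L = rpois(n, 2), R = rpois(n, 1))
  pr <- runif(n)
  prob <- cbind(T = pr, Other = 1 - pr)
  sp <- make_spatial(expr, prob)
  perm <- sample(n)
  sp2 <- make_spatial(expr[perm, ], prob[perm, ])
  expect_equal(coloc_statistic(sp, "L", "R", "T"),
               coloc_statistic(sp2, "L", "R", "T"))
})

test_that("permutation p-values follow the add-one convention", {
  # constant ligand: every permutation reproduces the observed statistic
  n <- 16
  expr <- cbind(L = rep(2, n), R = rbinom(n, 1, 0.5))
  pr <- runif(n); prob <- cbind(T = pr, Other = 1 - pr)
  sp <- make_spatial(expr, prob)
  expect_equal(permutation_pvalue(sp, "L", "R", "T", n_perm = 50)$p, 1)
  # perfectly concentrated layout: observed beats every permutation
  sim <- simulate_spatial(seed = 9)
  res <- permutation_pvalue(sim$spatial, "LIG1", "REC1", "Macrophage",
                            n_perm = 100, seed = 2)
  expect_equal(res$p, 1 / 101, tolerance = 0.05)
  expect_lte(res$p, 0.05)
  # deterministic given the seed
  res2 <- permutation_pvalue(sim$spatial, "LIG1", "REC1", "Macrophage",
                             n_perm = 100, seed = 2)
  expect_identical(res, res2)
})

test_that("background triples yield roughly uniform p-values", {
  ps <- vapply(1:60, function(i) {
    sim <- simulate_spatial(grid = c(8, 8), seed = 1000 + i)
    permutation_pvalue(sim$spatial, "LIG2", "REC2", "Tcell",
                       n_perm = 60, seed = i)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.2)
  expect_gt(mean(ps < 0.5), 0.25)
})

test_that("fraction colocalized tracks the ranked list and alpha", {
  sim <- simulate_spatial(
    colocalized = data.frame(ligand = c("LIG1", "LIG3"),
                             receptor = c("REC1", "REC3"),
                             target_type = c("Macrophage", "Tumor")),
    background = data.frame(ligand = "LIG2", receptor = "REC2",
                            target_type = "Tcell"),
    seed = 5)
  ranked <- data.frame(ligand = c("LIG1", "LIG3", "LIG2"),
                       receptor = c("REC1", "REC3", "REC2"),
                       target_type = c("Macrophage", "Tumor", "Tcell"))
  fc <- fraction_colocalized(sim$spatial, ranked, top_n_grid = c(1, 2, 3),
                             n_perm = 60, seed = 3)
  expect_equal(fc$fraction_colocalized[1], 1)
  expect_equal(fc$fraction_colocalized[2], 1)
  expect_lte(fc$fraction_colocalized[3], 1)
  # alpha = 1 calls everything colocalized
  fc1 <- fraction_colocalized(sim$spatial, ranked, top_n_grid = 3,
                              alpha = 1, n_perm = 20, seed = 3)
  expect_equal(fc1$fraction_colocalized, 1)
})

test_that("radius pooling: zero radius matches spot-level scoring", {
  sim <- simulate_spatial(seed = 11)
  s0 <- coloc_statistic(sim$spatial, "LIG1", "REC1", "Macrophage")
  expect_equal(coloc_statistic(sim$spatial, "LIG1", "REC1", "Macrophage",
                               radius = 0), s0)
  # a large radius pools neighbours and changes the statistic
  s200 <- coloc_statistic(sim$spatial, "LIG1", "REC1", "Macrophage",
                          radius = 200)
  expect_gt(s200, s0)
})

test_that("spatial IO and validation round-trip", {
  sim <- simulate_spatial(grid = c(4, 4), seed = 3)
  sp <- sim$spatial
  d <- tempfile(); dir.create(d)
  write.table(sp$spots, file.path(d, "spots.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.csv(sp$expr, file.path(d, "expr.csv"))
  write.csv(sp$celltype_prob, file.path(d, "prob.csv"))
  sp2 <- read_spatial(file.path(d, "spots.tsv"), file.path(d, "expr.csv"),
                      file.path(d, "prob.csv"))
  expect_equal(sp2$expr, sp$expr)
  expect_equal(sp2$celltype_prob, sp$celltype_prob, tolerance = 1e-12)
  # invalid probabilities are rejected
  bad <- sp$celltype_prob; bad[1, ] <- bad[1, ] * 0.5
  expect_error(SpatialDataset(sp$spots, sp$expr, bad), "sum to 1")
})
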