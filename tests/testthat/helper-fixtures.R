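# Shared fixtures, all built in code.

# Tiny ExpressionDataset from a dense count matrix (cells x genes).
make_ds <- function(counts, cell_type = "A", condition = "c1",
                    subcluster = NULL, scale = 1e4) {
  n <- nrow(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell%03d", seq_len(n))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  ann <- data.frame(cell_id = rownames(counts),
                    cell_type = rep_len(cell_type, n),
                    condition = rep_len(condition, n),
                    stringsAsFactors = FALSE)
  if (!is.null(subcluster)) ann$subcluster <- rep_len(subcluster, n)
  ExpressionDataset(counts, ann, scale = scale)
}

# Deterministic random count matrix with every cell nonempty.
rand_counts <- function(n, g, lambda = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * g, lambda), n, g)
  m[rowSums(m) == 0, 1] <- 1
  m
}

write_tsv_tmp <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = if (ext == ".csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  path
}
write_csv_tmp <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  path
}

# Independent brute-force maximizer of the two-part hurdle likelihood,
# used as the oracle for the analytic fits. Numerical optimization only;
# shares no code with the implementation under test.
oracle_hurdle_loglik <- function(y, X, k_min = 3) {
  z <- as.numeric(y > 0)
  ll <- 0
  if (sum(z) > 0 && sum(z) < length(z)) {
    nll <- function(b) {
      eta <- pmin(pmax(drop(X %*% b), -30), 30)
      -sum(z * eta - log1p(exp(eta)))
    }
    gr <- function(b) {
      eta <- pmin(pmax(drop(X %*% b), -30), 30)
      -drop(crossprod(X, z - stats::plogis(eta)))
    }
    fit <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    ll <- ll - fit$value
  }
  idx <- which(z == 1)
  if (length(idx) >= k_min) {
    Xd <- X[idx, , drop = FALSE]
    yd <- y[idx]
    nll <- function(par) {
      beta <- par[-length(par)]
      s <- exp(par[length(par)])
      r <- yd - drop(Xd %*% beta)
      length(yd) * log(s) + sum(r^2) / (2 * s^2) +
        length(yd) / 2 * log(2 * pi)
    }
    st <- c(rep(0, ncol(Xd)), log(stats::sd(yd) + 0.1))
    fit <- stats::optim(st, nll, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    fit <- stats::optim(fit$par, nll, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    if (abs(sum((yd - drop(Xd %*% fit$par[-length(fit$par)]))^2)) > 1e-10)
      ll <- ll - fit$value
  }
  ll
}

# Random tiny hurdle instance guaranteed fittable (no separation, both
# parts informative). Deterministic given seed.
tiny_hurdle_instance <- function(seed) {
  set.seed(seed)
  repeat {
    n <- sample(30:50, 1)
    p <- sample(2:3, 1)                       # incl. intercept
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
    z <- rbinom(n, 1, plogis(drop(X %*% runif(p, -0.7, 0.7))))
    if (sum(z) < 8 || sum(z) > n - 8) next
    y <- ifelse(z == 1, abs(drop(X %*% runif(p, -0.5, 0.5)) + rnorm(n)) +
                  0.05, 0)
    fit <- suppressWarnings(glm.fit(X, z, family = binomial()))
    if (!fit$converged || any(abs(fit$coefficients) > 8)) next
    return(list(y = y, X = X))
  }
}
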