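# REML variance components and BLUP solving: closed-form oracles,
# cross-route consistency, and the GBLUP/ssGBLUP/GFBLUP equivalences.

test_that("restricted likelihood matches a direct dense computation", {
  withr::with_seed(11, {
    n <- 40
    ids <- rep(paste0("s", 1:20), each = 2)
    y <- rnorm(n) + rep(rnorm(20), each = 2)
    X <- cbind(1, rnorm(n))
  })
  m <- mme_model(y, X = X, random = list(random_term("s", ids = ids)))
  terms <- pigblup:::.prep_terms(m)
  s2 <- c(0.7); s2e <- 1.3
  ev <- pigblup:::.reml_eval(m, terms, s2, s2e)
  Z <- diag(20)[match(ids, unique(ids)), ]
  oracle <- direct_reml_loglik(y, X, list(tcrossprod(Z)), c(s2, s2e))
  # both drop the same 2 pi constant
  expect_equal(-0.5 * ev$neg2ll, oracle, tolerance = 1e-8)
})

test_that("REML matches the balanced one-way ANOVA closed form", {
  withr::with_seed(9, {
    k <- 10; r <- 5
    grp <- rep(paste0("g", 1:k), each = r)
    y <- 3 + rnorm(k, 0, sqrt(2))[as.integer(factor(grp))] + rnorm(k * r)
  })
  vc <- reml(mme_model(y, random = list(random_term("grp", ids = grp))))
  av <- anova(lm(y ~ grp))
  msb <- av$`Mean Sq`[1]; msw <- av$`Mean Sq`[2]
  expect_equal(unname(vc$sigma2["grp"]), (msb - msw) / r, tolerance = 1e-5)
  expect_equal(unname(vc$sigma2["e"]), msw, tolerance = 1e-5)
})

test_that("REML recovers a moderate heritability from genomic data", {
  err <- vapply(c(401, 402, 403), function(seed) {
    withr::with_seed(seed, {
      n <- 300; m <- 600
      M <- matrix(rbinom(n * m, 2, 0.4), n, m)
      p <- colMeans(M) / 2
      Z <- sweep(M, 2, 2 * p)
      G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
      ids <- paste0("a", 1:n)
      dimnames(G) <- list(ids, ids)
      u <- t(chol(G + diag(1e-6, n))) %*% rnorm(n) * sqrt(0.5)
      y <- stats::setNames(as.numeric(u) + rnorm(n, 0, sqrt(0.5)), ids)
    })
    vc <- reml(mme_model(y, random = list(random_term("g", ids = ids, K = G))))
    unname(vc$h2["g"]) - 0.5
  }, 0)
  expect_lt(abs(mean(err)), 0.1)
})

test_that("residual-only fit reproduces the fixed-model residual variance", {
  withr::with_seed(3, {
    y <- rnorm(30, mean = 5)
    grp <- rep(c("u", "v"), 15)
  })
  X <- stats::model.matrix(~grp)
  # single nuisance term held essentially at zero: residual absorbs all
  m <- mme_model(y, X = X,
                 random = list(random_term("z", ids = rep("l1", 30))))
  sol <- solve_blup(m, c(z = 1e-10, e = 1))
  fit <- lm(y ~ grp)
  expect_equal(sol$residuals, unname(resid(fit)), tolerance = 1e-4)
})

test_that("BLUP shrinkage follows the closed form at lambda = 1", {
  y <- c(a = 1, b = 1, d = -2)
  m <- mme_model(y, X = matrix(numeric(0), 3, 0),
                 random = list(random_term("g", ids = names(y))))
  sol <- solve_blup(m, c(g = 1, e = 1))
  expect_equal(sol$u$g, y / 2)
  # all equal responses: mu absorbs everything, predictions go to zero
  y2 <- c(a = 4, b = 4, d = 4)
  m2 <- mme_model(y2, random = list(random_term("g", ids = names(y2))))
  sol2 <- solve_blup(m2, c(g = 1, e = 1))
  expect_equal(unname(sol2$beta), 4, tolerance = 1e-10)
  expect_equal(max(abs(sol2$u$g)), 0, tolerance = 1e-10)
})

test_that("GBLUP equals marker ridge regression through the duality", {
  withr::with_seed(7, {
    n <- 50; m <- 200
    M <- matrix(rbinom(n * m, 2, 0.4), n, m,
                dimnames = list(paste0("a", 1:n), paste0("M", 1:m)))
    p <- colMeans(M) / 2
    Z <- sweep(M, 2, 2 * p)
    c0 <- 2 * sum(p * (1 - p))
    G <- tcrossprod(Z) / c0
    dimnames(G) <- list(rownames(M), rownames(M))
    y <- stats::setNames(rnorm(n) + Z[, 1] * 0.8, rownames(M))
  })
  fit <- fit_gblup(y, K = G, vc = c(g = 0.4, e = 0.6))
  lam <- 0.6 / (0.4 / c0)
  X <- matrix(1, n, 1)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(lam, m)))
  sol <- solve(C, c(crossprod(X, y), crossprod(Z, y)))
  expect_lt(max(abs(fit$gebv - as.numeric(Z %*% sol[-1]))), 1e-8)
})

test_that("ssGBLUP degenerates to GBLUP and to pedigree BLUP", {
  ped <- random_pedigree(15, n_founders = 5, seed = 21)
  panel <- random_panel(15, 120, seed = 21)
  rownames(panel$dosage) <- ped$id
  withr::with_seed(4, y <- stats::setNames(rnorm(15), ped$id))
  A <- unclass(a_matrix(ped))
  adj <- adjust_g(unclass(g_matrix(panel)), A)
  Gw <- unclass(blend_g(adj$Ga, A))
  vc <- c(g = 0.5, e = 0.5)
  # every phenotyped animal genotyped: identical to GBLUP on Gw
  parts <- h_inverse(ped, Gw, ped$id)
  fit_ss <- fit_gblup(y, Kinv = assemble_h_inverse(parts), vc = vc)
  fit_g <- fit_gblup(y, K = Gw, vc = vc)
  expect_lt(max(abs(fit_ss$gebv - fit_g$gebv[names(fit_ss$gebv)])), 1e-8)
  # nobody genotyped: identical to pedigree BLUP on A
  parts0 <- h_inverse(ped, Gw, character(0))
  fit_ss0 <- fit_gblup(y, Kinv = assemble_h_inverse(parts0), vc = vc)
  fit_a <- fit_gblup(y, K = A, vc = vc)
  expect_lt(max(abs(fit_ss0$gebv - fit_a$gebv[names(fit_ss0$gebv)])), 1e-8)
})

test_that("GFBLUP with the full panel as feature reduces to GBLUP", {
  panel <- random_panel(25, 60, seed = 13)
  withr::with_seed(5, y <- stats::setNames(rnorm(25),
                                           rownames(panel$dosage)))
  fit_f <- fit_gfblup(y, colnames(panel$dosage), panel,
                      vc = c(g = 0.5, e = 0.5))
  fit_g <- fit_gblup(y, K = g_matrix(panel), vc = c(g = 0.5, e = 0.5))
  expect_lt(max(abs(fit_f$gebv - fit_g$gebv)), 1e-8)
  expect_error(fit_gfblup(y, character(0), panel), "empty feature")
})

test_that("random 50/50 marker splits show no systematic variance asymmetry", {
  diffs <- vapply(1:8, function(seed) {
    panel <- random_panel(60, 100, seed = 100 + seed)
    withr::with_seed(seed, {
      y <- stats::setNames(rnorm(60), rownames(panel$dosage))
      f <- sample(colnames(panel$dosage), 50)
    })
    fit <- fit_gfblup(y, f, panel)
    unname(fit$vc$sigma2["f"] - fit$vc$sigma2["r"])
  }, 0)
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("feature sets enriched for causal markers capture more variance", {
  withr::with_seed(31, {
    n <- 150; m <- 200
    M <- matrix(rbinom(n * m, 2, 0.4), n, m,
                dimnames = list(paste0("a", 1:n), paste0("M", 1:m)))
    qtl <- paste0("M", 1:20)
    eff <- rnorm(20)
    g <- as.numeric(M[, qtl] %*% eff)
    g <- (g - mean(g)) / sd(g) * sqrt(0.4)
    y <- stats::setNames(g + rnorm(n, 0, sqrt(0.6)), rownames(M))
    map <- data.frame(marker = colnames(M), chrom = 1, pos = seq_len(m) * 1e4)
    panel <- genotype_panel(M, map)
  })
  fit <- fit_gfblup(y, qtl, panel)
  share <- fit$vc$sigma2["f"] / (fit$vc$sigma2["f"] + fit$vc$sigma2["r"])
  expect_gt(unname(share), 20 / 200)
})

test_that("predictions are invariant to a constant response shift", {
  panel <- random_panel(30, 80, seed = 17)
  withr::with_seed(2, y <- stats::setNames(rnorm(30),
                                           rownames(panel$dosage)))
  G <- g_matrix(panel)
  f1 <- fit_gblup(y, K = G, vc = c(g = 0.3, e = 0.7))
  f2 <- fit_gblup(y + 100, K = G, vc = c(g = 0.3, e = 0.7))
  expect_equal(f1$gebv, f2$gebv, tolerance = 1e-8)
})

test_that("the likelihood trace never decreases over iterations", {
  ped <- random_pedigree(60, seed = 33)
  withr::with_seed(6, {
    ids <- sample(ped$id, 120, replace = TRUE)
    y <- rnorm(120)
  })
  vc <- reml(mme_model(y, random = list(
    random_term("a", ids = ids, Kinv = a_inverse(ped)),
    random_term("pe", ids = ids))))
  expect_true(all(diff(vc$loglik) > -1e-8))
})

test_that("rank-deficient fixed designs fail loudly with column names", {
  y <- rnorm(10)
  X <- matrix(1, 10, 2, dimnames = list(NULL, c("a", "b")))  # identical columns
  expect_error(mme_model(y, X = X,
                         random = list(random_term("g", ids = rep("l", 10)))),
               "aliased")
})
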