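# Relationship matrices: pedigree A and its inverse, VanRaden G, the
# Ga rescaling, blending and the single-step H inverse.

test_that("tabular A reproduces hand-derived relationships", {
  expect_equal(unname(a_matrix(data.frame(id = 1:3, sire = 0, dam = 0))),
               diag(3), ignore_attr = TRUE)
  ped <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
  A <- a_matrix(ped)
  expect_equal(A["1", "3"], 0.5)
  expect_equal(A["3", "3"], 1)
  # full sibs mated: offspring inbreeding F = 0.25
  ped2 <- data.frame(id = 1:5, sire = c(0, 0, 1, 1, 3),
                     dam = c(0, 0, 2, 2, 4))
  A2 <- a_matrix(ped2)
  expect_equal(A2["3", "4"], 0.5)
  expect_equal(A2["5", "5"], 1.25)
})

test_that("a_matrix sorts unordered pedigrees and rejects ancestry loops", {
  ped <- data.frame(id = c(3, 1, 2), sire = c(1, 0, 0), dam = c(2, 0, 0))
  A <- a_matrix(ped)
  expect_equal(A["1", "3"], 0.5)
  loop <- data.frame(id = c(1, 2), sire = c(2, 1), dam = c(0, 0))
  expect_error(a_matrix(loop), "ancestor")
})

test_that("Henderson A-inverse agrees with dense inversion", {
  expect_equal(as.matrix(a_inverse(data.frame(id = 1:4, sire = 0, dam = 0))),
               diag(4), ignore_attr = TRUE)
  trio <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
  expect_equal(unname(diag(as.matrix(a_inverse(trio)))), c(1.5, 1.5, 2.0))
  for (seed in 1:3) {
    ped <- random_pedigree(200, seed = seed)
    A <- a_matrix(ped)
    Ainv <- as.matrix(a_inverse(ped))
    expect_lt(max(abs(Ainv %*% A - diag(nrow(A)))), 1e-8)
  }
})

test_that("VanRaden G matches the hand example and its scaling expectation", {
  M <- rbind(a = c(0, 2), b = c(2, 0))
  colnames(M) <- c("m1", "m2")
  G <- g_matrix(M, p = c(0.5, 0.5))
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)
  # duplicated individuals give identical rows and off-diagonal = diagonal
  M2 <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), d = c(2, 1, 0, 1))
  colnames(M2) <- paste0("m", 1:4)
  G2 <- g_matrix(M2)
  expect_equal(G2["a", ], G2["b", ])
  expect_equal(G2["a", "b"], G2["a", "a"])
  # mean diagonal near 1 with observed frequencies
  panel <- random_panel(50, 500, seed = 4)
  expect_lt(abs(mean(diag(g_matrix(panel))) - 1), 0.1)
})

test_that("G is additive over marker subsets weighted by their scale", {
  panel <- random_panel(30, 80, seed = 7)
  mk <- colnames(panel$dosage)
  f <- mk[1:25]
  r <- setdiff(mk, f)
  p <- colMeans(panel$dosage) / 2
  sf <- 2 * sum(p[f] * (1 - p[f]))
  sr <- 2 * sum(p[r] * (1 - p[r]))
  Gf <- g_matrix(subset_panel(panel, markers = f), p = p[f])
  Gr <- g_matrix(subset_panel(panel, markers = r), p = p[r])
  G <- g_matrix(panel, p = p)
  expect_equal(unname((sf * unclass(Gf) + sr * unclass(Gr)) / (sf + sr)),
               unname(unclass(G)), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("adjust_g solves the average-matching system", {
  G <- diag(2)
  A22 <- matrix(c(1.2, 0.4, 0.4, 1.2), 2)
  dimnames(G) <- dimnames(A22) <- list(c("a", "b"), c("a", "b"))
  adj <- adjust_g(G, A22)
  expect_equal(adj$beta, 0.8)
  expect_equal(adj$alpha, 0.4)
  # G = A22 is a fixed point
  adj2 <- adjust_g(A22, A22)
  expect_equal(adj2$beta, 1)
  expect_equal(adj2$alpha, 0)
  expect_equal(unclass(adj2$Ga), A22, ignore_attr = TRUE)
})

test_that("adjusted Ga matches A22 averages on random instances", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(3:12, 1)
      Z <- matrix(rnorm(n * n), n)
      G <- crossprod(Z) / n
      W <- matrix(rnorm(n * n), n)
      A22 <- crossprod(W) / n + diag(n) * 0.5
      ids <- paste0("x", 1:n)
      dimnames(G) <- dimnames(A22) <- list(ids, ids)
    })
    adj <- adjust_g(G, A22)
    off <- row(G) != col(G)
    expect_equal(mean(diag(adj$Ga)), mean(diag(A22)), tolerance = 1e-12)
    expect_equal(mean(adj$Ga[off]), mean(A22[off]), tolerance = 1e-12)
  }
})

test_that("blending weights follow Gw = w Ga + (1 - w) A22", {
  Ga <- matrix(c(1.1, 0.2, 0.2, 0.9), 2)
  A22 <- diag(2)
  dimnames(Ga) <- dimnames(A22) <- list(c("a", "b"), c("a", "b"))
  expect_equal(unclass(blend_g(Ga, A22)), 0.95 * Ga + 0.05 * A22,
               ignore_attr = TRUE)
  expect_equal(unclass(blend_g(Ga, A22, w = 1)), Ga, ignore_attr = TRUE)
  expect_equal(unclass(blend_g(A22, A22, w = 0.3)), A22, ignore_attr = TRUE)
  expect_error(blend_g(Ga, A22, w = 1.2), "\\[0, 1\\]")
})

test_that("H inverse reduces correctly in the degenerate cases", {
  ped <- random_pedigree(12, seed = 5)
  panel <- random_panel(12, 60, seed = 5)
  rownames(panel$dosage) <- ped$id
  A <- a_matrix(ped)
  # all animals genotyped: H^-1 = Gw^-1
  G <- g_matrix(panel)
  adj <- adjust_g(unclass(G), unclass(A)[rownames(G), rownames(G)])
  Gw <- blend_g(adj$Ga, unclass(A))
  parts <- h_inverse(ped, unclass(Gw), genotyped_ids = ped$id)
  expect_equal(assemble_h_inverse(parts), solve(unclass(Gw)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # no animals genotyped: H^-1 = A^-1
  parts0 <- h_inverse(ped, Gw, genotyped_ids = character(0))
  expect_equal(assemble_h_inverse(parts0), as.matrix(a_inverse(ped)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("mixed-case H matches the joint-distribution construction", {
  ped <- random_pedigree(20, n_founders = 6, seed = 9)
  gen_ids <- as.character(11:20)
  panel <- random_panel(10, 80, seed = 9)
  rownames(panel$dosage) <- gen_ids
  A <- unclass(a_matrix(ped))
  A22 <- A[gen_ids, gen_ids]
  adj <- adjust_g(unclass(g_matrix(panel)), A22)
  Gw <- unclass(blend_g(adj$Ga, A22))
  parts <- h_inverse(ped, Gw, gen_ids)
  H <- h_matrix(parts)
  # oracle: H11 = A11 + A12 A22^-1 (Gw - A22) A22^-1 A21; H12 = A12 A22^-1 Gw
  non <- setdiff(ped$id, gen_ids)
  A11 <- A[non, non]; A12 <- A[non, gen_ids]
  A22i <- solve(A22)
  H_or <- rbind(
    cbind(A11 + A12 %*% A22i %*% (Gw - A22) %*% A22i %*% t(A12),
          A12 %*% A22i %*% Gw),
    cbind(Gw %*% A22i %*% t(A12), Gw))
  ord <- c(non, gen_ids)
  expect_equal(H[ord, ord], H_or, tolerance = 1e-8, ignore_attr = TRUE)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("relationship matrices round-trip through both writers", {
  ped <- random_pedigree(8, seed = 2)
  A <- unclass(a_matrix(ped))
  txt <- withr::local_tempfile(fileext = ".txt")
  bin <- withr::local_tempfile(fileext = ".bin")
  write_relmat(A, txt, format = "text")
  expect_equal(read_relmat(txt, format = "text"), A, ignore_attr = TRUE)
  write_relmat(A, bin, format = "binary")
  attr(A, "kind") <- NULL
  expect_identical(read_relmat(bin, format = "binary")[rownames(A), ], A)
})
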