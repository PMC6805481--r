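# Shared fixtures and independent oracles, built in code at test time.

# random valid pedigree: founders then offspring with parents drawn from
# earlier animals (never creates loops)
random_pedigree <- function(n, n_founders = max(4, n %/% 5), seed = 1) {
  withr::with_seed(seed, {
    id <- as.character(seq_len(n))
    sire <- dam <- rep(NA_character_, n)
    for (i in (n_founders + 1):n) {
      pool <- seq_len(i - 1)
      sire[i] <- as.character(sample(pool, 1))
      dam[i] <- as.character(sample(pool, 1))
    }
    data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
  })
}

# small random dosage panel with a uniform map
random_panel <- function(n = 20, m = 50, seed = 1, n_chrom = 2,
                         label = "sequence") {
  withr::with_seed(seed, {
    p <- runif(m, 0.1, 0.9)
    M <- sapply(p, function(pp) rbinom(n, 2, pp))
    dimnames(M) <- list(paste0("id", seq_len(n)), sprintf("M%03d", seq_len(m)))
    map <- data.frame(marker = colnames(M),
                      chrom = rep(seq_len(n_chrom), length.out = m),
                      pos = rep(sort(sample.int(1e8, ceiling(m / n_chrom))),
                                length.out = m),
                      stringsAsFactors = FALSE)
    map <- map[order(map$chrom, map$pos), ]
    storage.mode(M) <- "double"
    genotype_panel(M[, map$marker, drop = FALSE], map, label = label)
  })
}

# direct restricted log-likelihood through the phenotypic covariance --
# an oracle independent of the package's REML engine internals
direct_reml_loglik <- function(y, X, Vlist, s2) {
  n <- length(y)
  V <- diag(s2[length(s2)], n)
  for (i in seq_along(Vlist)) V <- V + s2[i] * Vlist[[i]]
  Vinv <- solve(V)
  XtViX <- t(X) %*% Vinv %*% X
  P <- Vinv - Vinv %*% X %*% solve(XtViX) %*% t(X) %*% Vinv
  -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            determinant(XtViX, logarithm = TRUE)$modulus +
            t(y) %*% P %*% y)[1]
}

# Hudson's two-population Fst estimator on founder dosages
hudson_fst <- function(M1, M2) {
  p1 <- colMeans(M1) / 2
  p2 <- colMeans(M2) / 2
  n1 <- 2 * nrow(M1)
  n2 <- 2 * nrow(M2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# tiny simulation profile shared by slower integration tests
small_sim_config <- function(seed, ...) {
  sim_config(n_populations = 2L, founders_per_pop = 48L, generations = 2L,
             dams_per_sire = 3L, progeny_per_dam = 2L, n_chromosomes = 2L,
             n_seq_markers = 600L, n_chip_markers = 80L, n_qtl = 30L,
             divergence = 0.1, seed = seed, ...)
}
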