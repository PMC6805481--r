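## Marker quality control (autosome filter, MAF, call rate, LD pruning) and
## imputation-accuracy metrics (concordance rate and dosage r-squared, the
## empirical analogue of Beagle's allelic R-squared) with MAF-binned
## summaries.

#' Marker quality control
#'
#' Applies, in order: removal of non-autosomal markers (non-numeric
#' chromosome codes, or codes above `n_autosomes` when given), removal of
#' markers with minor allele frequency below `maf_min` (default 0.01), and
#' removal of markers with call rate below `call_rate_min` (default 0.90).
#' Remaining missing dosages are mean-imputed so the panel is ready for
#' relationship-matrix construction.
#'
#' @param panel a `genotype_panel`.
#' @param maf_min MAF threshold.
#' @param call_rate_min per-marker call-rate threshold.
#' @param autosomes_only drop non-autosomal markers first.
#' @param n_autosomes optional highest autosome number (codes above it are
#'   dropped); by default only non-numeric codes count as non-autosomal.
#' @return list: `panel` (filtered, mean-imputed) and `report` (class
#'   `qc_report`: removed counts per filter, retained ids, thresholds).
#' @export
qc_filter <- function(panel, maf_min = 0.01, call_rate_min = 0.90,
                      autosomes_only = TRUE, n_autosomes = NULL) {
  .check(inherits(panel, "genotype_panel"), "panel must be a genotype_panel")
  M <- panel$dosage
  map <- panel$map
  n_in <- ncol(M)
  removed <- c(non_autosomal = 0L, maf = 0L, call_rate = 0L)
  keep <- rep(TRUE, n_in)
  if (autosomes_only) {
    chrom <- suppressWarnings(as.numeric(as.character(map$chrom)))
    auto <- !is.na(chrom)
    if (!is.null(n_autosomes)) auto <- auto & chrom <= n_autosomes
    removed["non_autosomal"] <- sum(!auto)
    keep <- keep & auto
  }
  cr <- colMeans(!is.na(M))
  mafv <- {
    p <- colMeans(M, na.rm = TRUE) / 2
    pmin(p, 1 - p)
  }
  fail_maf <- keep & (mafv < maf_min)
  removed["maf"] <- sum(fail_maf)
  keep <- keep & !fail_maf
  fail_cr <- keep & (cr < call_rate_min)
  removed["call_rate"] <- sum(fail_cr)
  keep <- keep & !fail_cr
  .check(any(keep), "no markers left after quality control")
  M2 <- M[, keep, drop = FALSE]
  if (anyNA(M2)) {        # mean-impute what survived the call-rate filter
    mu <- colMeans(M2, na.rm = TRUE)
    idx <- which(is.na(M2), arr.ind = TRUE)
    M2[idx] <- mu[idx[, 2]]
  }
  out <- genotype_panel(M2, map[keep, , drop = FALSE], label = panel$label)
  report <- structure(list(n_input = n_in, removed = removed,
                           retained = colnames(M2),
                           thresholds = list(maf_min = maf_min,
                                             call_rate_min = call_rate_min,
                                             autosomes_only = autosomes_only)),
                      class = "qc_report")
  list(panel = out, report = report)
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d markers in, %d retained (removed: %s)\n", x$n_input,
              length(x$retained),
              paste(names(x$removed), x$removed, sep = "=", collapse = ", ")))
  invisible(x)
}

## r^2 of within-window retained pairs; helper shared with the pruner
.window_starts <- function(n, window, step) {
  if (n <= window) return(1L)
  unique(c(seq(1L, n - window + 1L, by = step), n - window + 1L))
}

#' LD pruning by pairwise genotype correlation
#'
#' Greedy windowed pruning: within sliding windows of `window_markers`
#' markers (stepping by `step`), one marker of every pair with squared
#' genotype correlation at or above `r2_max` is removed. The default,
#' reproducible rule removes the marker with the lower MAF (ties: the later
#' marker); `rule = "random"` removes a random member of the pair. Passes
#' repeat until no retained within-window pair reaches the threshold.
#'
#' @param panel a `genotype_panel`, position-sorted within chromosome
#'   (sorted internally if not).
#' @param r2_max squared-correlation threshold (default 0.9).
#' @param window_markers,step window size and stride in markers.
#' @param rule `"maf"` (deterministic) or `"random"`.
#' @return list: `panel` (pruned, labelled `"pruned"`) and `report`
#'   (`qc_report` with the `ld_prune` removal count).
#' @export
ld_prune <- function(panel, r2_max = 0.9, window_markers = 50L, step = 5L,
                     rule = c("maf", "random")) {
  rule <- match.arg(rule)
  .check(.is_scalar(r2_max) && r2_max > 0 && r2_max <= 1,
         "r2_max must lie in (0, 1]")
  M <- panel$dosage
  map <- panel$map
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  M <- M[, ord, drop = FALSE]
  mafv <- {
    p <- colMeans(M, na.rm = TRUE) / 2
    pmin(p, 1 - p)
  }
  keep <- rep(TRUE, ncol(M))
  names(keep) <- colnames(M)
  chrom_idx <- split(seq_len(ncol(M)), map$chrom)
  repeat {
    removed_this_pass <- 0L
    for (idx in chrom_idx) {
      ret <- idx[keep[idx]]
      n <- length(ret)
      if (n < 2) next
      for (s in .window_starts(n, window_markers, step)) {
        win <- ret[s:min(n, s + window_markers - 1L)]
        win <- win[keep[win]]
        if (length(win) < 2) next
        r2 <- suppressWarnings(cor(M[, win, drop = FALSE]))^2
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        while (max(r2) >= r2_max) {
          hit <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          i <- win[hit[1]]; j <- win[hit[2]]
          drop_i <- switch(rule,
            maf = if (mafv[i] != mafv[j]) ifelse(mafv[i] < mafv[j], i, j)
                  else max(i, j),
            random = sample(c(i, j), 1))
          keep[drop_i] <- FALSE
          removed_this_pass <- removed_this_pass + 1L
          w <- which(win == drop_i)
          r2[w, ] <- 0; r2[, w] <- 0
        }
      }
    }
    if (removed_this_pass == 0L) break
  }
  sel <- names(keep)[keep]
  out <- subset_panel(panel, markers = map$marker[map$marker %in% sel],
                      label = "pruned")
  report <- structure(list(n_input = ncol(panel$dosage),
                           removed = c(ld_prune = sum(!keep)),
                           retained = colnames(out$dosage),
                           thresholds = list(r2_max = r2_max,
                                             window_markers = window_markers,
                                             step = step, rule = rule)),
                      class = "qc_report")
  list(panel = out, report = report)
}

## exhaustive within-window r2 check used by tests and assertions
max_window_r2 <- function(panel, window_markers = 50L, step = 5L) {
  M <- panel$dosage
  map <- panel$map
  ord <- order(map$chrom, map$pos)
  M <- M[, ord, drop = FALSE]
  map <- map[ord, , drop = FALSE]
  worst <- 0
  for (idx in split(seq_len(ncol(M)), map$chrom)) {
    n <- length(idx)
    if (n < 2) next
    for (s in .window_starts(n, window_markers, step)) {
      win <- idx[s:min(n, s + window_markers - 1L)]
      r2 <- suppressWarnings(cor(M[, win, drop = FALSE]))^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      worst <- max(worst, max(r2))
    }
  }
  worst
}

#' Imputation-accuracy metrics with MAF-binned summaries
#'
#' Per marker: the concordance rate CR (fraction of identical hard
#' genotypes, dosages rounded to the nearest integer) and the squared
#' Pearson correlation between imputed and true dosages — the empirical
#' analogue of Beagle's allelic R-squared. Markers whose truth MAF falls
#' below `maf_floor` are flagged; zero-variance truth markers get `NA`
#' r-squared and are excluded from bin means. Bins are 0.01-wide up to MAF
#' 0.05 and 0.05-wide up to 0.5.
#'
#' @param imputed,truth `genotype_panel`s with identical individuals and
#'   markers.
#' @param maf_floor reporting floor on truth MAF (default 9.9e-5).
#' @param bin_edges optional explicit MAF bin edges.
#' @return object of class `imputation_accuracy`: `per_marker` (marker, maf,
#'   cr, r2, flagged) and `bins` (bin bounds, mean CR, mean r2, count).
#' @export
imputation_metrics <- function(imputed, truth, maf_floor = 9.9e-5,
                               bin_edges = NULL) {
  Mi <- dosage_matrix(imputed)
  Mt <- dosage_matrix(truth)
  .check(identical(dim(Mi), dim(Mt)) &&
           identical(colnames(Mi), colnames(Mt)) &&
           identical(rownames(Mi), rownames(Mt)),
         "imputed and truth panels must match in individuals and markers")
  hard_i <- round(Mi); hard_t <- round(Mt)
  cr <- colMeans(hard_i == hard_t)
  vt <- apply(Mt, 2, stats::var)
  r2 <- rep(NA_real_, ncol(Mt))
  ok <- vt > 0 & apply(Mi, 2, stats::var) > 0
  if (any(ok))
    r2[ok] <- vapply(which(ok), function(j) cor(Mi[, j], Mt[, j])^2, 0)
  r2[vt > 0 & !ok] <- 0          # truth varies, imputation constant
  p <- colMeans(Mt) / 2
  mafv <- pmin(p, 1 - p)
  flagged <- mafv < maf_floor
  if (is.null(bin_edges))
    bin_edges <- c(seq(0, 0.05, by = 0.01), seq(0.10, 0.50, by = 0.05))
  bin <- cut(mafv, bin_edges, include.lowest = TRUE, right = TRUE)
  per_marker <- data.frame(marker = colnames(Mt), maf = mafv, cr = cr,
                           r2 = r2, flagged = flagged,
                           stringsAsFactors = FALSE, row.names = NULL)
  usable <- !flagged & !is.na(r2)
  bins <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- usable & bin == b & !is.na(bin)
    data.frame(bin = b, n = sum(sel),
               mean_cr = if (any(sel)) mean(cr[sel]) else NA_real_,
               mean_r2 = if (any(sel)) mean(r2[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_marker = per_marker, bins = bins,
                 maf_floor = maf_floor, bin_edges = bin_edges),
            class = "imputation_accuracy")
}

#' @exportS3Method base::print
print.imputation_accuracy <- function(x, ...) {
  cat("imputation accuracy:", nrow(x$per_marker), "markers; mean CR =",
      signif(mean(x$per_marker$cr), 4), "\n")
  print(x$bins[x$bins$n > 0, ], row.names = FALSE)
  invisible(x)
}

#' Simulate MAF-dependent imputation error on a panel
#'
#' Emulates the error structure of statistical imputation: each genotype is
#' replaced, with a per-marker probability that grows as the MAF shrinks, by
#' a random Hardy-Weinberg draw at the marker's allele frequency. Rare
#' variants are therefore imputed towards the major genotype, which is what
#' depresses dosage r-squared at low MAF.
#'
#' @param panel truth `genotype_panel`.
#' @param base_error error probability at MAF 0.5.
#' @param maf_scale half-saturation constant: the error rate is
#'   `base_error * (0.5 + maf_scale) / (maf + maf_scale)`, capped at 0.95.
#' @return a `genotype_panel` with the corrupted dosages.
#' @export
simulate_imputation_error <- function(panel, base_error = 0.02,
                                      maf_scale = 0.05) {
  M <- dosage_matrix(panel)
  p <- colMeans(M) / 2
  mafv <- pmin(p, 1 - p)
  err <- pmin(0.95, base_error * (0.5 + maf_scale) / (mafv + maf_scale))
  n <- nrow(M)
  for (j in seq_len(ncol(M))) {
    hit <- runif(n) < err[j]
    if (any(hit)) M[hit, j] <- rbinom(sum(hit), 2, p[j])
  }
  genotype_panel(M, panel$map, label = panel$label)
}
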