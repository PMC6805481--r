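## Mixed-linear-model association scan (single variance-component
## estimation reused across markers, P3D style) and construction of
## genomic-feature marker sets from scan results or QTL windows.

#' Mixed-linear-model association scan
#'
#' Tests each marker with `y = 1 mu + Z g + x b + e`, `g ~ N(0, G sigma2_g)`.
#' The variance components are estimated once on the no-marker model and
#' reused for every test (population parameters previously determined), so
#' each marker costs one generalized-least-squares solve against the fixed
#' phenotypic covariance. Markers monomorphic among the scanned animals get
#' `p = 1` and a flag. With `drop_polygenic = TRUE` the polygenic term is
#' omitted and each test reduces to ordinary least squares.
#'
#' @param y named numeric responses (corrected phenotypes of the reference
#'   animals only).
#' @param panel `genotype_panel` holding the markers to scan; individuals
#'   must cover `names(y)`.
#' @param G optional genomic relationship matrix; built once from the
#'   scanned panel (over the reference animals) when omitted.
#' @param vc optional fixed variance components (`g`, `e`).
#' @param drop_polygenic drop the `Z g` term (pure fixed-effect model).
#' @return object of class `assoc_result`: data frame `marker`, `chrom`,
#'   `pos`, `beta`, `se`, `p`, `monomorphic`, plus the variance components
#'   used as attribute `vc`.
#' @export
mlm_scan <- function(y, panel, G = NULL, vc = NULL, drop_polygenic = FALSE) {
  .check(!is.null(names(y)), "y must be named by animal id")
  .check(inherits(panel, "genotype_panel"), "panel must be a genotype_panel")
  ids <- names(y)
  .check(all(ids %in% rownames(panel$dosage)),
         "all phenotyped animals must be genotyped in the panel")
  M <- panel$dosage[ids, , drop = FALSE]
  n <- length(y)
  if (drop_polygenic) {
    V <- diag(n)
    vc_used <- c(g = 0, e = stats::var(y))
  } else {
    if (is.null(G)) G <- g_matrix(genotype_panel(M, panel$map, panel$label))
    G <- G[ids, ids]
    if (is.null(vc)) {
      model <- mme_model(y, random = list(random_term("g", ids = ids,
                                                      K = G, levels = ids)))
      vc <- reml(model)
    }
    s2 <- if (inherits(vc, "variance_components")) vc$sigma2 else vc
    V <- s2["g"] * G + s2["e"] * diag(n)
    vc_used <- s2
  }
  Vinv <- chol2inv(chol(V))
  X <- matrix(1, n, 1)
  XtVi <- crossprod(X, Vinv)
  P <- Vinv - t(XtVi) %*% solve(XtVi %*% X, XtVi)
  Py <- as.numeric(P %*% y)
  PM <- P %*% M
  xPx <- colSums(M * PM)
  xPy <- as.numeric(crossprod(M, Py))
  mono <- apply(M, 2, function(col) length(unique(col)) == 1L) | xPx <= 1e-10
  beta <- se <- rep(NA_real_, ncol(M))
  p <- rep(1, ncol(M))
  beta[!mono] <- xPy[!mono] / xPx[!mono]
  se[!mono] <- sqrt(1 / xPx[!mono])
  p[!mono] <- pchisq(beta[!mono]^2 * xPx[!mono], df = 1, lower.tail = FALSE)
  res <- data.frame(marker = colnames(M),
                    chrom = panel$map$chrom[match(colnames(M), panel$map$marker)],
                    pos = panel$map$pos[match(colnames(M), panel$map$marker)],
                    beta = beta, se = se, p = pmin(pmax(p, 1e-300), 1),
                    monomorphic = mono,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("assoc_result", "data.frame"), vc = vc_used)
}

#' Feature set from association results
#'
#' Markers with `p <= p_cutoff` form the genomic feature. An empty result is
#' returned (with a message) when no marker passes, so the caller can fall
#' back to GBLUP.
#'
#' @param result an `assoc_result` from [mlm_scan()].
#' @param p_cutoff p-value threshold, typically on the `10^-1 ... 10^-7`
#'   grid.
#' @return object of class `feature_set`: `markers`, `definition`.
#' @export
features_from_gwas <- function(result, p_cutoff) {
  .check(inherits(result, "assoc_result"), "result must come from mlm_scan()")
  .check(.is_scalar(p_cutoff) && p_cutoff > 0 && p_cutoff <= 1,
         "p_cutoff must lie in (0, 1]")
  markers <- result$marker[result$p <= p_cutoff]
  if (length(markers) == 0)
    message("no marker passed p <= ", p_cutoff, "; fall back to GBLUP")
  structure(list(markers = markers,
                 definition = list(type = "gwas", p_cutoff = p_cutoff)),
            class = "feature_set")
}

#' Feature set from QTL windows
#'
#' Every QTL region is standardised to a window of `bin_halfwidth_bp` on
#' each side of its midpoint; panel markers whose position falls inside any
#' window (inclusive bounds, 1-based coordinates) form the feature. Regions
#' on chromosomes absent from the panel are skipped with a message.
#'
#' @param regions data frame with columns `chrom`, `start_bp`, `end_bp`
#'   (and optionally `trait_category`, `source`), or the path-backed result
#'   of [read_qtl_regions()].
#' @param panel `genotype_panel`.
#' @param bin_halfwidth_bp half-width of the standardised window; the
#'   conventional bins are 100 kb, 500 kb and 1000 kb.
#' @param trait_category optional filter on the regions' trait category.
#' @return `feature_set` (markers unique across overlapping windows).
#' @export
features_from_qtl <- function(regions, panel,
                              bin_halfwidth_bp = c(1e5, 5e5, 1e6)[1],
                              trait_category = NULL) {
  .check(all(c("chrom", "start_bp", "end_bp") %in% names(regions)),
         "regions need columns chrom, start_bp, end_bp")
  .check(all(regions$start_bp <= regions$end_bp),
         "QTL regions must satisfy start <= end")
  if (!is.null(trait_category) && "trait_category" %in% names(regions))
    regions <- regions[regions$trait_category %in% trait_category, , drop = FALSE]
  map <- panel$map
  sel <- rep(FALSE, nrow(map))
  skipped <- 0L
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    if (!ch %in% map$chrom) {
      skipped <- skipped + 1L
      next
    }
    mid <- floor((regions$start_bp[i] + regions$end_bp[i]) / 2)
    lo <- mid - bin_halfwidth_bp
    hi <- mid + bin_halfwidth_bp
    sel <- sel | (map$chrom == ch & map$pos >= lo & map$pos <= hi)
  }
  if (skipped > 0)
    message(skipped, " region(s) on chromosomes absent from the panel skipped")
  structure(list(markers = map$marker[sel],
                 definition = list(type = "qtl",
                                   bin_halfwidth_bp = bin_halfwidth_bp)),
            class = "feature_set")
}

#' @exportS3Method base::print
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set (%s): %d markers\n", x$definition$type,
              length(x$markers)))
  invisible(x)
}
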