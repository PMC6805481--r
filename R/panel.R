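## Genotype panel container: an individuals-by-markers dosage matrix plus a
## marker map, tagged with the panel's provenance (chip / sequence / pruned).

#' Construct a genotype panel
#'
#' @param dosage numeric matrix, individuals in rows (ids as rownames),
#'   markers in columns (ids as colnames); entries 0/1/2 or NA for missing.
#' @param map data frame with columns `marker`, `chrom`, `pos` (1-based bp)
#'   and optionally `a1`, `a2`; row order must match the dosage columns.
#' @param label panel provenance: `"chip"`, `"sequence"` or `"pruned"`.
#' @return object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, map, label = c("sequence", "chip", "pruned")) {
  label <- match.arg(label)
  .check(is.matrix(dosage), "dosage must be a matrix")
  .check(!is.null(rownames(dosage)) && !is.null(colnames(dosage)),
         "dosage needs individual rownames and marker colnames")
  .check(is.data.frame(map) && all(c("marker", "chrom", "pos") %in% names(map)),
         "map must have columns marker, chrom, pos")
  .check(identical(as.character(map$marker), colnames(dosage)),
         "map rows must match dosage columns (same markers, same order)")
  rng <- range(dosage, na.rm = TRUE)
  .check(rng[1] >= 0 && rng[2] <= 2, "dosages must lie in [0, 2]")
  map$marker <- as.character(map$marker)
  structure(list(dosage = dosage, map = map, label = label),
            class = "genotype_panel")
}

#' Extract the dosage matrix from a panel or pass a matrix through
#' @param x a `genotype_panel` or a dosage matrix.
#' @return numeric matrix (individuals x markers).
#' @export
dosage_matrix <- function(x) {
  if (inherits(x, "genotype_panel")) x$dosage
  else if (is.matrix(x)) x
  else stop("expected a genotype_panel or a dosage matrix", call. = FALSE)
}

#' @exportS3Method base::print
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel [%s]: %d individuals x %d markers, %d chromosome(s)\n",
              x$label, nrow(x$dosage), ncol(x$dosage),
              length(unique(x$map$chrom))))
  invisible(x)
}

#' Subset a panel by markers and/or individuals
#'
#' @param panel a `genotype_panel`.
#' @param markers character marker ids to keep (default: all).
#' @param ids character individual ids to keep (default: all).
#' @param label optional new provenance label.
#' @return a `genotype_panel`.
#' @export
subset_panel <- function(panel, markers = NULL, ids = NULL, label = NULL) {
  .check(inherits(panel, "genotype_panel"), "panel must be a genotype_panel")
  if (is.null(markers)) markers <- colnames(panel$dosage)
  if (is.null(ids)) ids <- rownames(panel$dosage)
  .check(all(markers %in% colnames(panel$dosage)), "unknown marker ids")
  .check(all(ids %in% rownames(panel$dosage)), "unknown individual ids")
  dos <- panel$dosage[ids, markers, drop = FALSE]
  map <- panel$map[match(markers, panel$map$marker), , drop = FALSE]
  rownames(map) <- NULL
  genotype_panel(dos, map, label = if (is.null(label)) panel$label else label)
}

#' Allele frequencies of a panel
#' @param x panel or dosage matrix.
#' @return vector of alternate-allele frequencies (NA-aware).
#' @export
allele_freq <- function(x) {
  M <- dosage_matrix(x)
  colMeans(M, na.rm = TRUE) / 2
}

#' Minor allele frequencies of a panel
#' @inheritParams allele_freq
#' @export
maf <- function(x) {
  p <- allele_freq(x)
  pmin(p, 1 - p)
}
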