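## Experimental design: population-structure PCA, forward (birth-date)
## validation splits, and the reference-set x method x panel scenario grid
## with accuracy measured as cor(GEBV, corrected phenotype) in validation.

#' Principal components of population structure
#'
#' Eigendecomposition of the (double-centred) genomic relationship matrix;
#' for a panel the VanRaden G is built first. Returns the leading component
#' scores and each component's share of variance.
#'
#' @param x a `genotype_panel` or a relationship matrix.
#' @param n_components number of components to return.
#' @return list: `scores` (individuals x components, scaled by the square
#'   root of the eigenvalue), `var_explained` (shares over all positive
#'   eigenvalues), `values`.
#' @export
pca_structure <- function(x, n_components = 2L) {
  G <- if (inherits(x, "genotype_panel")) g_matrix(x) else as.matrix(x)
  n <- nrow(G)
  .check(n >= 2, "need at least two individuals")
  if (n_components > n) {
    message("fewer individuals than requested components; truncating")
    n_components <- n
  }
  Cmat <- diag(n) - matrix(1 / n, n, n)
  Gc <- Cmat %*% G %*% Cmat
  ee <- eigen(.symmetrize(Gc), symmetric = TRUE)
  pos <- pmax(ee$values, 0)
  k <- seq_len(n_components)
  scores <- ee$vectors[, k, drop = FALSE] %*% diag(sqrt(pos[k]), n_components)
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", k)
  list(scores = scores, var_explained = pos[k] / sum(pos), values = ee$values)
}

#' Forward validation split by birth date
#'
#' Validation animals are those of `validation_population` born strictly
#' after `split_date`; the reference set is every other animal with a
#' corrected phenotype whose population belongs to
#' `reference_populations`. Validation animals never enter the reference,
#' and an across-population split simply omits the validation population
#' from `reference_populations`.
#'
#' @param pedigree pedigree data frame (`id`, `birth_date`, `population`).
#' @param yc_ids ids of animals with a corrected phenotype.
#' @param validation_population population label of the validation set.
#' @param split_date ISO date string; born-after animals validate.
#' @param reference_populations labels of populations allowed in the
#'   reference (default: all).
#' @return list: `reference`, `validation` (character id vectors).
#' @export
split_validation <- function(pedigree, yc_ids, validation_population,
                             split_date,
                             reference_populations = unique(pedigree$population)) {
  .check(all(c("id", "birth_date", "population") %in% names(pedigree)),
         "pedigree needs id, birth_date, population")
  ped <- pedigree[pedigree$id %in% yc_ids, , drop = FALSE]
  bd <- as.Date(ped$birth_date)
  .check(!anyNA(bd), "birth dates must parse as dates")
  val <- ped$id[ped$population == validation_population &
                  bd > as.Date(split_date)]
  .check(length(val) > 0, "validation set is empty: check the split date")
  ref <- ped$id[ped$population %in% reference_populations & !(ped$id %in% val)]
  list(reference = ref, validation = val)
}

#' Define one prediction scenario
#'
#' @param reference_populations populations contributing reference animals.
#' @param validation_population population validated by the forward split.
#' @param method `"GBLUP"`, `"ssGBLUP"`, `"GFBLUP_QTL"` or `"GFBLUP_GWAS"`.
#' @param panel which panel to use: `"chip"`, `"seq"` or `"seq_pruned"`.
#' @param split_date forward-split date (born after = validation).
#' @param trait trait name the scenario evaluates.
#' @param p_cutoff GWAS p-value cut-off (GFBLUP_GWAS).
#' @param qtl_halfwidth_bp QTL window half-width (GFBLUP_QTL).
#' @return a `scenario` list.
#' @export
scenario <- function(reference_populations, validation_population,
                     method = c("GBLUP", "ssGBLUP", "GFBLUP_QTL", "GFBLUP_GWAS"),
                     panel = c("chip", "seq", "seq_pruned"),
                     split_date, trait, p_cutoff = 1e-3,
                     qtl_halfwidth_bp = 1e5) {
  method <- match.arg(method)
  panel <- match.arg(panel)
  structure(list(reference_populations = reference_populations,
                 validation_population = validation_population,
                 method = method, panel = panel, split_date = split_date,
                 trait = trait, p_cutoff = p_cutoff,
                 qtl_halfwidth_bp = qtl_halfwidth_bp),
            class = "scenario")
}

#' Run a single prediction scenario
#'
#' Fits the scenario's method on the reference animals only and reports the
#' Pearson correlation between predicted GEBV and the corrected phenotypes
#' of the validation animals. GBLUP and GFBLUP use the genotyped reference;
#' ssGBLUP additionally lets non-genotyped phenotyped animals contribute
#' through the single-step H inverse. GFBLUP features are derived from the
#' scenario's own reference set (GWAS strategy) or from the shared QTL file.
#'
#' @param sc a [scenario()].
#' @param data list with elements `yc` (named corrected-phenotype vector for
#'   the scenario's trait), `pedigree`, `panels` (named list `chip`, `seq`,
#'   `seq_pruned`), `genotyped_ids` (default: panel individuals) and, for
#'   GFBLUP_QTL, `qtl_regions`.
#' @return one-row data frame (class `scenario_result`): scenario fields,
#'   `n_reference`, `n_validation`, `accuracy`, `s2_g`, `s2_e`.
#' @export
run_scenario <- function(sc, data) {
  .check(inherits(sc, "scenario"), "sc must come from scenario()")
  .check(all(c("yc", "pedigree", "panels") %in% names(data)),
         "data needs yc, pedigree, panels")
  panel <- data$panels[[sc$panel]]
  .check(!is.null(panel), paste0("panel '", sc$panel, "' missing from data"))
  genotyped <- if (!is.null(data$genotyped_ids)) data$genotyped_ids
               else rownames(panel$dosage)
  split <- split_validation(data$pedigree, names(data$yc),
                            sc$validation_population, sc$split_date,
                            sc$reference_populations)
  val <- intersect(split$validation, genotyped)
  .check(length(val) >= 3, "need at least three genotyped validation animals")
  ref_geno <- intersect(split$reference, genotyped)
  .check(length(if (sc$method == "ssGBLUP") split$reference else ref_geno) >= 10,
         paste0("reference set too small after the split/reliability filter",
                " (", length(ref_geno), " genotyped reference animals);",
                " check split_date and reference_populations"))
  yc <- data$yc
  acc_ids <- val
  feature_info <- NA_character_
  if (sc$method == "ssGBLUP") {
    ## all phenotyped reference animals contribute; H ties in the pedigree
    gids <- intersect(rownames(panel$dosage), data$pedigree$id)
    gids <- intersect(gids, genotyped)
    sub <- subset_panel(panel, ids = gids)
    G <- g_matrix(sub)
    A <- a_matrix(data$pedigree)
    A22 <- A[gids, gids, drop = FALSE]
    adj <- adjust_g(G, A22)
    Gw <- blend_g(adj$Ga, A22)
    parts <- h_inverse(data$pedigree, Gw, gids)
    Hinv <- assemble_h_inverse(parts)
    yref <- yc[split$reference]
    fit <- fit_gblup(yref, Kinv = Matrix::Matrix(Hinv, sparse = TRUE))
    gebv <- fit$gebv[val]
    vc_used <- fit$vc$sigma2
  } else {
    ids_model <- union(ref_geno, val)
    sub <- subset_panel(panel, ids = ids_model)
    yref <- yc[ref_geno]
    if (sc$method == "GBLUP") {
      fit <- fit_gblup(yref, K = g_matrix(sub))
    } else {
      fs <- if (sc$method == "GFBLUP_QTL") {
        .check(!is.null(data$qtl_regions), "GFBLUP_QTL needs data$qtl_regions")
        features_from_qtl(data$qtl_regions, sub,
                          bin_halfwidth_bp = sc$qtl_halfwidth_bp,
                          trait_category = sc$trait)
      } else {
        ref_panel <- subset_panel(sub, ids = ref_geno)
        scan <- mlm_scan(yref, ref_panel)
        features_from_gwas(scan, sc$p_cutoff)
      }
      feature_info <- sprintf("%d feature markers", length(fs$markers))
      if (length(fs$markers) == 0 ||
          length(fs$markers) == ncol(sub$dosage)) {
        message("degenerate feature set (", length(fs$markers),
                " markers); falling back to GBLUP")
        fit <- fit_gblup(yref, K = g_matrix(sub))
      } else {
        fit <- fit_gfblup(yref, fs$markers, sub)
      }
    }
    gebv <- fit$gebv[val]
    vc_used <- fit$vc$sigma2
  }
  accuracy <- cor(gebv, yc[acc_ids])
  out <- data.frame(reference = paste(sc$reference_populations, collapse = "+"),
                    validation = sc$validation_population,
                    method = sc$method, panel = sc$panel, trait = sc$trait,
                    n_reference = length(split$reference),
                    n_validation = length(val),
                    accuracy = accuracy,
                    s2_g = unname(vc_used[setdiff(names(vc_used), "e")][1]),
                    s2_e = unname(vc_used["e"]),
                    features = feature_info,
                    stringsAsFactors = FALSE)
  class(out) <- c("scenario_result", "data.frame")
  out
}

#' Run a grid of scenarios
#'
#' Executes every scenario with a deterministically derived child seed and
#' collects the results in a long-format table; individual scenario failures
#' are recorded (NA accuracy, message kept) and the grid continues.
#'
#' @param scenarios list of [scenario()] objects.
#' @param data shared data list (see [run_scenario()]).
#' @param master_seed integer; per-scenario seeds derive from it.
#' @return data frame of scenario results with an `error` column.
#' @export
scenario_grid <- function(scenarios, data, master_seed = 1L) {
  rows <- lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    lab <- paste(sc$method, sc$panel, sc$trait,
                 paste(sc$reference_populations, collapse = "+"), i, sep = "|")
    seed_i <- derive_seed(master_seed, lab)
    res <- tryCatch(
      with_seed(seed_i, run_scenario(sc, data)),
      error = function(e) {
        warning("scenario ", lab, " failed: ", conditionMessage(e))
        data.frame(reference = paste(sc$reference_populations, collapse = "+"),
                   validation = sc$validation_population, method = sc$method,
                   panel = sc$panel, trait = sc$trait,
                   n_reference = NA_integer_, n_validation = NA_integer_,
                   accuracy = NA_real_, s2_g = NA_real_, s2_e = NA_real_,
                   features = NA_character_, stringsAsFactors = FALSE)
      })
    res$error <- if (is.na(res$accuracy[1]) && is.na(res$n_reference[1]))
      "failed" else NA_character_
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pivot a scenario-result table to the reference-by-method layout
#'
#' @param results long-format results from [scenario_grid()].
#' @return data frame with one row per reference set and one column per
#'   method-panel combination.
#' @export
pivot_results <- function(results) {
  key <- paste(results$method, results$panel, sep = "_")
  refs <- unique(results$reference)
  cols <- unique(key)
  out <- data.frame(reference = refs, stringsAsFactors = FALSE)
  for (cn in cols) {
    out[[cn]] <- vapply(refs, function(r) {
      v <- results$accuracy[results$reference == r & key == cn]
      if (length(v)) round(mean(v, na.rm = TRUE), 4) else NA_real_
    }, 0)
  }
  out
}
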