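## Corrected phenotypes: weight-adjustment of the production traits to
## 100 kg, herd-year-season(-sex) fixed-effect coding, pedigree BLUP with a
## repeatability (reproduction) or litter (production) model, and the
## corrected phenotype y_c = EBV + (mean) residual with a reliability filter.

.CF_AGE <- c(M = 50.775, F = 46.415)
.CF_BFT <- c(M = -7.277, F = -9.440)

#' Adjust days to 100 kg
#'
#' `AGE = age + (100 - weight) * (age - CF) / weight`, with the national
#' swine-improvement-programme correction factors CF = 50.775 (males) and
#' 46.415 (females). Weights are expected between 85 and 130 kg; values
#' outside that window are still computed with a warning.
#'
#' @param age measured age in days.
#' @param weight measured live weight in kg.
#' @param sex `"M"` or `"F"` (vectorised).
#' @param cf optional explicit correction factor overriding the sex default.
#' @return adjusted age in days at 100 kg.
#' @export
#' @examples
#' adjust_age(160, 110, "M")   # 150.0705
adjust_age <- function(age, weight, sex, cf = NULL) {
  .check(all(weight > 0), "weight must be positive")
  if (any(weight < 85 | weight > 130))
    warning("weights outside the 85-130 kg measurement window")
  if (is.null(cf)) {
    .check(all(sex %in% c("M", "F")), "sex must be 'M' or 'F'")
    cf <- .CF_AGE[sex]
  }
  unname(age + (100 - weight) * (age - cf) / weight)
}

#' Adjust backfat thickness to 100 kg
#'
#' `BFT = bft + (100 - weight) * bft / (weight - CF)` with CF = -7.277
#' (males) and -9.440 (females).
#'
#' @param bft measured backfat thickness in mm.
#' @inheritParams adjust_age
#' @return adjusted backfat in mm at 100 kg.
#' @export
#' @examples
#' adjust_bft(12, 110, "M")    # 10.9767
adjust_bft <- function(bft, weight, sex, cf = NULL) {
  .check(all(weight > 0), "weight must be positive")
  if (any(weight < 85 | weight > 130))
    warning("weights outside the 85-130 kg measurement window")
  if (is.null(cf)) {
    .check(all(sex %in% c("M", "F")), "sex must be 'M' or 'F'")
    cf <- .CF_BFT[sex]
  }
  .check(all(abs(weight - cf) > 1e-12), "weight equals CF: division by zero")
  unname(bft + (100 - weight) * bft / (weight - cf))
}

#' Herd-year-season(-sex) fixed-effect codes
#'
#' Seasons follow the four three-month windows 1st = December-February,
#' 2nd = March-May, 3rd = June-August, 4th = September-November. December is
#' assigned to season 1 of the *following* year so each winter stays in one
#' level.
#'
#' @param herd,year,month vectors (recycled to a common length).
#' @param sex optional sex vector; when given the code is herd-year-season-sex.
#' @return character code vector.
#' @export
#' @examples
#' hys_code("H1", 2013, 1)    # January -> season 1
#' hys_code("H1", 2013, 12)   # December -> season 1 of 2014
hys_code <- function(herd, year, month, sex = NULL) {
  .check(all(month %in% 1:12), "month must be in 1..12")
  season <- c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4, 1)[month]
  year <- ifelse(month == 12, year + 1, year)
  code <- paste(herd, year, paste0("S", season), sep = "_")
  if (!is.null(sex)) code <- paste(code, sex, sep = "_")
  code
}

#' Build fixed-effect codes for a record table
#'
#' Reproduction (repeated) records get herd-year-season codes; production
#' (single-record) records get herd-year-season-sex codes. Records with a
#' missing or unparseable date are dropped with a message.
#'
#' @param records data frame with columns `id`, `value`, `herd`, `date`
#'   (ISO `yyyy-mm-dd`), and `sex` for production traits.
#' @param trait_kind `"repeated"` or `"single_record"`.
#' @return the records with an added character column `hys`.
#' @export
build_fixed_effects <- function(records, trait_kind = c("repeated", "single_record")) {
  trait_kind <- match.arg(trait_kind)
  ok <- !is.na(records$date) & grepl("^\\d{4}-\\d{2}", records$date)
  if (any(!ok)) {
    message(sum(!ok), " record(s) dropped for missing/invalid date")
    records <- records[ok, , drop = FALSE]
  }
  yr <- as.integer(substr(records$date, 1, 4))
  mo <- as.integer(substr(records$date, 6, 7))
  records$hys <- if (trait_kind == "single_record")
    hys_code(records$herd, yr, mo, sex = records$sex)
  else hys_code(records$herd, yr, mo)
  records
}

#' Pedigree BLUP with repeatability or litter model
#'
#' Reproduction traits: `y = HYS + animal + pe + e` (repeatability model,
#' permanent-environment effect per sow). Production traits:
#' `y = HYSS + animal + litter + e`, fitted univariately per trait. The
#' additive effect uses the sparse pedigree A inverse; variance components
#' are estimated by REML unless supplied. Reliability is
#' `1 - PEV / sigma2_a`, from the direct inverse of the MME coefficient
#' matrix.
#'
#' @param records record table for one trait (columns `id`, `value`,
#'   `herd`, `date`, `parity`, `litter`, `sex`).
#' @param pedigree pedigree data frame covering at least all recorded
#'   animals.
#' @param trait_kind `"repeated"` or `"single_record"`.
#' @param vc optional fixed variance components (named `a`, `pe`/`litter`,
#'   `e`).
#' @return object of class `ebv_result`: `ebv` (named, all pedigree
#'   animals), `reliability` (named), `residuals` (data frame `id`,
#'   `parity`, `residual`), `vc`, `trait_kind`.
#' @export
fit_pedigree_blup <- function(records, pedigree,
                              trait_kind = c("repeated", "single_record"),
                              vc = NULL) {
  trait_kind <- match.arg(trait_kind)
  ped <- normalize_pedigree(pedigree)
  .check(all(records$id %in% ped$id), "recorded animals missing from pedigree")
  records <- build_fixed_effects(records, trait_kind)
  y <- records$value
  hys <- factor(records$hys)
  X <- if (nlevels(hys) > 1) stats::model.matrix(~hys) else
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  Ainv <- a_inverse(ped)
  terms <- list(random_term("a", ids = as.character(records$id), Kinv = Ainv))
  if (trait_kind == "repeated") {
    terms <- c(terms, list(random_term("pe", ids = as.character(records$id))))
  } else {
    .check(!anyNA(records$litter), "production records need a litter code")
    terms <- c(terms, list(random_term("litter",
                                       ids = as.character(records$litter))))
  }
  model <- tryCatch(mme_model(y, X = X, random = terms),
                    error = function(e)
                      stop("pedigree model could not be set up: ",
                           conditionMessage(e), call. = FALSE))
  if (is.null(vc)) vc <- reml(model)
  sol <- solve_blup(model, vc, pev = TRUE)
  s2a <- sol$sigma2["a"]
  rel <- pmin(pmax(1 - sol$pev$a / s2a, 0), 1)
  structure(list(ebv = sol$u$a, reliability = rel,
                 residuals = data.frame(id = as.character(records$id),
                                        parity = records$parity,
                                        residual = sol$residuals,
                                        stringsAsFactors = FALSE),
                 vc = vc, trait_kind = trait_kind, solution = sol),
            class = "ebv_result")
}

#' Derive corrected phenotypes from an EBV fit
#'
#' Reproduction: `y_c = EBV + mean(residuals over parities)` per sow.
#' Production: `y_c = EBV + residual`. Animals with EBV reliability below
#' `min_reliability` (default 0.3) are removed.
#'
#' @param ebv an `ebv_result` from [fit_pedigree_blup()].
#' @param min_reliability reliability threshold.
#' @return data frame `id`, `y_c`, `reliability` for the phenotyped animals
#'   passing the filter.
#' @export
derive_yc <- function(ebv, min_reliability = 0.3) {
  .check(inherits(ebv, "ebv_result"), "ebv must come from fit_pedigree_blup()")
  res <- ebv$residuals
  .check(nrow(res) > 0, "no residuals available: was the model fitted?")
  mean_res <- tapply(res$residual, res$id, mean)
  ids <- names(mean_res)
  missing_ebv <- setdiff(ids, names(ebv$ebv))
  .check(length(missing_ebv) == 0, "phenotyped animal without an EBV")
  yc <- ebv$ebv[ids] + as.numeric(mean_res)
  rel <- ebv$reliability[ids]
  keep <- rel >= min_reliability
  data.frame(id = ids[keep], y_c = unname(yc[keep]),
             reliability = unname(rel[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}
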