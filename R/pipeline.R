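## End-to-end orchestration from a single declarative (YAML) config:
## simulate a data bundle to disk, and run the corrected-phenotype ->
## relationship-matrix -> REML/BLUP -> feature-selection -> QC ->
## scenario-grid pipeline over it. A thin command-line wrapper around these
## functions ships in inst/scripts/pigblup.R.

#' Read a pipeline run configuration
#'
#' The YAML file has two top-level blocks: `simulate` (fields of
#' [sim_config()]) and `run` (`traits`, `scenarios`, `qc`, `split_date`,
#' `out_dir`, `seed`). [example_config()] writes a commented template with
#' every default.
#'
#' @param path YAML config path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  .check(is.list(cfg) && (("simulate" %in% names(cfg)) ||
                            ("data" %in% names(cfg))),
         "config must contain a 'simulate' block or a 'data' block of paths")
  cfg
}

#' Write a fully-commented example configuration
#' @param path destination YAML path.
#' @export
example_config <- function(path) {
  writeLines(c(
    "# pigblup pipeline configuration",
    "seed: 1            # master seed; per-scenario seeds derive from it",
    "out_dir: pigblup_out",
    "simulate:          # omit this block to read real data via 'data:' paths",
    "  n_populations: 2",
    "  founders_per_pop: 80",
    "  generations: 3",
    "  dams_per_sire: 4",
    "  progeny_per_dam: 2",
    "  n_chromosomes: 3",
    "  chrom_length_bp: 100000000   # 1 cM/Mb genetic map",
    "  n_seq_markers: 3000",
    "  n_chip_markers: 300       # chip is a subset of the sequence panel",
    "  n_qtl: 60",
    "  divergence: 0.1           # Fst-like differentiation between populations",
    "  chip_subset: even         # or: random",
    "  start_year: 2010",
    "# data:                     # real-data mode",
    "#   pedigree: ped.csv",
    "#   records: records.csv",
    "#   chip_vcf: chip.vcf",
    "#   seq_vcf: seq.vcf",
    "#   qtl_regions: qtl.tsv",
    "run:",
    "  traits: [NBA, AGE]",
    "  split_year_offset: 1      # validation = born after start_year + generations - offset",
    "  qc:",
    "    maf_min: 0.01",
    "    call_rate_min: 0.90",
    "    ld_r2_max: 0.9",
    "    ld_window: 50",
    "    ld_step: 5",
    "  methods: [GBLUP, ssGBLUP, GFBLUP_GWAS]",
    "  panels: [chip, seq, seq_pruned]",
    "  gwas_p_cutoff: 0.001",
    "  qtl_halfwidth_bp: 100000"
  ), path)
  invisible(path)
}

#' Simulate a data bundle and write it to disk
#'
#' Writes pedigree and phenotype CSVs, chip/sequence panels as PLINK text
#' and VCF, the QTL truth table, and a JSON manifest recording the seed and
#' file list. Refuses to overwrite a non-empty directory unless
#' `force = TRUE`.
#'
#' @param config a [sim_config()], or a config list with a `simulate` block.
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return the `sim_bundle`, invisibly; files land in `out_dir`.
#' @export
pipeline_simulate <- function(config, out_dir, force = FALSE) {
  if (!inherits(config, "sim_config")) {
    .check(is.list(config) && "simulate" %in% names(config),
           "config must be a sim_config or contain a 'simulate' block")
    args <- config$simulate
    if (!is.null(config$seed) && is.null(args$seed)) args$seed <- config$seed
    config <- do.call(sim_config, args)
  }
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory ", out_dir, " is not empty (use force = TRUE)",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- simulate_population(config)
  paths <- list(
    pedigree = file.path(out_dir, "pedigree.csv"),
    records = file.path(out_dir, "records.csv"),
    chip_plink = file.path(out_dir, "chip"),
    seq_plink = file.path(out_dir, "seq"),
    chip_vcf = file.path(out_dir, "chip.vcf"),
    seq_vcf = file.path(out_dir, "seq.vcf"),
    qtl_truth = file.path(out_dir, "qtl_truth.csv"),
    tbv = file.path(out_dir, "tbv.csv"))
  write_pedigree(bundle$pedigree, paths$pedigree)
  write_records(bundle$records, paths$records)
  write_plink(bundle$chip_panel, paths$chip_plink)
  write_plink(bundle$seq_panel, paths$seq_plink)
  write_vcf(bundle$chip_panel, paths$chip_vcf)
  write_vcf(bundle$seq_panel, paths$seq_vcf)
  data.table::fwrite(bundle$qtl_effects, paths$qtl_truth)
  tbv_df <- data.frame(id = rownames(bundle$tbv), bundle$tbv,
                       check.names = FALSE)
  data.table::fwrite(tbv_df, paths$tbv)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("pigblup")),
                   files = lapply(paths, basename),
                   n_animals = nrow(bundle$pedigree),
                   n_seq_markers = ncol(bundle$seq_panel$dosage),
                   n_chip_markers = ncol(bundle$chip_panel$dosage))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(bundle)
}

## derive per-trait corrected phenotypes for a bundle
.bundle_yc <- function(bundle, trait) {
  specs <- bundle$config$trait_specs
  ts <- specs[[which(vapply(specs, `[[`, "", "name") == trait)]]
  rec <- bundle$records[bundle$records$trait == trait, , drop = FALSE]
  fit <- fit_pedigree_blup(rec, bundle$pedigree, trait_kind = ts$kind)
  yc <- derive_yc(fit)
  stats::setNames(yc$y_c, yc$id)
}

#' Run the full scenario pipeline over a simulated bundle
#'
#' Stages: corrected phenotypes per trait (pedigree BLUP + reliability
#' filter), marker QC and LD pruning of the sequence panel, scenario grid
#' over the configured reference sets, methods and panels, and result
#' tables (long CSV + pivoted layout + PCA coordinates).
#'
#' @param bundle a `sim_bundle` from [simulate_population()] or
#'   [pipeline_simulate()].
#' @param run_cfg list with `traits`, `methods`, `panels`, `qc` thresholds,
#'   `gwas_p_cutoff`, `qtl_halfwidth_bp`, `split_date` (or
#'   `split_year_offset`).
#' @param out_dir optional output directory for CSVs.
#' @param master_seed integer master seed for the grid.
#' @return list: `results` (long table), `pivot`, `yc` (per trait), `pca`.
#' @export
pipeline_run <- function(bundle, run_cfg = list(), out_dir = NULL,
                         master_seed = 1L) {
  .check(inherits(bundle, "sim_bundle"), "bundle must be a sim_bundle")
  cfg <- utils::modifyList(list(
    traits = vapply(bundle$config$trait_specs, `[[`, "", "name")[1],
    methods = c("GBLUP", "ssGBLUP"),
    panels = c("chip", "seq"),
    qc = list(maf_min = 0.01, call_rate_min = 0.90, ld_r2_max = 0.9,
              ld_window = 50L, ld_step = 5L),
    gwas_p_cutoff = 1e-3, qtl_halfwidth_bp = 1e5,
    split_year_offset = 1L), run_cfg)
  pops <- unique(bundle$pedigree$population)
  if (is.null(cfg$split_date)) {
    yr <- bundle$config$start_year + bundle$config$generations -
      cfg$split_year_offset
    cfg$split_date <- sprintf("%d-12-31", yr)
  }
  ## QC + pruning on the sequence panel
  qc_seq <- qc_filter(bundle$seq_panel, maf_min = cfg$qc$maf_min,
                      call_rate_min = cfg$qc$call_rate_min)
  pruned <- ld_prune(qc_seq$panel, r2_max = cfg$qc$ld_r2_max,
                     window_markers = cfg$qc$ld_window, step = cfg$qc$ld_step)
  qc_chip <- qc_filter(bundle$chip_panel, maf_min = cfg$qc$maf_min,
                       call_rate_min = cfg$qc$call_rate_min)
  panels <- list(chip = qc_chip$panel, seq = qc_seq$panel,
                 seq_pruned = pruned$panel)
  message(sprintf("panels after QC: chip %d, seq %d, pruned %d markers",
                  ncol(panels$chip$dosage), ncol(panels$seq$dosage),
                  ncol(panels$seq_pruned$dosage)))
  ## QTL regions from the truth table (windows around causal markers)
  qtl_regions <- NULL
  if (length(bundle$qtl_markers)) {
    map <- bundle$seq_panel$map
    qm <- map[map$marker %in% bundle$qtl_markers, ]
    qtl_regions <- do.call(rbind, lapply(unique(bundle$qtl_effects$trait),
      function(tr) data.frame(chrom = qm$chrom, start_bp = qm$pos,
                              end_bp = qm$pos, trait_category = tr,
                              source = "truth", stringsAsFactors = FALSE)))
  }
  yc_list <- list()
  all_rows <- list()
  pca <- pca_structure(panels$chip, n_components = 2)
  for (trait in cfg$traits) {
    message("deriving corrected phenotypes for ", trait)
    yc <- .bundle_yc(bundle, trait)
    yc_list[[trait]] <- yc
    data <- list(yc = yc, pedigree = bundle$pedigree, panels = panels,
                 qtl_regions = qtl_regions)
    ref_sets <- c(lapply(pops, identity), if (length(pops) > 1) list(pops))
    scenarios <- list()
    for (rs in ref_sets) for (mth in cfg$methods) for (pn in cfg$panels) {
      scenarios[[length(scenarios) + 1L]] <-
        scenario(reference_populations = rs, validation_population = pops[1],
                 method = mth, panel = pn, split_date = cfg$split_date,
                 trait = trait, p_cutoff = cfg$gwas_p_cutoff,
                 qtl_halfwidth_bp = cfg$qtl_halfwidth_bp)
    }
    all_rows[[trait]] <- scenario_grid(scenarios, data,
                                       master_seed = master_seed)
  }
  results <- do.call(rbind, all_rows)
  rownames(results) <- NULL
  piv <- pivot_results(results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(results, file.path(out_dir, "scenario_results.csv"))
    data.table::fwrite(piv, file.path(out_dir, "scenario_pivot.csv"))
    pca_df <- data.frame(id = rownames(pca$scores), pca$scores,
                         check.names = FALSE)
    data.table::fwrite(pca_df, file.path(out_dir, "pca_coordinates.csv"))
    for (trait in names(yc_list))
      write_yc(data.frame(id = names(yc_list[[trait]]),
                          y_c = unname(yc_list[[trait]]),
                          reliability = NA_real_),
               trait, file.path(out_dir, paste0("yc_", trait, ".csv")))
  }
  list(results = results, pivot = piv, yc = yc_list, pca = pca)
}
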