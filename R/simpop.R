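## Synthetic multi-population breeding data: diverged founder populations of
## one breed (Balding-Nichols allele-frequency model), gene dropping through
## a multi-generation pedigree with recombination, chip/sequence marker
## panels where the chip is a subset of the sequence panel, shared QTL, and
## repeated-record reproduction traits / single-record production traits.

#' Specify a simulated trait
#'
#' @param name trait label.
#' @param kind `"repeated"` (reproduction trait with a permanent-environment
#'   effect and one record per parity) or `"single_record"` (production trait
#'   with a litter effect).
#' @param h2 narrow-sense heritability in (0, 1).
#' @param rep_or_litter_var_ratio share of phenotypic variance due to the
#'   permanent-environment (repeated) or litter (single-record) effect.
#' @param parities number of records per sow (repeated kind only).
#' @param mean trait mean.
#' @return object of class `trait_spec`.
#' @export
trait_spec <- function(name, kind = c("repeated", "single_record"),
                       h2, rep_or_litter_var_ratio = 0.1,
                       parities = 3L, mean = 0) {
  kind <- match.arg(kind)
  .check(.is_scalar(h2) && h2 > 0 && h2 < 1, "h2 must lie in (0, 1)")
  .check(.is_scalar(rep_or_litter_var_ratio) && rep_or_litter_var_ratio >= 0 &&
           rep_or_litter_var_ratio < 1, "variance ratio must lie in [0, 1)")
  .check(h2 + rep_or_litter_var_ratio < 1,
         "h2 + rep_or_litter_var_ratio must be < 1")
  .check(.is_count(parities), "parities must be a positive integer")
  structure(list(name = name, kind = kind, h2 = h2,
                 ratio = rep_or_litter_var_ratio,
                 parities = as.integer(parities), mean = mean),
            class = "trait_spec")
}

#' Default trait panel: two reproduction and two production traits
#'
#' Litter-size-like reproduction traits at low heritability (0.08) and
#' growth/backfat-like production traits at moderate heritability
#' (0.38 / 0.24), matching the range typical of pig breeding programmes.
#' @return list of [trait_spec()] objects.
#' @export
default_traits <- function() {
  list(trait_spec("NBA", "repeated", h2 = 0.08, rep_or_litter_var_ratio = 0.08,
                  parities = 3L, mean = 12),
       trait_spec("TNB", "repeated", h2 = 0.09, rep_or_litter_var_ratio = 0.08,
                  parities = 3L, mean = 13),
       trait_spec("AGE", "single_record", h2 = 0.38,
                  rep_or_litter_var_ratio = 0.12, mean = 160),
       trait_spec("BFT", "single_record", h2 = 0.24,
                  rep_or_litter_var_ratio = 0.12, mean = 12))
}

#' Simulation configuration
#'
#' @param n_populations number of diverged populations of the breed.
#' @param founders_per_pop founder animals per population.
#' @param generations number of non-overlapping offspring generations.
#' @param dams_per_sire mating ratio.
#' @param progeny_per_dam litter size retained per dam.
#' @param n_chromosomes,chrom_length_bp genome layout (1 cM/Mb map).
#' @param n_seq_markers,n_chip_markers sequence-density marker count and the
#'   chip subset size (chip must not exceed sequence).
#' @param n_qtl number of causal markers (sampled from the sequence panel).
#' @param divergence Fst-like differentiation among populations in [0, 1).
#' @param trait_specs list of [trait_spec()]; default [default_traits()].
#' @param chip_subset `"even"` (evenly spaced by position, mimicking
#'   commercial chip design) or `"random"`.
#' @param hys_sd standard deviation of the herd-year-season(-sex) fixed
#'   effects on the unit phenotypic-variance scale.
#' @param start_year birth year of the founder generation.
#' @param seed integer master seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_populations = 2L, founders_per_pop = 80L,
                       generations = 3L, dams_per_sire = 4L,
                       progeny_per_dam = 2L, n_chromosomes = 3L,
                       chrom_length_bp = 1e8, n_seq_markers = 3000L,
                       n_chip_markers = 300L, n_qtl = 60L,
                       divergence = 0.1, trait_specs = default_traits(),
                       chip_subset = c("even", "random"),
                       hys_sd = 0.3, start_year = 2010L, seed = 1L) {
  chip_subset <- match.arg(chip_subset)
  .check(.is_count(n_populations), "n_populations must be a positive integer")
  .check(.is_count(founders_per_pop, 2), "founders_per_pop must be >= 2")
  .check(.is_count(generations, 0), "generations must be a non-negative integer")
  .check(.is_count(dams_per_sire), "dams_per_sire must be a positive integer")
  .check(.is_count(progeny_per_dam), "progeny_per_dam must be a positive integer")
  .check(.is_count(n_chromosomes), "n_chromosomes must be a positive integer")
  .check(.is_scalar(chrom_length_bp) && chrom_length_bp >= 1e6,
         "chrom_length_bp must be at least 1 Mb")
  .check(.is_count(n_seq_markers), "n_seq_markers must be a positive integer")
  .check(.is_count(n_chip_markers), "n_chip_markers must be a positive integer")
  .check(n_chip_markers <= n_seq_markers,
         "n_chip_markers must not exceed n_seq_markers")
  .check(.is_count(n_qtl, 0) && n_qtl < n_seq_markers,
         "n_qtl must be a non-negative integer below n_seq_markers")
  .check(.is_scalar(divergence) && divergence >= 0 && divergence < 1,
         "divergence must lie in [0, 1)")
  .check(.is_scalar(hys_sd) && hys_sd >= 0, "hys_sd must be non-negative")
  for (ts in trait_specs)
    .check(inherits(ts, "trait_spec"), "trait_specs must be trait_spec objects")
  structure(list(n_populations = as.integer(n_populations),
                 founders_per_pop = as.integer(founders_per_pop),
                 generations = as.integer(generations),
                 dams_per_sire = as.integer(dams_per_sire),
                 progeny_per_dam = as.integer(progeny_per_dam),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = chrom_length_bp,
                 n_seq_markers = as.integer(n_seq_markers),
                 n_chip_markers = as.integer(n_chip_markers),
                 n_qtl = as.integer(n_qtl), divergence = divergence,
                 trait_specs = trait_specs, chip_subset = chip_subset,
                 hys_sd = hys_sd, start_year = as.integer(start_year),
                 seed = as.integer(seed)),
            class = "sim_config")
}

## marker map: positions uniform along each chromosome, 1-based bp
.sim_map <- function(config) {
  per_chr <- diff(round(seq(0, config$n_seq_markers,
                            length.out = config$n_chromosomes + 1)))
  maps <- lapply(seq_len(config$n_chromosomes), function(ch) {
    m <- per_chr[ch]
    pos <- sort(sample.int(config$chrom_length_bp, m, replace = FALSE))
    data.frame(chrom = ch, pos = pos)
  })
  map <- do.call(rbind, maps)
  map <- data.frame(marker = sprintf("M%06d", seq_len(nrow(map))),
                    chrom = map$chrom, pos = map$pos,
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  map
}

#' Simulate founder haplotypes for diverged populations
#'
#' Per marker an ancestral frequency `p0 ~ Uniform(0.1, 0.9)` is drawn; each
#' population's frequency follows a Beta distribution with mean `p0` and
#' variance `divergence * p0 * (1 - p0)` (Balding-Nichols model), so
#' `divergence` acts as an Fst-like knob. Founder haplotype alleles are
#' Bernoulli draws from the population frequency.
#'
#' @param config a [sim_config()]. The RNG state is taken as-is; seed
#'   management is done by [simulate_population()].
#' @return list: `hap1`/`hap2` (founders x markers 0/1 matrices),
#'   `panel` (founder `genotype_panel`, sequence density), `pedigree`
#'   (founder rows), `map`, `chip_markers` (chip subset ids).
#' @export
simulate_founders <- function(config) {
  .check(inherits(config, "sim_config"), "config must come from sim_config()")
  map <- .sim_map(config)
  m <- nrow(map)
  npop <- config$n_populations
  nf <- config$founders_per_pop
  p0 <- runif(m, 0.1, 0.9)
  d <- config$divergence
  freq <- matrix(0, npop, m)
  for (k in seq_len(npop)) {
    if (d == 0) {
      freq[k, ] <- p0
    } else {
      shape1 <- p0 * (1 - d) / d
      shape2 <- (1 - p0) * (1 - d) / d
      freq[k, ] <- rbeta(m, shape1, shape2)
    }
  }
  if (any(freq < 0 | freq > 1)) {   # cannot occur under Beta draws; guard
    warning("population frequencies clipped to [0, 1]")
    freq <- pmin(pmax(freq, 0), 1)
  }
  ids <- character(0); pops <- character(0)
  hap1 <- matrix(0L, npop * nf, m)
  hap2 <- matrix(0L, npop * nf, m)
  sexes <- character(0)
  for (k in seq_len(npop)) {
    rows <- (k - 1) * nf + seq_len(nf)
    hap1[rows, ] <- matrix(rbinom(nf * m, 1, rep(freq[k, ], each = nf)), nf, m)
    hap2[rows, ] <- matrix(rbinom(nf * m, 1, rep(freq[k, ], each = nf)), nf, m)
    ids <- c(ids, sprintf("P%d_G0_%04d", k, seq_len(nf)))
    pops <- c(pops, rep(paste0("POP", k), nf))
    sexes <- c(sexes, rep(c("M", "F"), length.out = nf))
  }
  rownames(hap1) <- rownames(hap2) <- ids
  colnames(hap1) <- colnames(hap2) <- map$marker
  dos <- hap1 + hap2
  storage.mode(dos) <- "double"
  panel <- genotype_panel(dos, map, label = "sequence")
  ped <- data.frame(id = ids, sire = "0", dam = "0", sex = sexes,
                    birth_date = sprintf("%d-%02d-%02d", config$start_year,
                                         sample(1:12, length(ids), TRUE),
                                         sample(1:28, length(ids), TRUE)),
                    population = pops, herd = pops, generation = 0L,
                    stringsAsFactors = FALSE)
  chip_markers <- select_chip_markers(map, config$n_chip_markers,
                                      method = config$chip_subset)
  list(hap1 = hap1, hap2 = hap2, panel = panel, pedigree = ped, map = map,
       chip_markers = chip_markers, freq = freq)
}

#' Choose the chip-panel marker subset from a sequence map
#'
#' @param map marker map (columns `marker`, `chrom`, `pos`).
#' @param n_chip number of chip markers.
#' @param method `"even"`: evenly spaced by position within chromosomes
#'   (commercial-chip-like); `"random"`: simple random subset.
#' @return character vector of chip marker ids (a strict subset of the map).
#' @export
select_chip_markers <- function(map, n_chip, method = c("even", "random")) {
  method <- match.arg(method)
  .check(n_chip <= nrow(map), "n_chip exceeds the number of markers")
  if (method == "random")
    return(sort(sample(map$marker, n_chip)))
  chroms <- unique(map$chrom)
  per_chr <- diff(round(seq(0, n_chip, length.out = length(chroms) + 1)))
  sel <- character(0)
  for (i in seq_along(chroms)) {
    sub <- map[map$chrom == chroms[i], ]
    k <- per_chr[i]
    if (k == 0) next
    take <- unique(round(seq(1, nrow(sub), length.out = k)))
    sel <- c(sel, sub$marker[take])
  }
  sort(sel)
}

## one meiosis: recombine the two parental haplotypes along the map
## crossover count per chromosome ~ Poisson(map length in Morgans, 1 cM/Mb)
.gamete <- function(h1, h2, map_split, morgans) {
  out <- integer(length(h1))
  for (ch in seq_along(map_split)) {
    idx <- map_split[[ch]]$idx
    pos <- map_split[[ch]]$pos
    L <- morgans[ch]
    nco <- rpois(1, L)
    phase <- sample(c(TRUE, FALSE), 1)
    if (nco == 0) {
      out[idx] <- if (phase) h1[idx] else h2[idx]
    } else {
      co <- sort(runif(nco, 0, map_split[[ch]]$len))
      seg <- findInterval(pos, co)          # segment index per marker
      use1 <- xor(phase, seg %% 2 == 1)
      out[idx] <- ifelse(use1, h1[idx], h2[idx])
    }
  }
  out
}

#' Simulate the pedigree and drop genotypes through it
#'
#' Non-overlapping generations within each population: a fixed number of
#' sires is mated to `dams_per_sire` dams each, every dam leaving
#' `progeny_per_dam` offspring. Each progeny receives one recombinant gamete
#' per parent (crossovers Poisson with 1 cM/Mb). Birth years increase by
#' generation with a random month, sexes alternate within litters, and the
#' herd equals the population.
#'
#' @param config a [sim_config()].
#' @param founders output of [simulate_founders()].
#' @return list: `pedigree` (all animals), `panel` (sequence-density
#'   `genotype_panel` for all animals), `hap1`, `hap2`, `chip_markers`.
#' @export
simulate_pedigree_and_dropdown <- function(config, founders) {
  .check(config$generations >= 0, "generations must be >= 0")
  map <- founders$map
  map_split <- lapply(split(seq_len(nrow(map)), map$chrom), function(idx) {
    list(idx = idx, pos = map$pos[idx] / 1e8,      # bp -> Morgans at 1 cM/Mb
         len = config$chrom_length_bp / 1e8)
  })
  morgans <- vapply(map_split, `[[`, 0, "len")
  ped <- founders$pedigree
  n_sires <- max(1L, round(config$founders_per_pop /
                             (config$dams_per_sire * config$progeny_per_dam)))
  per_gen <- config$n_populations * n_sires * config$dams_per_sire *
    config$progeny_per_dam
  n_total <- nrow(ped) + config$generations * per_gen
  m <- nrow(map)
  hap1 <- matrix(0L, n_total, m)
  hap2 <- matrix(0L, n_total, m)
  hap1[seq_len(nrow(ped)), ] <- founders$hap1
  hap2[seq_len(nrow(ped)), ] <- founders$hap2
  all_ids <- character(n_total)
  all_ids[seq_len(nrow(ped))] <- ped$id
  row_of <- seq_len(nrow(ped))
  names(row_of) <- ped$id
  nxt <- nrow(ped)
  for (g in seq_len(config$generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    new_rows <- list()
    for (k in seq_len(config$n_populations)) {
      popname <- paste0("POP", k)
      cand <- prev[prev$population == popname, ]
      males <- cand$id[cand$sex == "M"]
      females <- cand$id[cand$sex == "F"]
      nd <- n_sires * config$dams_per_sire
      .check(length(males) >= n_sires && length(females) >= nd,
             "not enough parents available; increase founders_per_pop")
      sires <- sample(males, n_sires)
      dams <- sample(females, nd)
      cnt <- 0L
      for (s in seq_len(n_sires)) {
        for (dd in seq_len(config$dams_per_sire)) {
          dam <- dams[(s - 1) * config$dams_per_sire + dd]
          for (pr in seq_len(config$progeny_per_dam)) {
            cnt <- cnt + 1L
            id <- sprintf("P%d_G%d_%04d", k, g, cnt)
            rs <- row_of[sires[s]]; rd <- row_of[dam]
            nxt <- nxt + 1L
            hap1[nxt, ] <- .gamete(hap1[rs, ], hap2[rs, ], map_split, morgans)
            hap2[nxt, ] <- .gamete(hap1[rd, ], hap2[rd, ], map_split, morgans)
            all_ids[nxt] <- id
            row_of[id] <- nxt
            new_rows[[length(new_rows) + 1L]] <- data.frame(
              id = id, sire = sires[s], dam = dam,
              sex = if (pr %% 2 == 1) "M" else "F",
              birth_date = sprintf("%d-%02d-%02d", config$start_year + g,
                                   sample(1:12, 1), sample(1:28, 1)),
              population = popname, herd = popname, generation = g,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    ped <- rbind(ped, do.call(rbind, new_rows))
  }
  hap1 <- hap1[seq_len(nxt), , drop = FALSE]
  hap2 <- hap2[seq_len(nxt), , drop = FALSE]
  rownames(hap1) <- rownames(hap2) <- all_ids[seq_len(nxt)]
  colnames(hap1) <- colnames(hap2) <- map$marker
  dos <- hap1 + hap2
  storage.mode(dos) <- "double"
  panel <- genotype_panel(dos, map, label = "sequence")
  list(pedigree = ped, panel = panel, hap1 = hap1, hap2 = hap2,
       chip_markers = founders$chip_markers)
}

#' Assign QTL effects and simulate phenotypes
#'
#' QTL are sampled from the sequence panel (so some fall off the chip subset
#' by construction), additive effects are normal, and the true breeding value
#' is exactly the sum of dosage times effect. Effects are rescaled so the
#' realized `var(TBV)` equals `h2` on a unit phenotypic-variance scale.
#' Repeated traits add a permanent-environment effect per sow and one record
#' per parity with herd-year-season fixed effects; single-record traits add a
#' litter effect (full sibs share a litter) and herd-year-season-sex effects.
#'
#' @param config a [sim_config()].
#' @param panel sequence-density `genotype_panel` covering all animals.
#' @param pedigree pedigree data frame from the dropdown.
#' @return list: `records` (data frame id, trait, value, parity, litter,
#'   herd, date), `tbv` (animals x traits matrix), `qtl_effects`
#'   (data frame marker, trait, effect), `qtl_markers`.
#' @export
assign_qtl_and_phenotypes <- function(config, panel, pedigree) {
  .check(all(pedigree$id %in% rownames(panel$dosage)),
         "panel must cover all pedigree animals")
  for (ts in config$trait_specs)
    .check(ts$h2 > 0 && ts$h2 < 1, "h2 must lie in (0, 1)")
  M <- panel$dosage[pedigree$id, , drop = FALSE]
  qtl <- sort(sample(colnames(M), config$n_qtl))
  Q <- M[, qtl, drop = FALSE]
  traits <- config$trait_specs
  tbv <- matrix(0, nrow(pedigree), length(traits),
                dimnames = list(pedigree$id,
                                vapply(traits, `[[`, "", "name")))
  eff_list <- list()
  records <- list()
  phen_gen <- pedigree$generation >= 1L    # founders carry no records
  birth_year <- as.integer(substr(pedigree$birth_date, 1, 4))
  for (t in seq_along(traits)) {
    ts <- traits[[t]]
    a <- rnorm(config$n_qtl)
    raw <- as.numeric(Q %*% a)
    sc <- sqrt(ts$h2 / stats::var(raw))
    a <- a * sc
    g <- as.numeric(Q %*% a)
    g <- g - mean(g)
    tbv[, t] <- g
    eff_list[[t]] <- data.frame(marker = qtl, trait = ts$name, effect = a,
                                stringsAsFactors = FALSE)
    s2e <- 1 - ts$h2 - ts$ratio
    if (ts$kind == "repeated") {
      keep <- phen_gen & pedigree$sex == "F"
      anim <- pedigree$id[keep]
      if (!length(anim)) next
      pe <- rnorm(length(anim), 0, sqrt(ts$ratio))
      names(pe) <- anim
      for (par in seq_len(ts$parities)) {
        yr <- birth_year[keep] + par
        mo <- sample(1:12, length(anim), TRUE)
        hys <- hys_code(pedigree$herd[keep], yr, mo)
        hys_eff <- .level_effects(hys, sd = config$hys_sd)
        val <- ts$mean + hys_eff + tbv[anim, t] + pe +
          rnorm(length(anim), 0, sqrt(s2e))
        records[[length(records) + 1L]] <- data.frame(
          id = anim, trait = ts$name, value = val, parity = par,
          litter = NA_character_, herd = pedigree$herd[keep],
          date = sprintf("%d-%02d-15", yr, mo), sex = "F",
          stringsAsFactors = FALSE)
      }
    } else {
      keep <- phen_gen
      anim <- pedigree$id[keep]
      if (!length(anim)) next
      litter <- paste0(pedigree$dam[keep], "_", birth_year[keep])
      lit_lev <- unique(litter)
      lit_eff <- stats::setNames(rnorm(length(lit_lev), 0, sqrt(ts$ratio)),
                                 lit_lev)
      yr <- birth_year[keep]
      mo <- sample(1:12, length(anim), TRUE)
      hys <- hys_code(pedigree$herd[keep], yr, mo, sex = pedigree$sex[keep])
      hys_eff <- .level_effects(hys, sd = config$hys_sd)
      val <- ts$mean + hys_eff + tbv[anim, t] + lit_eff[litter] +
        rnorm(length(anim), 0, sqrt(s2e))
      records[[length(records) + 1L]] <- data.frame(
        id = anim, trait = ts$name, value = unname(val), parity = 1L,
        litter = litter, herd = pedigree$herd[keep],
        date = sprintf("%d-%02d-15", yr, mo), sex = pedigree$sex[keep],
        stringsAsFactors = FALSE)
    }
  }
  list(records = do.call(rbind, records), tbv = tbv,
       qtl_effects = do.call(rbind, eff_list), qtl_markers = qtl)
}

## per-level fixed effects drawn once per level (names = codes)
.level_effects <- function(codes, sd = 0.3) {
  lev <- unique(codes)
  eff <- stats::setNames(rnorm(length(lev), 0, sd), lev)
  unname(eff[codes])
}

#' Simulate a complete multi-population data bundle
#'
#' Runs founders, pedigree dropdown and phenotype assignment under the
#' configured master seed (byte-identical on rerun) and returns everything
#' downstream modules consume.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_bundle`: `config`, `pedigree`, `seq_panel`,
#'   `chip_panel`, `records`, `tbv`, `qtl_effects`, `qtl_markers`.
#' @export
simulate_population <- function(config) {
  with_seed(config$seed, {
    founders <- simulate_founders(config)
    drop <- simulate_pedigree_and_dropdown(config, founders)
    phen <- assign_qtl_and_phenotypes(config, drop$panel, drop$pedigree)
    chip <- subset_panel(drop$panel, markers = drop$chip_markers,
                         label = "chip")
    structure(list(config = config, pedigree = drop$pedigree,
                   seq_panel = drop$panel, chip_panel = chip,
                   records = phen$records, tbv = phen$tbv,
                   qtl_effects = phen$qtl_effects,
                   qtl_markers = phen$qtl_markers),
              class = "sim_bundle")
  })
}

#' @exportS3Method base::print
print.sim_bundle <- function(x, ...) {
  cat(sprintf(paste0("sim_bundle: %d animals in %d population(s), ",
                     "%d sequence / %d chip markers, %d QTL, %d records\n"),
              nrow(x$pedigree), x$config$n_populations,
              ncol(x$seq_panel$dosage), ncol(x$chip_panel$dosage),
              length(x$qtl_markers), nrow(x$records)))
  invisible(x)
}
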