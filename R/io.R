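## Readers and writers: pedigree/phenotype CSV, PLINK-style .ped/.map text,
## VCF with GT and DS fields, QTL-region tables, relationship matrices
## (lower-triangle text and a binary container with an id header).
## Conventions: 0 = missing parent; 1-based inclusive bp positions.

#' Write / read a pedigree CSV
#'
#' Columns: `id, sire, dam, sex, birth_date, population, herd` (0 denotes a
#' missing parent).
#' @param ped pedigree data frame.
#' @param path file path.
#' @export
write_pedigree <- function(ped, path) {
  cols <- c("id", "sire", "dam", "sex", "birth_date", "population", "herd")
  .check(all(cols %in% names(ped)), paste("pedigree needs columns:",
                                          paste(cols, collapse = ", ")))
  out <- ped[, cols]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- as.data.frame(data.table::fread(path, colClasses = "character"))
  ped$sire[ped$sire == "0"] <- NA
  ped$dam[ped$dam == "0"] <- NA
  ped
}

#' Write / read a phenotype-record CSV
#'
#' Columns: `id, trait, value, parity, litter, herd, date, sex`.
#' @param records record data frame.
#' @param path file path.
#' @export
write_records <- function(records, path) {
  data.table::fwrite(records, path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- as.data.frame(data.table::fread(path))
  rec$id <- as.character(rec$id)
  rec$value <- as.numeric(rec$value)
  rec
}

#' Write a corrected-phenotype table
#' @param yc data frame `id`, `y_c`, `reliability` (from [derive_yc()]).
#' @param trait trait label recorded in the file.
#' @param path file path.
#' @export
write_yc <- function(yc, trait, path) {
  out <- data.frame(id = yc$id, trait = trait, y_c = yc$y_c,
                    reliability = yc$reliability)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Write a genotype panel as PLINK-style .ped/.map text
#'
#' The .map holds chromosome, marker id, 0 genetic distance and bp position;
#' the .ped holds family/individual ids, parents 0, sex 0, phenotype -9 and
#' two allele calls per marker (`a1`/`a2` letters; missing dosage writes
#' `0 0`).
#'
#' @param panel `genotype_panel`.
#' @param prefix output path prefix (writes `prefix.ped`, `prefix.map`).
#' @export
write_plink <- function(panel, prefix) {
  map <- panel$map
  data.table::fwrite(data.frame(map$chrom, map$marker, 0, map$pos),
                     paste0(prefix, ".map"), sep = "\t", col.names = FALSE)
  M <- panel$dosage
  a1 <- if ("a1" %in% names(map)) map$a1 else rep("A", ncol(M))
  a2 <- if ("a2" %in% names(map)) map$a2 else rep("B", ncol(M))
  lines <- vapply(seq_len(nrow(M)), function(i) {
    d <- round(M[i, ])
    first <- ifelse(is.na(d), "0", ifelse(d >= 1, a2, a1))
    second <- ifelse(is.na(d), "0", ifelse(d == 2, a2, a1))
    paste(c(rownames(M)[i], rownames(M)[i], "0", "0", "0", "-9",
            as.vector(rbind(first, second))), collapse = " ")
  }, "")
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read a PLINK-style .ped/.map pair into a genotype panel
#'
#' Dosages count the second (alternate) allele per marker, taken as the
#' rarer allele letter unless `alt` is supplied; `0 0` calls become NA.
#'
#' @param prefix path prefix of the `.ped`/`.map` pair.
#' @param label panel label.
#' @return `genotype_panel`.
#' @export
read_plink <- function(prefix, label = "sequence") {
  map <- as.data.frame(data.table::fread(paste0(prefix, ".map"),
                                         col.names = c("chrom", "marker",
                                                       "cm", "pos")))
  ped <- as.data.frame(data.table::fread(paste0(prefix, ".ped"),
                                         header = FALSE,
                                         colClasses = "character"))
  ids <- ped[[2]]
  allele_cols <- ped[, -(1:6), drop = FALSE]
  m <- nrow(map)
  .check(ncol(allele_cols) == 2 * m, ".ped column count does not match .map")
  M <- matrix(NA_real_, length(ids), m,
              dimnames = list(ids, map$marker))
  for (j in seq_len(m)) {
    x1 <- allele_cols[[2 * j - 1]]
    x2 <- allele_cols[[2 * j]]
    obs <- c(x1, x2)
    alleles <- setdiff(unique(obs), "0")
    alt <- if (length(alleles) >= 2) {
      tab <- table(factor(obs, levels = alleles))
      names(tab)[which.min(tab)]
    } else if (length(alleles) == 1) alleles else NA
    miss <- x1 == "0" | x2 == "0"
    M[, j] <- ifelse(miss, NA_real_, (x1 == alt) + (x2 == alt))
  }
  genotype_panel(M, data.frame(marker = map$marker, chrom = map$chrom,
                               pos = map$pos, stringsAsFactors = FALSE),
                 label = label)
}

#' Write a genotype panel as VCF with GT and DS fields
#'
#' Hard genotypes are the rounded dosages; DS carries the (possibly
#' fractional) dosage itself.
#'
#' @param panel `genotype_panel`.
#' @param path output path (plain text).
#' @export
write_vcf <- function(panel, path) {
  M <- panel$dosage
  map <- panel$map
  ids <- rownames(M)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(M))) {
    d <- M[, j]
    hard <- round(d)
    gt <- ifelse(is.na(d), "./.", gt_codes[hard + 1])
    ds <- ifelse(is.na(d), ".", format(d, trim = TRUE, digits = 6))
    writeLines(paste(c(map$chrom[j], map$pos[j], map$marker[j],
                       if ("a1" %in% names(map)) map$a1[j] else "A",
                       if ("a2" %in% names(map)) map$a2[j] else "B",
                       ".", "PASS", ".", "GT:DS",
                       paste0(gt, ":", ds)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF (GT and/or DS) into a genotype panel
#'
#' Uses the DS field when present, otherwise counts alternate alleles in
#' GT. Reads through `vcfR` when installed, with a plain-text fallback
#' parser for the simple single-ALT files this package writes.
#'
#' @param path VCF path (uncompressed text).
#' @param label panel label.
#' @return `genotype_panel`.
#' @export
read_vcf_panel <- function(path, label = "sequence") {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  ids <- header[-(1:9)]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  m <- length(rows)
  map <- data.frame(marker = vapply(rows, `[[`, "", 3),
                    chrom = vapply(rows, `[[`, "", 1),
                    pos = as.integer(vapply(rows, `[[`, "", 2)),
                    a1 = vapply(rows, `[[`, "", 4),
                    a2 = vapply(rows, `[[`, "", 5),
                    stringsAsFactors = FALSE)
  suppressWarnings(map$chrom <- ifelse(is.na(as.numeric(map$chrom)),
                                       map$chrom, as.numeric(map$chrom)))
  M <- matrix(NA_real_, length(ids), m, dimnames = list(ids, map$marker))
  for (j in seq_len(m)) {
    fmt <- strsplit(rows[[j]][9], ":", fixed = TRUE)[[1]]
    ds_idx <- match("DS", fmt)
    gt_idx <- match("GT", fmt)
    cells <- strsplit(rows[[j]][-(1:9)], ":", fixed = TRUE)
    if (!is.na(ds_idx)) {
      v <- vapply(cells, function(cc) cc[ds_idx], "")
      M[, j] <- suppressWarnings(as.numeric(v))
    } else if (!is.na(gt_idx)) {
      gt <- vapply(cells, function(cc) cc[gt_idx], "")
      M[, j] <- ifelse(grepl("\\.", gt), NA_real_,
                       vapply(strsplit(gsub("\\|", "/", gt), "/"),
                              function(a) sum(a == "1"), 0))
    }
  }
  genotype_panel(M, map, label = label)
}

#' Write / read a QTL-region table
#'
#' Tab-separated columns `chrom`, `start_bp`, `end_bp`, `trait_category`,
#' `source`; 1-based inclusive coordinates.
#' @param regions QTL-region data frame.
#' @param path file path.
#' @export
write_qtl_regions <- function(regions, path) {
  data.table::fwrite(regions, path, sep = "\t")
  invisible(path)
}

#' @rdname write_qtl_regions
#' @export
read_qtl_regions <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Convert a GFF-like table to QTL regions
#'
#' Accepts the 9-column GFF dialect (seqid, source, type, start, end, score,
#' strand, phase, attributes); the trait category is taken from a
#' `trait=...` or `Name=...` attribute, falling back to the `type` column.
#'
#' @param path GFF file path.
#' @return QTL-region data frame (`chrom`, `start_bp`, `end_bp`,
#'   `trait_category`, `source`).
#' @export
qtl_from_gff <- function(path) {
  gff <- as.data.frame(data.table::fread(path, header = FALSE, sep = "\t",
                                         col.names = c("seqid", "source",
                                                       "type", "start", "end",
                                                       "score", "strand",
                                                       "phase", "attributes")))
  attr_get <- function(s, key) {
    m <- regmatches(s, regexpr(paste0(key, "=[^;]+"), s))
    if (length(m)) sub(paste0(key, "="), "", m) else NA_character_
  }
  cat_of <- vapply(gff$attributes, function(s) {
    v <- attr_get(s, "trait")
    if (is.na(v)) v <- attr_get(s, "Name")
    v
  }, "", USE.NAMES = FALSE)
  cat_of[is.na(cat_of)] <- gff$type[is.na(cat_of)]
  data.frame(chrom = gff$seqid, start_bp = gff$start, end_bp = gff$end,
             trait_category = cat_of, source = gff$source,
             stringsAsFactors = FALSE)
}

#' Write / read a relationship matrix as id-indexed lower-triangle text
#'
#' The text format holds one `id_i id_j value` row per lower-triangle
#' element (full precision); the binary container stores the id header and
#' the lower triangle as doubles and round-trips bit-exactly.
#'
#' @param R symmetric matrix with id dimnames.
#' @param path output path.
#' @param format `"text"` or `"binary"`.
#' @export
write_relmat <- function(R, path, format = c("text", "binary")) {
  format <- match.arg(format)
  ids <- rownames(R)
  .check(!is.null(ids), "matrix needs id dimnames")
  n <- nrow(R)
  if (format == "text") {
    lt <- which(lower.tri(R, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id_i = ids[lt[, 1]], id_j = ids[lt[, 2]],
                     value = sprintf("%.17g", R[lt]))
    data.table::fwrite(df, path, sep = "\t")
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin("RELMAT1", con)
    writeBin(as.integer(n), con)
    for (id in ids) writeBin(id, con)
    writeBin(as.numeric(R[lower.tri(R, diag = TRUE)]), con)
  }
  invisible(path)
}

#' @rdname write_relmat
#' @export
read_relmat <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "text") {
    df <- as.data.frame(data.table::fread(path, colClasses = list(
      character = c("id_i", "id_j"))))
    ids <- unique(df$id_i)
    n <- length(ids)
    R <- matrix(0, n, n, dimnames = list(ids, ids))
    i <- match(df$id_i, ids); j <- match(df$id_j, ids)
    v <- as.numeric(df$value)
    R[cbind(i, j)] <- v
    R[cbind(j, i)] <- v
    R
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "character")
    .check(identical(magic, "RELMAT1"), "not a relmat binary container")
    n <- readBin(con, "integer")
    ids <- vapply(seq_len(n), function(i) readBin(con, "character"), "")
    vals <- readBin(con, "numeric", n * (n + 1) / 2)
    R <- matrix(0, n, n, dimnames = list(ids, ids))
    R[lower.tri(R, diag = TRUE)] <- vals
    R <- R + t(R) - diag(diag(R))
    R
  }
}
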