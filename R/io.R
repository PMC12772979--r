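# Readers and writers for the package's plain-text interchange formats:
# long genotype CSV (canonical), VCF genotype ingest, haplotype read-count
# CSV and FST-landscape CSV. CSV round-trips are lossless.

#' Read a genotype table from CSV or VCF
#'
#' The canonical interchange format is a long CSV with columns `indiv`,
#' `collection`, `repunit`, `locus`, `allele_1`, `allele_2` (missing cells
#' empty). VCF input is supported for genotype ingest: multi-allelic
#' records are preserved (alleles are the REF/ALT strings), `./.` becomes a
#' missing cell, and the locus id is the VCF ID field when present,
#' otherwise `CHROM_POS`. Samples are mapped to collections/reporting
#' units through a sidecar table.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"vcf"`.
#' @param collection_map tibble (or CSV path) with `indiv`, `collection`
#'   and optionally `repunit`; required meaningfully only for VCF input.
#' @return long genotype tibble; duplicate (indiv, locus) rows are an
#'   error.
#' @export
read_genotypes <- function(path, format = c("auto", "csv", "vcf"),
                           collection_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "csv"
  }
  if (is.character(collection_map)) {
    collection_map <- readr::read_csv(collection_map, col_types = readr::cols(),
                                      progress = FALSE)
  }
  g <- if (format == "csv") read_genotypes_csv(path) else
    read_genotypes_vcf(path, collection_map)
  validate_genotypes(g)
  g
}

read_genotypes_csv <- function(path) {
  g <- readr::read_csv(path, na = "", progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("indiv", "collection", "locus", "allele_1", "allele_2")
  if (!all(need %in% names(g))) {
    abort(paste0("genotype CSV must have columns ",
                 paste(need, collapse = ", "), ": ", path))
  }
  if (!"repunit" %in% names(g)) g$repunit <- g$collection
  prob <- readr::problems(g)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed genotype CSV %s: first problem at line %d (%s)",
                  path, prob$row[1], prob$expected[1]))
  }
  g
}

read_genotypes_vcf <- function(path, collection_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste(fix[, "CHROM"], fix[, "POS"], sep = "_"), fix[, "ID"])
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- lapply(seq_len(nrow(fix)), function(i) {
    c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
  })
  samples <- colnames(gt)
  rows <- lapply(seq_len(nrow(gt)), function(i) {
    parts <- strsplit(gt[i, ], "[/|]")
    a <- vapply(parts, function(p) {
      if (length(p) != 2 || any(p == ".") || any(is.na(p))) {
        c(NA_character_, NA_character_)
      } else {
        alleles[[i]][as.integer(p) + 1]
      }
    }, character(2))
    tibble(indiv = samples, locus = unname(ids[i]),
           allele_1 = unname(a[1, ]), allele_2 = unname(a[2, ]))
  })
  g <- bind_rows(rows)
  if (!is.null(collection_map)) {
    g <- g |> left_join(collection_map, by = "indiv")
  }
  if (!"collection" %in% names(g)) g$collection <- "unassigned"
  g$collection <- coalesce(g$collection, "unassigned")
  if (!"repunit" %in% names(g)) g$repunit <- g$collection
  g |> select("indiv", "collection", "repunit", "locus",
              "allele_1", "allele_2") |>
    arrange(.data$indiv, .data$locus)
}

#' Write a genotype table to the canonical long CSV
#'
#' @param genotypes long genotype tibble.
#' @param path output path. Missing alleles are written as empty fields so
#'   `write -> read` round-trips losslessly.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  validate_genotypes(genotypes)
  readr::write_csv(genotypes, path, na = "")
  invisible(path)
}

#' Read / write haplotype read-count tables
#'
#' CSV with columns `indiv`, `locus`, `haplotype`, `depth`.
#'
#' @param path file path.
#' @return tibble (`read_haplotype_reads`) or `path` invisibly.
#' @export
read_haplotype_reads <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    indiv = readr::col_character(), locus = readr::col_character(),
    haplotype = readr::col_character(), depth = readr::col_integer()),
    progress = FALSE)
}

#' @rdname read_haplotype_reads
#' @param reads tibble `indiv`, `locus`, `haplotype`, `depth`.
#' @export
write_haplotype_reads <- function(reads, path) {
  readr::write_csv(reads, path)
  invisible(path)
}

#' Read / write FST landscapes
#'
#' CSV with columns `locus`, `chrom`, `pos`, `pair_id`, `fst`. Chromosome
#' lengths travel in a separate two-column TSV (`chrom`, `length`) read
#' with [read_chrom_lengths()].
#'
#' @param path file path.
#' @return tibble (readers) or `path` invisibly (writers).
#' @export
read_fst_landscape <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    locus = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_double(), pair_id = readr::col_character(),
    fst = readr::col_double()), progress = FALSE)
}

#' @rdname read_fst_landscape
#' @param landscape long FST landscape tibble.
#' @export
write_fst_landscape <- function(landscape, path) {
  readr::write_csv(landscape |>
                     select("locus", "chrom", "pos", "pair_id", "fst"), path)
  invisible(path)
}

#' @rdname read_fst_landscape
#' @export
read_chrom_lengths <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), length = readr::col_double()),
    progress = FALSE)
}

#' @rdname read_fst_landscape
#' @param chrom_lengths tibble `chrom`, `length`.
#' @export
write_chrom_lengths <- function(chrom_lengths, path) {
  readr::write_tsv(chrom_lengths, path)
  invisible(path)
}
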