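# Genotype calling from amplicon haplotype read counts, with the depth,
# depth-ratio, missingness and HWE filtering rules used for GT-seq
# microhaplotype panels.

#' Configuration for microhaplotype genotype calling and filtering
#'
#' Defaults reproduce the standard GT-seq filtering recipe: a cell needs at
#' least 20 reads at the locus to be called; haplotypes with less than 0.2
#' of the top haplotype's depth are discarded; individuals must be called
#' at more than 75% of loci and (then) loci in more than 75% of remaining
#' individuals; loci out of Hardy-Weinberg equilibrium (p < 0.05) in more
#' than half of the reference collections are removed.
#'
#' @param min_locus_depth minimum total reads per individual per locus
#'   (default 20); below it the cell is missing.
#' @param min_depth_ratio minimum ratio of a haplotype's depth to the
#'   highest-depth haplotype in the cell (default 0.2); haplotypes below it
#'   are dropped.
#' @param min_indiv_callrate,min_locus_callrate strict (`>`) call-rate
#'   thresholds for the two-pass missingness filter (defaults 0.75).
#' @param hwe_alpha significance level for the HWE filter (default 0.05).
#' @param hwe_collection_majority number of out-of-HWE collections at which
#'   a locus is removed; default `floor(n_collections / 2) + 1`, i.e. more
#'   than half (8 when there are 15 collections).
#' @param min_hwe_n collections with fewer called individuals than this at
#'   a locus are excluded from the majority count (default 5).
#' @return a `call_config` list.
#' @export
call_config <- function(min_locus_depth = 20, min_depth_ratio = 0.2,
                        min_indiv_callrate = 0.75, min_locus_callrate = 0.75,
                        hwe_alpha = 0.05, hwe_collection_majority = NULL,
                        min_hwe_n = 5) {
  stopifnot(min_locus_depth >= 1,
            min_depth_ratio > 0, min_depth_ratio <= 1,
            min_indiv_callrate > 0, min_indiv_callrate <= 1,
            min_locus_callrate > 0, min_locus_callrate <= 1)
  structure(list(min_locus_depth = min_locus_depth,
                 min_depth_ratio = min_depth_ratio,
                 min_indiv_callrate = min_indiv_callrate,
                 min_locus_callrate = min_locus_callrate,
                 hwe_alpha = hwe_alpha,
                 hwe_collection_majority = hwe_collection_majority,
                 min_hwe_n = min_hwe_n),
            class = "call_config")
}

#' Call one genotype from a haplotype read-depth map
#'
#' Applies the per-cell rules: a cell with total depth below
#' `min_locus_depth` is missing; haplotypes whose depth ratio against the
#' highest-depth haplotype is below `min_depth_ratio` are dropped; the call
#' is heterozygous for the two highest-depth survivors (second-place ties
#' broken by lexicographic haplotype id and flagged), homozygous when a
#' single haplotype survives. More than two survivors are flagged
#' (`"extra_haplotypes"`, possible contamination or a paralog) and the top
#' two retained.
#'
#' @param depths named non-negative integer vector (haplotype -> reads);
#'   may be empty.
#' @param cfg a [call_config()].
#' @return list with `alleles` (character length-2, or `NA` when missing),
#'   `depths` (reads supporting the retained alleles) and `flag`.
#' @export
call_genotype <- function(depths, cfg = call_config()) {
  miss <- list(alleles = c(NA_character_, NA_character_),
               depths = c(NA_integer_, NA_integer_), flag = "missing")
  if (length(depths) == 0 || sum(depths) < cfg$min_locus_depth) return(miss)
  if (any(depths < 0)) abort("read depths must be non-negative")
  keep <- depths / max(depths) >= cfg$min_depth_ratio
  surv <- depths[keep]
  surv <- surv[order(-surv, names(surv))]
  if (length(surv) == 1) {
    return(list(alleles = rep(names(surv), 2), depths = rep(unname(surv), 2),
                flag = "hom"))
  }
  flag <- "het"
  if (length(surv) > 2) flag <- "extra_haplotypes"
  if (length(surv) >= 3 && surv[2] == surv[3]) flag <- "tie_second"
  list(alleles = names(surv)[1:2], depths = unname(surv)[1:2], flag = flag)
}

#' Call genotypes for a full haplotype read table
#'
#' Vectorised application of the [call_genotype()] rules to every
#' (individual, locus) cell. Cells absent from the read table, and cells
#' failing the depth rule, are emitted as missing so that the output covers
#' the complete individual x locus grid.
#'
#' @param reads tibble `indiv`, `locus`, `haplotype`, `depth`.
#' @param collections optional tibble (`indiv`, `collection`, `repunit`)
#'   joined onto the calls; unknown individuals get collection
#'   `"unassigned"`.
#' @param cfg a [call_config()].
#' @return long genotype tibble (`indiv`, `collection`, `repunit`, `locus`,
#'   `allele_1`, `allele_2`, `flag`).
#' @export
call_genotypes <- function(reads, collections = NULL, cfg = call_config()) {
  stopifnot(all(c("indiv", "locus", "haplotype", "depth") %in% names(reads)))
  calls <- reads |>
    group_by(.data$indiv, .data$locus) |>
    arrange(desc(.data$depth), .data$haplotype, .by_group = TRUE) |>
    mutate(total = sum(.data$depth), ratio = .data$depth / max(.data$depth),
           n_surv = sum(.data$ratio >= cfg$min_depth_ratio)) |>
    filter(.data$total >= cfg$min_locus_depth,
           .data$ratio >= cfg$min_depth_ratio) |>
    summarise(
      allele_1 = .data$haplotype[1],
      allele_2 = if (n() >= 2) .data$haplotype[2] else .data$haplotype[1],
      flag = if (n() == 1) "hom" else if (.data$n_surv[1] > 2)
        "extra_haplotypes" else "het",
      .groups = "drop")
  grid <- crossing(indiv = unique(reads$indiv), locus = unique(reads$locus))
  out <- grid |>
    left_join(calls, by = c("indiv", "locus")) |>
    mutate(flag = coalesce(.data$flag, "missing"))
  if (!is.null(collections)) {
    out <- out |> left_join(collections, by = "indiv") |>
      mutate(collection = coalesce(.data$collection, "unassigned"))
  } else {
    out <- out |> mutate(collection = "unassigned", repunit = NA_character_)
  }
  if (!"repunit" %in% names(out)) out$repunit <- NA_character_
  out |>
    select("indiv", "collection", "repunit", "locus",
           "allele_1", "allele_2", "flag") |>
    arrange(.data$indiv, .data$locus)
}

#' Two-pass missingness filter (individuals first, then loci)
#'
#' Pass 1 retains individuals called at strictly more than
#' `min_indiv_callrate` of loci; pass 2 then retains loci called in strictly
#' more than `min_locus_callrate` of the *remaining* individuals. The order
#' matters: locus call rates are recomputed after individuals are dropped.
#' Re-running the filter on its own output changes nothing.
#'
#' @param genotypes long genotype tibble covering a full individual x locus
#'   grid (missing cells as `NA` alleles).
#' @param cfg a [call_config()].
#' @return list: `genotypes` (filtered), `dropped_indivs`, `dropped_loci`,
#'   and `report` (call rates at each pass).
#' @export
missingness_filter <- function(genotypes, cfg = call_config()) {
  validate_genotypes(genotypes)
  n_loci <- length(unique(genotypes$locus))
  ind_rate <- genotypes |>
    group_by(.data$indiv) |>
    summarise(callrate = sum(!is.na(.data$allele_1)) / n_loci)
  keep_ind <- ind_rate$indiv[ind_rate$callrate > cfg$min_indiv_callrate]
  g1 <- genotypes |> filter(.data$indiv %in% keep_ind)
  n_ind <- length(keep_ind)
  loc_rate <- g1 |>
    group_by(.data$locus) |>
    summarise(callrate = if (n_ind == 0) 0 else
      sum(!is.na(.data$allele_1)) / n_ind)
  keep_loc <- loc_rate$locus[loc_rate$callrate > cfg$min_locus_callrate]
  list(genotypes = g1 |> filter(.data$locus %in% keep_loc),
       dropped_indivs = setdiff(ind_rate$indiv, keep_ind),
       dropped_loci = setdiff(loc_rate$locus, keep_loc),
       report = list(indiv_callrate = ind_rate, locus_callrate = loc_rate))
}

#' Hardy-Weinberg locus filter across reference collections
#'
#' For each locus, counts the collections in which the HWE test
#' ([hwe_test()]) is significant at `hwe_alpha`; the locus is removed when
#' that count reaches `hwe_collection_majority` (default: more than half of
#' the collections). Collections with fewer than `min_hwe_n` called
#' individuals at the locus are excluded from the count — they carry no
#' power and would otherwise dilute the majority rule.
#'
#' @param genotypes long genotype tibble with `collection` labels.
#' @param cfg a [call_config()].
#' @param n_perm permutations for multi-allelic HWE tests.
#' @param seed optional integer seed (Monte-Carlo HWE tests).
#' @return list: `retained_loci`, `dropped_loci`, `pvalues` (tibble `locus`,
#'   `collection`, `n_called`, `p`, `tested`).
#' @export
hwe_locus_filter <- function(genotypes, cfg = call_config(), n_perm = 10000,
                             seed = NULL) {
  validate_genotypes(genotypes)
  colls <- sort(unique(genotypes$collection))
  majority <- cfg$hwe_collection_majority %||% (floor(length(colls) / 2) + 1)
  run <- function() {
    pv <- genotypes |>
      group_by(.data$locus, .data$collection) |>
      summarise(n_called = sum(!is.na(.data$allele_1)),
                p = if (n_called[1] >= cfg$min_hwe_n)
                  hwe_test(.data$allele_1[!is.na(.data$allele_1)],
                           .data$allele_2[!is.na(.data$allele_1)],
                           n_perm = n_perm)
                else NA_real_,
                .groups = "drop") |>
      mutate(tested = !is.na(.data$p))
    verdict <- pv |>
      group_by(.data$locus) |>
      summarise(n_sig = sum(.data$tested & .data$p < cfg$hwe_alpha))
    dropped <- verdict$locus[verdict$n_sig >= majority]
    list(retained_loci = setdiff(verdict$locus, dropped),
         dropped_loci = dropped, pvalues = pv)
  }
  if (is.null(seed)) run() else withr::with_seed(check_scalar_seed(seed), run())
}
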