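# FST-ranked, windowed downsampling of candidate loci for a GT-seq panel.
#
# The four-step algorithm: (1) take the top-N loci by FST per chromosome per
# pairwise comparison, (2) deduplicate, (3) drop loci whose maximum pairwise
# FST is below a floor, (4) split each chromosome into equal physical
# windows and keep the highest-FST loci per window subject to at most one
# locus per pairwise comparison per chromosome. With the defaults
# (10, 0.2, 6 windows, 2 per window) a saturated 23-chromosome landscape
# yields 6 x 2 x 23 = 276 candidates.

#' Configuration for panel selection
#'
#' @param top_n_per_chrom_pair loci kept per chromosome per pairwise
#'   comparison in step 1 (default 10).
#' @param fst_floor minimum max-pairwise-FST a locus must reach to survive
#'   step 3 (default 0.2).
#' @param windows_per_chrom equal physical windows per chromosome (default 6).
#' @param loci_per_window loci retained per window in step 4 (default 2).
#' @param one_pair_per_chrom if `TRUE` (default) at most one locus per
#'   attributed pairwise comparison is accepted per chromosome, preventing a
#'   single comparison from over-contributing.
#' @return a `selection_config` list.
#' @export
selection_config <- function(top_n_per_chrom_pair = 10, fst_floor = 0.2,
                             windows_per_chrom = 6, loci_per_window = 2,
                             one_pair_per_chrom = TRUE) {
  stopifnot(top_n_per_chrom_pair >= 1, windows_per_chrom >= 1,
            loci_per_window >= 1, fst_floor >= 0, fst_floor <= 1)
  structure(list(top_n_per_chrom_pair = as.integer(top_n_per_chrom_pair),
                 fst_floor = fst_floor,
                 windows_per_chrom = as.integer(windows_per_chrom),
                 loci_per_window = as.integer(loci_per_window),
                 one_pair_per_chrom = isTRUE(one_pair_per_chrom)),
            class = "selection_config")
}

#' Step 1: top loci per chromosome per pairwise comparison
#'
#' For every (chromosome, pair) stratum, returns the `top_n_per_chrom_pair`
#' loci with the highest FST for that pair (fewer when the chromosome has
#' fewer loci). Ties are broken by lower position, then locus id. The result
#' is a multiset: a locus maximal for several pairs appears once per pair.
#'
#' @param landscape long FST landscape (`locus`, `chrom`, `pos`, `pair_id`,
#'   `fst`).
#' @param cfg a [selection_config()].
#' @return tibble of selected rows (same columns as `landscape`).
#' @export
panel_step_top <- function(landscape, cfg = selection_config()) {
  if (nrow(landscape) == 0) abort("`landscape` is empty")
  landscape |>
    group_by(.data$chrom, .data$pair_id) |>
    arrange(desc(.data$fst), .data$pos, .data$locus, .by_group = TRUE) |>
    slice_head(n = cfg$top_n_per_chrom_pair) |>
    ungroup()
}

#' Step 2: reduce the step-1 multiset to unique loci
#'
#' @param multiset output of [panel_step_top()].
#' @return tibble `locus`, `chrom`, `pos`, one row per locus.
#' @export
panel_step_unique <- function(multiset) {
  multiset |> distinct(.data$locus, .data$chrom, .data$pos)
}

# Max pairwise FST and the pair achieving it (ties: lexicographically
# first pair id) for each locus in the landscape.
locus_scores <- function(landscape) {
  landscape |>
    group_by(.data$locus, .data$chrom, .data$pos) |>
    arrange(desc(.data$fst), .data$pair_id, .by_group = TRUE) |>
    summarise(score = .data$fst[1], attributed_pair = .data$pair_id[1],
              .groups = "drop")
}

#' Step 3: drop loci below the FST floor
#'
#' A locus survives iff its maximum FST across all pairwise comparisons
#' reaches `fst_floor`: the rationale is that comparisons with very low
#' overall FST should not force informative loci out, so the maximal
#' (selecting) comparison is what counts.
#'
#' @param loci_set tibble with a `locus` column (step-2 output).
#' @param landscape the full FST landscape.
#' @param cfg a [selection_config()].
#' @return filtered `loci_set`.
#' @export
panel_step_fst_floor <- function(loci_set, landscape, cfg = selection_config()) {
  sc <- locus_scores(landscape |> semi_join(loci_set, by = "locus"))
  keep <- sc$locus[sc$score >= cfg$fst_floor]
  loci_set |> filter(.data$locus %in% keep)
}

#' Step 4: windowed selection with a one-pair-per-chromosome constraint
#'
#' Each chromosome is split into `windows_per_chrom` equal physical windows
#' `[i L/W, (i+1) L/W)` (last window closed at `L`). Loci are ranked by
#' score (max pairwise FST) and accepted greedily across the whole
#' chromosome in descending score order (ties: lower position, then locus
#' id), skipping any locus whose attributed pair was already consumed on
#' that chromosome (when `one_pair_per_chrom`) and any window already
#' holding `loci_per_window` loci. Empty windows simply contribute nothing.
#'
#' @param loci_set step-3 output (tibble with `locus`).
#' @param landscape the full FST landscape.
#' @param chrom_lengths tibble (`chrom`, `length`) covering all loci;
#'   defaults to the landscape's `chrom_lengths` attribute.
#' @param cfg a [selection_config()].
#' @return tibble `locus`, `chrom`, `pos`, `window` (0-based), `score`,
#'   `attributed_pair`.
#' @export
panel_step_windows <- function(loci_set, landscape, chrom_lengths = NULL,
                               cfg = selection_config()) {
  chrom_lengths <- chrom_lengths %||% attr(landscape, "chrom_lengths")
  if (is.null(chrom_lengths)) abort("`chrom_lengths` required (chrom, length)")
  empty_panel <- tibble(locus = character(), chrom = character(),
                        pos = double(), window = double(), score = double(),
                        attributed_pair = character())
  if (nrow(loci_set) == 0) return(empty_panel)
  sc <- locus_scores(landscape |> semi_join(loci_set, by = "locus")) |>
    left_join(chrom_lengths, by = "chrom")
  if (any(is.na(sc$length)) || any(sc$pos > sc$length)) {
    abort("`chrom_lengths` must cover every locus position")
  }
  W <- cfg$windows_per_chrom
  sc <- sc |>
    mutate(window = pmin(floor(.data$pos / (.data$length / W)), W - 1)) |>
    arrange(.data$chrom, desc(.data$score), .data$pos, .data$locus)
  out <- vector("list", 0)
  for (ch in unique(sc$chrom)) {
    rows <- sc[sc$chrom == ch, ]
    win_used <- integer(W)
    pairs_used <- character(0)
    acc <- logical(nrow(rows))
    for (j in seq_len(nrow(rows))) {
      w <- rows$window[j] + 1L
      if (win_used[w] >= cfg$loci_per_window) next
      if (cfg$one_pair_per_chrom && rows$attributed_pair[j] %in% pairs_used) next
      acc[j] <- TRUE
      win_used[w] <- win_used[w] + 1L
      if (cfg$one_pair_per_chrom) {
        pairs_used <- c(pairs_used, rows$attributed_pair[j])
      }
    }
    out[[ch]] <- rows[acc, ]
  }
  bind_rows(out) |>
    select("locus", "chrom", "pos", "window", "score", "attributed_pair") |>
    arrange(.data$chrom, .data$window, desc(.data$score))
}

#' Run the full four-step panel selection
#'
#' @inheritParams panel_step_windows
#' @return the step-4 candidate tibble with attribute `stage_counts`, a
#'   named vector of locus counts after each step.
#' @export
select_panel <- function(landscape, chrom_lengths = NULL,
                         cfg = selection_config()) {
  s1 <- panel_step_top(landscape, cfg)
  s2 <- panel_step_unique(s1)
  s3 <- panel_step_fst_floor(s2, landscape, cfg)
  s4 <- panel_step_windows(s3, landscape, chrom_lengths, cfg)
  attr(s4, "stage_counts") <- c(step1_multiset = nrow(s1),
                                step2_unique = nrow(s2),
                                step3_floor = nrow(s3),
                                step4_windows = nrow(s4))
  s4
}

#' Add supplemental loci to a candidate panel
#'
#' Extras chosen outside the windowed algorithm (e.g. loci tagging known
#' high-differentiation regions or informative genes) are unioned onto the
#' candidate set. Extras already present are rejected with a warning and do
#' not change the count.
#'
#' @param candidates panel tibble with a `locus` column.
#' @param extra_loci character vector of locus ids, or a tibble with
#'   `locus` (and optionally `chrom`, `pos`).
#' @return the augmented panel; new rows carry `NA` score/window.
#' @export
add_supplemental <- function(candidates, extra_loci) {
  if (is.character(extra_loci)) extra_loci <- tibble(locus = extra_loci)
  if (nrow(extra_loci) == 0) return(candidates)
  dup <- extra_loci$locus %in% candidates$locus
  if (any(dup)) {
    warn(paste0("supplemental loci already in panel, skipped: ",
                paste(extra_loci$locus[dup], collapse = ", ")))
    extra_loci <- extra_loci[!dup, , drop = FALSE]
  }
  bind_rows(candidates, extra_loci)
}

#' Attrition bookkeeping across panel-development stages
#'
#' Given ordered locus counts through design and optimisation stages (e.g.
#' 286 designed, 269 surviving primer design, 225 surviving multiplex
#' optimisation, 199 after initial analysis), reports per-stage absolute
#' losses and percentage losses both against the count entering each stage
#' and against the initial count.
#'
#' @param stage_counts named numeric vector of non-increasing counts.
#' @return tibble `stage`, `count`, `loss`, `pct_of_previous`,
#'   `pct_of_initial`.
#' @export
attrition_report <- function(stage_counts) {
  counts <- as.numeric(stage_counts)
  if (length(counts) < 1) abort("need at least one stage count")
  if (any(diff(counts) > 0)) abort("stage counts must be non-increasing")
  loss <- c(NA_real_, -diff(counts))
  prev <- c(NA_real_, counts[-length(counts)])
  tibble(stage = names(stage_counts) %||% paste0("stage", seq_along(counts)),
         count = counts, loss = loss,
         pct_of_previous = 100 * loss / prev,
         pct_of_initial = 100 * loss / counts[1])
}
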