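# Internal helpers shared across modules.

# Dirichlet draws via gamma normalisation; rows are draws. At very small
# concentrations the gamma draws can all underflow to exact zero; the
# distribution's limit there is a categorical draw over the simplex
# corners with probabilities alpha / sum(alpha), which is substituted.
rdirichlet <- function(n, alpha) {
  if (all(alpha == 0) || any(alpha < 0)) {
    abort("Dirichlet alpha must be non-negative with positive mass")
  }
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  sw <- rowSums(x)
  for (i in which(sw == 0)) {
    x[i, sample.int(k, 1, prob = alpha)] <- 1
    sw[i] <- 1
  }
  x / sw
}

check_prob_vector <- function(p, what = "proportions", tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0)) {
    abort(paste0(what, " must be finite and non-negative"))
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("%s must sum to 1 (got %.12f)", what, sum(p)))
  }
  invisible(p)
}

#' Canonical pair identifier for two collections
#'
#' Pair ids are order-invariant: the two labels are sorted before joining,
#' so `pair_id("b", "a")` and `pair_id("a", "b")` are the same id.
#'
#' @param a,b character vectors of collection labels (recycled).
#' @param sep separator placed between the sorted labels.
#' @return character vector of canonical pair ids.
#' @export
pair_id <- function(a, b, sep = "--") {
  paste(pmin(a, b), pmax(a, b), sep = sep)
}

#' Enumerate all pairwise comparisons among collections
#'
#' @param collections character vector of collection labels (deduplicated,
#'   sorted).
#' @return tibble with columns `collection_1`, `collection_2`, `pair_id`,
#'   one row per unordered pair. Eleven collections give the 55 pairwise
#'   comparisons used when ranking loci for panel design.
#' @export
collection_pairs <- function(collections) {
  collections <- sort(unique(as.character(collections)))
  if (length(collections) < 2) {
    return(tibble(collection_1 = character(), collection_2 = character(),
                  pair_id = character()))
  }
  cmb <- combn(collections, 2)
  tibble(collection_1 = cmb[1, ], collection_2 = cmb[2, ],
         pair_id = pair_id(cmb[1, ], cmb[2, ]))
}

# Validate the long genotype-table contract used throughout the package.
validate_genotypes <- function(x, require_repunit = FALSE) {
  need <- c("indiv", "collection", "locus", "allele_1", "allele_2")
  if (require_repunit) need <- c(need, "repunit")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("genotype table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- duplicated(x[c("indiv", "locus")])
  if (any(dup)) {
    abort(sprintf("duplicate (indiv, locus) rows in genotype table (first at row %d)",
                  which(dup)[1]))
  }
  half <- xor(is.na(x$allele_1), is.na(x$allele_2))
  if (any(half)) {
    abort(sprintf("half-missing genotype at row %d: both alleles must be present or both NA",
                  which(half)[1]))
  }
  invisible(x)
}

check_scalar_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) || seed != trunc(seed)) {
    abort("`seed` must be a single integer")
  }
  as.integer(seed)
}
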