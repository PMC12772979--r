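# Seasonal stock-movement tests: Pearson chi-square on season x
# (local / non-local) assignment counts, with Monte-Carlo p-values when
# expected cell counts are small.

#' Build a season x outcome contingency table for one sample site
#'
#' A "success" is an individual whose assigned reporting unit matches the
#' region it was collected from; a "failure" is any other assignment. The
#' summer mixture collection is compared against the winter (baseline)
#' collection of the same region.
#'
#' @param summer,winter tibbles of confidence-filtered assignments with a
#'   `map_repunit` column (e.g. `confidence_filter(...)$retained`).
#' @param region the local reporting unit of the site.
#' @param site optional site label.
#' @return object of class `seasonal_contingency`: a 2x2 integer matrix
#'   (rows winter/summer, columns success/failure) with `site` and
#'   `region` attributes.
#' @export
build_contingency <- function(summer, winter, region, site = NA_character_) {
  stopifnot("map_repunit" %in% names(summer),
            "map_repunit" %in% names(winter))
  if (nrow(summer) == 0) abort(sprintf("site '%s': no summer individuals", site))
  if (nrow(winter) == 0) abort(sprintf("site '%s': no winter individuals", site))
  tab <- rbind(
    winter = c(success = sum(winter$map_repunit == region),
               failure = sum(winter$map_repunit != region)),
    summer = c(success = sum(summer$map_repunit == region),
               failure = sum(summer$map_repunit != region)))
  structure(tab, site = site, region = region,
            class = c("seasonal_contingency", class(tab)))
}

#' Pearson chi-square test with Monte-Carlo p-value
#'
#' Computes the Pearson statistic `X^2 = sum (O - E)^2 / E` (no continuity
#' correction) on a contingency table. When every expected count is at
#' least 5 the asymptotic chi-square p-value is used; otherwise the
#' p-value is simulated: `n_replicates` tables are drawn under the null
#' and `p = (1 + #\{X^2_rep >= X^2_obs\}) / (n_replicates + 1)` — the
#' add-one rule, so p is never 0 and its floor with 5000 replicates is
#' 1/5001 (0.0002 to four decimals). The default replicate generator fixes
#' both margins (via [stats::r2dtable()]), the convention of
#' `chisq.test(simulate.p.value = TRUE)`, under which the simulated and
#' asymptotic references agree for large tables;
#' `sampling = "multinomial"` instead draws each table as one multinomial
#' over cells with the null expected proportions and only the total fixed
#' (its reference distribution is wider than chi-square on 1 df, so its
#' p-values are larger for off-null 2x2 tables).
#'
#' A table with a zero margin is degenerate: statistic 0, p 1.
#'
#' @param table 2x2 (or r x c) matrix of counts, e.g. from
#'   [build_contingency()].
#' @param n_replicates Monte-Carlo replicates (default 5000).
#' @param seed optional integer seed for the simulated p-value.
#' @param method `"auto"` (default), `"asymptotic"` or `"monte_carlo"`.
#' @param sampling replicate generator for the Monte-Carlo p-value.
#' @return tibble `statistic`, `p_value`, `method`, `signif_code`, `site`.
#' @export
chisq_test_mc <- function(table, n_replicates = 5000, seed = NULL,
                          method = c("auto", "asymptotic", "monte_carlo"),
                          sampling = c("conditional", "multinomial")) {
  method <- match.arg(method)
  sampling <- match.arg(sampling)
  tab <- unclass(as.matrix(table))
  if (any(tab < 0)) abort("counts must be non-negative")
  site <- attr(table, "site") %||% NA_character_
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (N == 0 || any(rs == 0) || any(cs == 0)) {
    return(tibble(statistic = 0, p_value = 1, method = "degenerate",
                  signif_code = "NS", site = site))
  }
  E <- outer(rs, cs) / N
  x2 <- sum((tab - E)^2 / E)
  if (method == "auto") {
    method <- if (any(E < 5)) "monte_carlo" else "asymptotic"
  }
  if (method == "asymptotic") {
    df <- (nrow(tab) - 1) * (ncol(tab) - 1)
    p <- pchisq(x2, df, lower.tail = FALSE)
  } else {
    run <- function() {
      if (sampling == "multinomial") {
        reps <- rmultinom(n_replicates, N, as.vector(E) / N)
        x2r <- colSums((reps - as.vector(E))^2 / as.vector(E))
      } else {
        tabs <- r2dtable(n_replicates, rs, cs)
        x2r <- vapply(tabs, function(tt) sum((tt - E)^2 / E), 0)
      }
      (1 + sum(x2r >= x2 - 1e-12)) / (n_replicates + 1)
    }
    p <- if (is.null(seed)) run() else
      withr::with_seed(check_scalar_seed(seed), run())
  }
  tibble(statistic = x2, p_value = p, method = method,
         signif_code = significance_codes(p), site = site)
}

#' Significance banding for movement-test p-values
#'
#' `NS` for p > 0.05, `*` for p < 0.05, `**` for p < 0.01 and `***` for
#' p < 0.001 (p exactly 0.05 is NS).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return character vector of codes.
#' @export
significance_codes <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  dplyr::case_when(p < 0.001 ~ "***",
                   p < 0.01 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "NS")
}

#' Run movement tests for a set of sites
#'
#' @param contingencies list of [build_contingency()] tables.
#' @param n_replicates,seed,sampling forwarded to [chisq_test_mc()]; site
#'   i uses seed `seed + i` so the table of results is reproducible.
#' @return tibble with one row per site: `site`, `region`, `statistic`,
#'   `p_value`, `method`, `signif_code`.
#' @export
movement_tests <- function(contingencies, n_replicates = 5000, seed = 1,
                           sampling = "conditional") {
  seed <- check_scalar_seed(seed)
  rows <- lapply(seq_along(contingencies), function(i) {
    ct <- contingencies[[i]]
    chisq_test_mc(ct, n_replicates = n_replicates, seed = seed + i,
                  sampling = sampling) |>
      mutate(region = attr(ct, "region") %||% NA_character_)
  })
  bind_rows(rows) |>
    select("site", "region", "statistic", "p_value", "method", "signif_code")
}
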