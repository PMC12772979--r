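# End-to-end pipeline: simulate -> FST -> panel selection -> read
# simulation -> genotype calling -> mixture inference -> movement test,
# with every artifact written to disk and a JSON manifest recording seeds
# and file hashes.

#' Assemble a pipeline configuration
#'
#' Stage blocks mirror the module configuration objects; defaults are the
#' standard GT-seq analysis parameters (20-read floor, 0.2 depth ratio,
#' 75%/75% missingness, 0.9 confidence, z in (-5, 5), 5000 chi-square
#' replicates, 10 individuals per mixture site, 6 windows x 2 loci with a
#' 0.2 FST floor and top-10 preselection). Unknown keys are rejected.
#'
#' @param seed global integer seed; stage seeds are derived from it.
#' @param n_pops,fst,n_loci,n_per_pop,n_chroms baseline simulation block.
#' @param mixture_size,true_proportions mixture block (`NULL` proportions =
#'   uniform over units).
#' @param mean_depth,depth_dispersion,error_rate read-simulation block.
#' @param call a [call_config()].
#' @param selection a [selection_config()].
#' @param sweeps,burn_in MCMC block.
#' @param min_posterior,z_bounds confidence filter block.
#' @param n_replicates movement-test Monte-Carlo replicates.
#' @param min_individuals minimum mixture size per site.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_pops = 4, fst = 0.05, n_loci = 120,
                            n_per_pop = 30, n_chroms = 23,
                            mixture_size = 60, true_proportions = NULL,
                            mean_depth = 100, depth_dispersion = 5,
                            error_rate = 0.005,
                            call = call_config(),
                            selection = selection_config(),
                            sweeps = 500, burn_in = 50,
                            min_posterior = 0.9, z_bounds = c(-5, 5),
                            n_replicates = 5000, min_individuals = 10) {
  cfg <- as.list(environment())
  cfg$seed <- check_scalar_seed(seed)
  structure(cfg, class = "pipeline_config")
}

# Merge a YAML (or list) override into the defaults; unknown keys error.
load_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  base <- pipeline_config()
  unknown <- setdiff(names(x), names(base))
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, x)
}

#' Run the full GSI pipeline on synthetic data
#'
#' Executes every stage in order, writing each artifact as CSV/JSON under
#' `out_dir` and returning a manifest (also written as `manifest.json`)
#' that records the configuration, derived seeds and an md5 hash of every
#' output file, so identical configurations produce identical manifests.
#'
#' @param config a [pipeline_config()], a list of overrides, or a YAML
#'   path.
#' @param out_dir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("gsi_")) {
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  artifacts <- character(0)
  keep <- function(p) { artifacts[[length(artifacts) + 1]] <<- p; p }

  inform("stage 1/6: simulating baseline populations")
  model <- random_population_model(n_loci = cfg$n_loci, n_pops = cfg$n_pops,
                                   fst = cfg$fst, n_chroms = cfg$n_chroms,
                                   seed = cfg$seed)
  freqs <- draw_population_freqs(model, seed = cfg$seed + 1)
  baseline_geno <- simulate_baseline(freqs, n_per_pop = cfg$n_per_pop,
                                     seed = cfg$seed + 2)
  keep(write_genotypes(baseline_geno, pth("baseline_genotypes.csv")))

  inform("stage 2/6: pairwise FST landscape")
  landscape <- pairwise_fst(baseline_geno, loci_info = model$loci) |>
    filter(!is.na(.data$fst))
  keep(write_fst_landscape(landscape, pth("fst_landscape.csv")))
  chrom_lengths <- model$loci |>
    group_by(.data$chrom) |>
    summarise(length = max(.data$pos) + 1)
  keep(write_chrom_lengths(chrom_lengths, pth("chrom_lengths.tsv")))

  inform("stage 3/6: panel selection")
  panel <- select_panel(landscape, chrom_lengths, cfg$selection)
  # a demo baseline at modest divergence may clear the FST floor at only a
  # handful of loci, too few for a meaningful assignment demonstration
  panel_loci <- if (nrow(panel) >= 20) panel$locus else {
    inform(sprintf("panel selection kept %d loci; running assignment on all %d loci",
                   nrow(panel), nrow(model$loci)))
    model$loci$locus
  }
  readr::write_csv(panel, keep(pth("panel.csv")))
  jsonlite::write_json(
    as.list(attr(panel, "stage_counts")),
    keep(pth("panel_attrition.json")), auto_unbox = TRUE)

  inform("stage 4/6: mixture reads and genotype calling")
  units <- sort(unique(baseline_geno$repunit))
  props <- cfg$true_proportions %||%
    setNames(rep(1 / length(units), length(units)), units)
  mix <- simulate_mixture(freqs |> filter(.data$locus %in% panel_loci),
                          props, cfg$mixture_size, seed = cfg$seed + 3)
  reads <- simulate_reads(mix$genotypes, mean_depth = cfg$mean_depth,
                          depth_dispersion = cfg$depth_dispersion,
                          error_rate = cfg$error_rate, seed = cfg$seed + 4)
  keep(write_haplotype_reads(reads, pth("mixture_reads.csv")))
  calls <- call_genotypes(reads, cfg = cfg$call)
  filtered <- missingness_filter(calls |> select(-"flag"), cfg$call)
  keep(write_genotypes(filtered$genotypes, pth("mixture_genotypes.csv")))

  inform("stage 5/6: mixture inference")
  baseline <- gsi_baseline(baseline_geno |>
                             filter(.data$locus %in% panel_loci))
  fit <- infer_mixture(baseline, filtered$genotypes,
                       mcmc_config(n_sweeps = cfg$sweeps,
                                   burn_in = cfg$burn_in,
                                   seed = cfg$seed + 5))
  readr::write_csv(fit$indiv, keep(pth("assignments.csv")))
  readr::write_csv(fit$repunit_proportions, keep(pth("mixing_proportions.csv")))
  report <- mixture_composition_report(
    list(mixture = fit), min_individuals = cfg$min_individuals,
    min_posterior = cfg$min_posterior, z_bounds = cfg$z_bounds)
  readr::write_csv(report, keep(pth("composition_report.csv")))

  inform("stage 6/6: movement test")
  flt <- confidence_filter(fit, cfg$min_posterior, cfg$z_bounds)
  winter <- tibble(map_repunit = baseline_geno |>
                     distinct(.data$indiv, .data$repunit) |> pull("repunit"))
  local_region <- units[1]
  ct <- build_contingency(flt$retained, winter, region = local_region,
                          site = "mixture")
  mt <- movement_tests(list(ct), n_replicates = cfg$n_replicates,
                       seed = cfg$seed + 6)
  readr::write_csv(mt, keep(pth("movement_tests.csv")))

  manifest <- list(
    package = "gsikit",
    version = as.character(utils::packageVersion("gsikit")),
    seed = cfg$seed,
    stage_seeds = cfg$seed + 0:6,
    config = cfg[setdiff(names(cfg), c("call", "selection"))],
    call_config = unclass(cfg$call),
    selection_config = unclass(cfg$selection),
    outputs = as.list(setNames(unname(tools::md5sum(unlist(artifacts))),
                               basename(unlist(artifacts)))))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
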