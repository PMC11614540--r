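# flatten the corrected-statistic tables into the estimates.tsv layout
# (statistic, stratum, raw, corrected, mc_se, n_resamples, seed): the
# comparative raw-vs-corrected listing
estimates_table <- function(summaries, n_resamples, seed) {
  pick <- function(df) {
    df[c("statistic", "stratum", "numerator", "denominator", "raw",
         "corrected", "mc_se")]
  }
  out <- rbind(pick(summaries$modality_presence),
               pick(summaries$versatility),
               pick(summaries$venn),
               pick(summaries$proficiency),
               pick(summaries$special_activities))
  out$n_resamples <- n_resamples
  out$seed <- as.integer(seed)
  out
}

#' Run the whole analysis pipeline
#'
#' Reads the quote database, society table and time tree; applies the
#' eligibility gate; aggregates quote codes to society codes; derives
#' isolation weights; computes raw and phylogenetically corrected summary
#' statistics; and writes the outputs: `society_codes.tsv`,
#' `exclusion_report.tsv`, `code_diagnostics.tsv`, `weights.tsv`,
#' `estimates.tsv`, `summaries.json` and `manifest.json` (input MD5
#' checksums, seed, resample count, row counts, package version). Reruns
#' on identical inputs produce identical outputs. Any society in the
#' eligible sample that is missing from the tree is a hard error naming
#' it.
#'
#' @param quotes_path,societies_path,tree_path input files.
#' @param out_dir output directory (created if needed).
#' @param n_resamples resampling draws for corrected statistics
#'   (default 1e6).
#' @param seed integer run seed; per-statistic seeds are derived from it
#'   deterministically (default 20242553).
#' @param dependence_threshold,min_quotes eligibility gate parameters.
#' @param coast_threshold_km inland/coastal threshold.
#' @param biome_map_path optional alternative habitat-type map.
#' @return invisibly, a list with `codes`, `weights`, `summaries`,
#'   `eligible`, `excluded`, `diagnostics`, `manifest`.
#' @export
run_pipeline <- function(quotes_path, societies_path, tree_path, out_dir,
                         n_resamples = DEFAULT_RESAMPLES,
                         seed = DEFAULT_SEED,
                         dependence_threshold = 56, min_quotes = 2,
                         coast_threshold_km = 50,
                         biome_map_path = NULL) {
  biome_map <- if (is.null(biome_map_path)) NULL else
    read_biome_map(biome_map_path)
  quotes <- read_quotes(quotes_path)
  societies <- read_societies(societies_path, biome_map)
  gate <- eligible_societies(societies, quotes,
                             dependence_threshold, min_quotes)
  eligible <- gate$eligible
  if (!nrow(eligible)) {
    stop("no eligible societies after the dependence/quote gate",
         call. = FALSE)
  }
  codes <- aggregate_codes(quotes, eligible$society_id)
  diagnostics <- validate_codes(codes)
  tree <- read_timetree(tree_path, eligible$society_id)
  dist <- patristic_distances(tree, eligible$society_id)
  weights <- isolation_weights(dist)
  weights$subsample_id <- "full_sample"
  summaries <- summarize_dataset(codes, eligible, dist, n_resamples, seed,
                                 coast_threshold_km)
  estimates <- estimates_table(summaries, n_resamples, seed)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(codes, file.path(out_dir, "society_codes.tsv"))
  write_tsv(gate$excluded, file.path(out_dir, "exclusion_report.tsv"))
  write_tsv(diagnostics, file.path(out_dir, "code_diagnostics.tsv"))
  write_tsv(weights[c("society_id", "subsample_id", "raw_isolation",
                      "weight")],
            file.path(out_dir, "weights.tsv"))
  write_tsv(estimates, file.path(out_dir, "estimates.tsv"))
  jsonlite::write_json(summaries, file.path(out_dir, "summaries.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

  manifest <- list(
    inputs = list(
      quotes = unname(tools::md5sum(quotes_path)),
      societies = unname(tools::md5sum(societies_path)),
      tree = unname(tools::md5sum(tree_path))),
    seed = as.integer(seed),
    n_resamples = n_resamples,
    dependence_threshold = dependence_threshold,
    min_quotes = min_quotes,
    coast_threshold_km = coast_threshold_km,
    n_quotes = nrow(quotes),
    n_societies_input = nrow(societies),
    n_societies_eligible = nrow(eligible),
    package_version = as.character(utils::packageVersion("locomotr")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(codes = codes, weights = weights, summaries = summaries,
                 eligible = eligible, excluded = gate$excluded,
                 diagnostics = diagnostics, manifest = manifest))
}
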