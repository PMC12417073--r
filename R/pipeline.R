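#' Configuration for a full target-selection run
#'
#' @param model_path Path to an SBML-FBC or BiGG-style JSON model.
#' @param product_id,biomass_id,carbon_id Reaction ids of the product, the
#'   biomass objective, and the carbon-source exchange. All three must
#'   resolve in the loaded model before any optimization runs.
#' @param uptake_rate Carbon-source uptake bound, mmol/gDW/h.
#' @param filter A [filter_config()].
#' @param output_path Report path, or `NULL` to skip writing.
#' @param output_format `"tsv"` or `"csv"`.
#' @param log_level `"info"` (progress messages) or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(model_path, product_id, biomass_id, carbon_id,
                       uptake_rate = 10, filter = filter_config(),
                       output_path = NULL, output_format = c("tsv", "csv"),
                       log_level = c("info", "quiet")) {
  structure(
    list(model_path = model_path, product_id = product_id,
         biomass_id = biomass_id, carbon_id = carbon_id,
         uptake_rate = uptake_rate, filter = filter,
         output_path = output_path,
         output_format = match.arg(output_format),
         log_level = match.arg(log_level)),
    class = "run_config"
  )
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "info")) message(...)
}

#' Run the full target-selection pipeline
#'
#' Loads the model, fixes the carbon source, runs the enforced-production
#' scan, ranks and filters targets, maps them to genes, and (when
#' `output_path` is set) writes the report plus a JSON run manifest
#' recording every parameter, the maximum theoretical yield, the maximum
#' growth, the model id and the tool version — enough to reproduce the run.
#'
#' @param cfg A [run_config()].
#' @return List with `targets` (the ranked data frame), `scan` (the
#'   `scan_result`), and `files` (paths written).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  pipeline_log(cfg, "loading model from ", cfg$model_path)
  model <- load_model(cfg$model_path)
  for (id in c(cfg$product_id, cfg$biomass_id, cfg$carbon_id)) {
    resolve_reaction(model, id)
  }
  model <- set_carbon_source(model, cfg$carbon_id, cfg$uptake_rate)
  fractions <- seq_len(cfg$filter$n_fractions) / cfg$filter$n_fractions
  scan <- enforced_production_scan(
    model, cfg$product_id, cfg$biomass_id, cfg$carbon_id,
    fractions = fractions,
    biomass_min_fraction = cfg$filter$biomass_min_fraction)
  pipeline_log(cfg, sprintf("MTY %.6g, max growth %.6g over %d fractions",
                            scan$mty, scan$max_growth, length(fractions)))
  targets <- rank_targets(scan, cfg$filter)
  pipeline_log(cfg, nrow(targets), " target(s) survive filtering")
  if (nrow(targets) == 0L) {
    warning("no targets survive the configured filters; consider lowering ",
            "score_cutoff or flux_diff_cutoff")
  }
  targets <- map_genes(model, targets)
  files <- character()
  if (!is.null(cfg$output_path)) {
    write_target_table(targets, cfg$output_path, cfg$output_format)
    manifest_path <- paste0(cfg$output_path, ".manifest.json")
    write_run_manifest(cfg, scan, manifest_path)
    files <- c(report = cfg$output_path, manifest = manifest_path)
    pipeline_log(cfg, "report written to ", cfg$output_path)
  }
  list(targets = targets, scan = scan, files = files)
}

write_run_manifest <- function(cfg, scan, path) {
  manifest <- list(
    tool = "retap",
    version = as.character(utils::packageVersion("retap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    model_path = cfg$model_path,
    model_id = scan$config_echo$model_id,
    product_id = cfg$product_id,
    biomass_id = cfg$biomass_id,
    carbon_id = cfg$carbon_id,
    uptake_rate = cfg$uptake_rate,
    filter = unclass(cfg$filter),
    fractions = scan$fractions,
    mty = scan$mty,
    max_growth = scan$max_growth,
    output_format = cfg$output_format
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the ranked-target report
#'
#' Columns, in order: `rank`, `reaction_id`, `reaction_name`, `score`,
#' `overlap`, `intervention`, `mu_low`, `sigma_low`, `mu_high`,
#' `sigma_high`, `delta_mu`, `genes` (semicolon-joined), `gpr`. Floats are
#' printed with 6 significant digits; a capped score prints as the cap
#' value. An empty target list yields a header-only file.
#'
#' @param targets Target data frame from [rank_targets()] / [map_genes()].
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @return The path, invisibly.
#' @export
write_target_table <- function(targets, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  cols <- c("rank", "reaction_id", "reaction_name", "score", "overlap",
            "intervention", "mu_low", "sigma_low", "mu_high", "sigma_high",
            "delta_mu", "genes", "gpr")
  stopifnot(all(cols %in% names(targets)))
  out <- targets[, cols, drop = FALSE]
  for (col in c("score", "overlap", "mu_low", "sigma_low", "mu_high",
                "sigma_high", "delta_mu")) {
    out[[col]] <- formatC(out[[col]], digits = 6, format = "g")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write report, no such directory: ", dir)
  utils::write.table(out, path, sep = if (format == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
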