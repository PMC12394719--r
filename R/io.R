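#' Read a run-configuration YAML
#'
#' @param path YAML file.
#' @param required Character vector of required top-level keys; a missing key
#'   raises an error naming it.
#' @return Named list.
#' @export
read_config <- function(path, required = c("system", "conditions")) {
  cfg <- yaml::read_yaml(path)
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0)
    stop("config is missing required key(s): ", paste(missing, collapse = ", "))
  cfg
}

#' Write a screening report as JSON (with TSV box-plot data)
#'
#' The JSON carries provenance: a hash of the campaign configuration, the
#' replicate seed list and a run UUID. A side TSV
#' (`system`, `t_half`, `lag`, `censored`) is written next to it for box-plot
#' tooling.
#'
#' @param report A [run_ageing_campaign()] result.
#' @param config The [campaign_config()] used.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, config, path) {
  payload <- list(
    schema = "condage/screening-report/v1",
    run_uuid = sprintf("%08x-%04x-%04x", as.integer(Sys.time()) %% .Machine$integer.max,
                       sample.int(65535, 1), sample.int(65535, 1)),
    config_hash = rlang::hash(config[setdiff(names(config), "table")]),
    seeds = config$seeds,
    temperature = report$temperature,
    budget_time_ps = report$budget_time,
    systems = report$table)
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  tsv <- sub("\\.json$", "_boxplot.tsv", path)
  write.table(as.data.frame(report$replicates[, c("system", "t_half", "lag", "censored")]),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check a screening-report JSON for structural validity
#'
#' @param path Report JSON written by [write_report_json()].
#' @return `TRUE` (invisibly) or an error naming the missing field.
#' @export
validate_report <- function(path) {
  rep <- jsonlite::read_json(path)
  need <- c("schema", "run_uuid", "config_hash", "seeds", "systems")
  missing <- setdiff(need, names(rep))
  if (length(missing) > 0)
    stop("report missing field(s): ", paste(missing, collapse = ", "))
  if (!identical(rep$schema, "condage/screening-report/v1"))
    stop("unexpected report schema: ", rep$schema)
  invisible(TRUE)
}
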