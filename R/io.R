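# Output writers. Fixed schemas with a format version stamp; p-values printed
# with 6 significant digits; zero-exceedance p-values additionally carry the
# "< 1/n_perm" label in a separate column so the granularity of the
# permutation estimate stays visible in the flat files.

MESHPOOL_FORMAT <- "meshpool/1"

fmt_p <- function(p, n_perm) {
  ifelse(p == 0, paste0("<", format(signif(1 / n_perm, 6))),
         format(signif(p, 6)))
}

#' Write per-node enrichment results as TSV (and optionally JSON)
#'
#' Columns: `tree_number`, `term_id`, `name`, `k_direct`, `k_pooled`,
#' `p_direct`, `p_pooled`, `p_direct_label`, `p_pooled_label`, `n_perm`. The
#' label columns render zero-exceedance p-values as `"<1/n_perm"`.
#'
#' @param result An `enrich_result`.
#' @param path Output TSV path.
#' @param json_path Optional path for a JSON version (rows + run metadata).
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path, json_path = NULL) {
  stopifnot(inherits(result, "enrich_result"))
  n_perm <- attr(result, "n_perm")
  df <- tidy(result) |>
    mutate(p_direct_label = fmt_p(.data$p_direct, n_perm),
           p_pooled_label = fmt_p(.data$p_pooled, n_perm),
           p_direct = signif(.data$p_direct, 6),
           p_pooled = signif(.data$p_pooled, 6),
           n_perm = n_perm) |>
    select("tree_number", "term_id", "name", "k_direct", "k_pooled",
           "p_direct", "p_pooled", "p_direct_label", "p_pooled_label",
           "n_perm")
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(format = MESHPOOL_FORMAT,
           run = as.list(glance(result)),
           nodes = df),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
      na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Write a validation report: per-trial TSV plus JSON summary
#'
#' The TSV has one row per trial (`trial`, `n_SP`, `n_ST`, `P_P`, `P_T`,
#' `diff`); the JSON summary carries the trial averages and configuration.
#'
#' @param report A `validation_report`.
#' @param path Output TSV path.
#' @param json_path Optional JSON summary path.
#' @return `path`, invisibly.
#' @export
write_validation <- function(report, path, json_path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  df <- tidy(report) |>
    select("trial", "n_SP", "n_ST", "P_P", "P_T", "diff")
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(format = MESHPOOL_FORMAT,
           summary = as.list(glance(report)),
           diff = report$diff),
      json_path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Write density matrices as TSV (raw and z-scored)
#'
#' Rows are query sets; columns are top-level categories in sorted tree-number
#' order.
#'
#' @param dm A `density_matrix`.
#' @param raw_path Output path for the raw densities.
#' @param z_path Output path for the z-scored densities.
#' @return `raw_path`, invisibly.
#' @export
write_density <- function(dm, raw_path, z_path) {
  stopifnot(inherits(dm, "density_matrix"))
  readr::write_tsv(density_wide(dm, "density"), raw_path, progress = FALSE)
  readr::write_tsv(density_wide(dm, "z"), z_path, progress = FALSE)
  invisible(raw_path)
}

#' Write a run-configuration stamp
#'
#' Records the inputs, parameters and seed of a run as JSON so any output can
#' be regenerated from its stamp.
#'
#' @param config Named list of configuration values.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(c(list(format = MESHPOOL_FORMAT), config), path,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
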