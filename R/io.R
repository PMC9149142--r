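#' Write / read a self-describing results document
#'
#' JSON document carrying the tool version, the full configuration echo
#' (scoring structure, estimator, level, seeds), the pooled and per-site
#' numbers at full precision, and the QC flags — everything needed to
#' reproduce the run from its outputs alone. Numeric fields survive a
#' round-trip at full stored precision.
#'
#' @param run A `federated_run` from [run_single_shot()].
#' @param path Output path (.json).
#' @param model,cw The scoring configuration used.
#' @param seed Seed echoed for provenance.
#' @return `write_results()`: `path`, invisibly. `read_results()`: the
#'   parsed document (list) with `pooled` and `sites` as data.frames.
#' @export
write_results <- function(run, path, model = default_factor_model(),
                          cw = default_composite_weights(), seed = NULL) {
  stopifnot(inherits(run, "federated_run"))
  res <- run$result
  qc <- if (res$k >= 2L) flag_outlier_sites(res) else NULL
  doc <- list(
    tool = "fedmeta",
    version = as.character(utils::packageVersion("fedmeta")),
    config = c(list(estimator = res$estimator, level = res$level,
                    seed = seed,
                    parameters = run$log$parameters[
                      !vapply(run$log$parameters, is.null, logical(1))]),
               scoring_config_list(model, cw)),
    pooled = res$pooled,
    sites = res$sites,
    qc = qc,
    message_bytes = vapply(run$log$messages, `[[`, numeric(1), "bytes"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$pooled <- as.data.frame(doc$pooled, stringsAsFactors = FALSE)
  doc$sites <- as.data.frame(doc$sites, stringsAsFactors = FALSE)
  doc
}

#' Write the pooled summary as a delimited table
#'
#' One row per outcome with the conventional reporting columns
#' (d, SE, z, p, ci.lb, ci.ub) plus tau2, Q and I2, rounded under the
#' reporting rule ([round_report()]); the results document keeps full
#' precision.
#'
#' @param result A `meta_result`.
#' @param path Output path (.csv).
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(result, path) {
  stopifnot(inherits(result, "meta_result"))
  tab <- result$pooled
  out <- data.frame(outcome = tab$outcome,
                    d = round_report(tab$d), SE = round_report(tab$se),
                    z = round_report(tab$z), p = round_report(tab$p),
                    ci.lb = round_report(tab$ci_lb),
                    ci.ub = round_report(tab$ci_ub),
                    tau2 = round_report(tab$tau2), Q = round_report(tab$Q),
                    I2 = round_report(tab$I2),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
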