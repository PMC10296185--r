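#' Assemble a full analysis report
#'
#' Bundles the permutation test (null sample + observed statistic, the
#' histogram-vs-line summary), the per-frame closeness trace with its
#' top-quantile threshold, the selected frames with delay-corrected
#' timestamps, the channel relevance table, and provenance (package version,
#' configuration, input digests) into one serialisable object.
#'
#' @param test a [intersubject_similarity_test()] result.
#' @param frames a [top_frames()] result (defaults to the test's per-frame
#'   series at quantile 0.95).
#' @param relevance optional [channel_relevance()] result.
#' @param hrf_delay hemodynamic delay for timestamp correction (seconds).
#' @param flag_fraction fraction of channels flagged as the top set in the
#'   channel table (default 0.05).
#' @param config optional configuration list embedded verbatim.
#' @param input_files optional character vector; md5 digests are recorded.
#' @return object of class `analysis_report` (a nested list).
#' @export
analysis_report <- function(test, frames = NULL, relevance = NULL,
                            hrf_delay = 5.0, flag_fraction = 0.05,
                            config = NULL, input_files = NULL) {
  stopifnot(inherits(test, "similarity_test"))
  if (is.null(frames)) frames <- top_frames(test$per_frame)
  stamps <- frame_timestamps(frames, hrf_delay = hrf_delay)
  report <- list(
    schema_version = "1",
    test = list(observed = test$observed, B = test$B,
                p_value = test$p_value, seed = test$seed,
                min_attainable_p = 1 / (test$B + 1),
                null_sample = test$null_sample),
    closeness_trace = list(
      frame = test$per_frame$frame_indices,
      closeness = test$per_frame$values,
      fs = test$per_frame$fs,
      threshold_quantile = frames$threshold_quantile,
      closeness_at_threshold = frames$closeness_at_threshold),
    top_frames = list(frames = frames$frames,
                      hrf_delay_s = hrf_delay,
                      stimulus_seconds = stamps$seconds,
                      stimulus_mmss = stamps$mmss))
  if (!is.null(relevance)) {
    stopifnot(inherits(relevance, "channel_relevance"))
    n_flag <- max(1L, ceiling(flag_fraction *
                                length(relevance$channel_ids)))
    flagged <- rank(-relevance$relevance_frequency,
                    ties.method = "first") <= n_flag
    report$channel_table <- list(
      channel = relevance$channel_ids,
      relevance_frequency = as.numeric(relevance$relevance_frequency),
      top_fraction = relevance$top_fraction,
      flagged_top_set = as.logical(flagged))
  }
  prov <- list(package = "nirsgraph",
               version = as.character(utils::packageVersion("nirsgraph")))
  if (!is.null(config)) prov$config <- config
  if (!is.null(input_files))
    prov$input_md5 <- as.list(tools::md5sum(sort(input_files)))
  report$provenance <- prov
  structure(report, class = "analysis_report")
}

#' Serialise / restore an analysis report (lossless JSON)
#'
#' Numbers are written with 17 significant digits (full double precision),
#' so a report round-trips through disk without loss and identical analyses
#' produce byte-identical files.
#'
#' @param report an [analysis_report()].
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  structure(jsonlite::fromJSON(path, simplifyVector = TRUE),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> schema ", x$schema_version, "\n", sep = "")
  cat("  observed mean closeness ", format(x$test$observed, digits = 6),
      ", p = ", format(x$test$p_value, digits = 4), " (B = ", x$test$B,
      ")\n", sep = "")
  cat("  ", length(x$top_frames$frames), " top frames (quantile ",
      x$closeness_trace$threshold_quantile, ")\n", sep = "")
  if (!is.null(x$channel_table))
    cat("  channel table: ", length(x$channel_table$channel),
        " channels, flagged: ",
        paste(x$channel_table$channel[x$channel_table$flagged_top_set],
              collapse = ", "), "\n", sep = "")
  invisible(x)
}
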