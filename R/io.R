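# Plain-text interchange formats: TSV segment tables (onset_s, offset_s,
# label, bout_id; seconds, half-open intervals), TSV feature matrices with
# the 532-name header, JSON run configs. Decimal point, no locale handling.

#' Write a segment table as TSV
#'
#' Columns `onset_s`, `offset_s` (decimal seconds, 6 places), `label`
#' (empty when unlabeled), `bout_id` (empty when outside a bout), sorted by
#' onset.
#'
#' @param segs a `segment_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segs, path) {
  stopifnot(inherits(segs, "segment_table"))
  df <- data.frame(
    onset_s = sprintf("%.6f", segs$onset_s),
    offset_s = sprintf("%.6f", segs$offset_s),
    label = ifelse(is.na(segs$label), "", segs$label),
    bout_id = ifelse(is.na(segs$bout_id), "", as.character(segs$bout_id)))
  utils::write.table(df[order(segs$onset_s), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a segment-table TSV
#'
#' Permissive reader: requires `onset_s` and `offset_s` columns; `label`
#' and `bout_id` are optional, and extra columns are ignored.
#'
#' @param path path to the TSV file.
#' @return A `segment_table`.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = NA, na.strings = c("", "NA"))
  if (!all(c("onset_s", "offset_s") %in% names(df)))
    stop("segment table needs onset_s and offset_s columns: ", path)
  lab <- if ("label" %in% names(df)) as.character(df$label) else NA_character_
  bid <- if ("bout_id" %in% names(df)) as.integer(df$bout_id) else NA_integer_
  out <- .segment_table(df$onset_s, df$offset_s, label = lab, bout_id = bid)
  out[order(out$onset_s), ]
}

#' Write a feature matrix as TSV
#'
#' Header uses the block.bin feature names (e.g. `spec.001`); a `label`
#' column is appended when the matrix is labeled. Values are written with
#' 17 significant digits so the round trip is lossless well below 1e-9.
#'
#' @param m a `feature_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(m, path) {
  stopifnot(inherits(m, "feature_matrix"))
  x <- unclass(m)
  df <- as.data.frame(apply(x, 2, function(col) sprintf("%.17g", col),
                            simplify = FALSE))
  names(df) <- colnames(x)
  labels <- attr(m, "labels")
  if (!is.null(labels)) df$label <- labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-matrix TSV written by [write_features()]
#'
#' @param path path to the TSV file.
#' @return A `feature_matrix` (labeled when a `label` column is present).
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.character(df$label)
    df$label <- NULL
  }
  m <- as.matrix(df)
  blocks <- if (ncol(m) == 532) NULL else .blocks_from_names(colnames(m))
  feature_matrix(m, labels = labels, blocks = blocks)
}

.blocks_from_names <- function(nm) {
  prefix <- sub("\\..*$", "", nm)
  blocks <- list()
  for (p in unique(prefix)) blocks[[p]] <- which(prefix == p)
  blocks
}

#' Build a run configuration
#'
#' Bundles the tunable pipeline parameters so they can be serialized next
#' to every output for provenance.
#'
#' @param gap_threshold_ms gap elimination threshold, ms (default 5).
#' @param min_syllable_ms minimum syllable duration, ms (default 20).
#' @param sd_multiplier detection threshold in noise SDs (default 4).
#' @param feature_condition feature condition name (default `"ALL"`).
#' @param solver SVM solver name (default `"2R-2L"`).
#' @param cost_c soft-margin cost (default 1).
#' @param reject_threshold optional rejection threshold.
#' @param seed integer seed (default 1).
#' @return A `run_config` list.
#' @export
run_config <- function(gap_threshold_ms = 5, min_syllable_ms = 20,
                       sd_multiplier = 4, feature_condition = "ALL",
                       solver = "2R-2L", cost_c = 1,
                       reject_threshold = NULL, seed = 1) {
  structure(list(gap_threshold_ms = gap_threshold_ms,
                 min_syllable_ms = min_syllable_ms,
                 sd_multiplier = sd_multiplier,
                 feature_condition = feature_condition,
                 solver = solver, cost_c = cost_c,
                 reject_threshold = reject_threshold, seed = seed),
            class = "run_config")
}

#' Serialize a run configuration as JSON
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' Read a run configuration
#' @param path JSON path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, doc[!vapply(doc, is.null, logical(1))])
}
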