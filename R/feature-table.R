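# Feature tables: the tabular interchange format of the package. One row
# per analyzed image, keyed by (subject_id, group_label, timepoint_label),
# with the 20 canonical feature columns.

key_columns <- function() c("subject_id", "group_label", "timepoint_label")

#' Assemble a feature table from feature sets
#'
#' @param features A list of \code{vasc_features} objects.
#' @param subject_id,group_label,timepoint_label Key vectors, recycled to
#'   the number of rows.
#' @return A data frame with the key columns and the 20 canonical feature
#'   columns in canonical order.
#' @export
feature_table <- function(features, subject_id,
                          group_label = "group", timepoint_label = "t0") {
  if (inherits(features, "vasc_features")) features <- list(features)
  rows <- do.call(rbind, lapply(features, as.data.frame))
  cbind(data.frame(subject_id = rep_len(as.character(subject_id), nrow(rows)),
                   group_label = rep_len(as.character(group_label), nrow(rows)),
                   timepoint_label = rep_len(as.character(timepoint_label),
                                             nrow(rows))),
        rows)
}

#' Write a feature table to CSV
#'
#' UTF-8, header row, "." decimal separator; columns in canonical order.
#' Values round-trip through \code{\link{read_feature_table}} to at least
#' 12 significant digits.
#'
#' @param table Feature table (data frame).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  if (nrow(table) == 0L) stop("refusing to write an empty feature table",
                              call. = FALSE)
  out <- table[, c(key_columns(), feature_names())]
  for (f in feature_names()) {
    out[[f]] <- formatC(out[[f]], digits = 15, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' The file must contain exactly the key columns and the canonical feature
#' columns; an unknown column is an error (naming the offender), as is a
#' duplicated (subject, group, timepoint) key.
#'
#' @param path CSV path.
#' @return A feature table data frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tb <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  unknown <- setdiff(names(tb), c(key_columns(), feature_names()))
  if (length(unknown)) {
    stop("unknown feature column(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  validate_feature_table(tb)
  tb[, c(key_columns(), feature_names())]
}

#' @noRd
validate_feature_table <- function(tb) {
  missing_cols <- setdiff(c(key_columns(), feature_names()), names(tb))
  if (length(missing_cols)) {
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, c(tb[key_columns()], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, group_label, timepoint_label) keys",
         call. = FALSE)
  }
  invisible(tb)
}
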