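# Plain-text interchange formats: joint-distribution TSV, channel CSV with
# a JSON sidecar for the alphabets, and simplex-point JSON.

#' Read / write a joint distribution as TSV
#'
#' Format: a header line `t<TAB>y1<TAB>...<TAB>yn<TAB>p`, one outcome tuple
#' per line, probabilities as decimal literals, UTF-8.
#'
#' @param path File path.
#' @return A [joint_from_table()] object.
#' @export
read_joint_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) pid_error("BAD_INPUT", "joint TSV needs >= 2 columns")
  df[[ncol(df)]] <- suppressWarnings(as.numeric(df[[ncol(df)]]))
  names(df)[ncol(df)] <- "p"
  joint_from_table(df)
}

#' @rdname read_joint_tsv
#' @param joint A joint distribution.
#' @export
write_joint_tsv <- function(joint, path) {
  df <- as.data.frame(joint)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a channel as CSV plus JSON sidecar
#'
#' The CSV holds the plain matrix (no row names, header = output labels in
#' declared order); the sidecar holds
#' `{"input_labels": [...], "output_labels": [...]}`.
#'
#' @param path CSV path.
#' @param sidecar Sidecar path; defaults to `<path>.json`.
#' @return A [channel()].
#' @export
read_channel_csv <- function(path, sidecar = paste0(path, ".json")) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    channel(m, meta$input_labels, meta$output_labels)
  } else {
    channel(m, seq_len(nrow(m)) - 1L, colnames(m))
  }
}

#' @rdname read_channel_csv
#' @param K A channel.
#' @export
write_channel_csv <- function(K, path, sidecar = paste0(path, ".json")) {
  K <- if (is_channel(K)) K else channel(K)
  utils::write.csv(as.data.frame(unclass(K), row.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(input_labels = rownames(K),
                            output_labels = colnames(K)),
                       sidecar, auto_unbox = FALSE)
  invisible(path)
}

#' Read / write a probability vector as a JSON array
#'
#' @param path File path.
#' @return A simplex point (named numeric vector).
#' @export
read_simplex_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (is.list(x) && !is.null(x$weights)) {
    simplex_point(as.numeric(x$weights), x$labels)
  } else {
    simplex_point(as.numeric(x))
  }
}

#' @rdname read_simplex_json
#' @param p A probability vector.
#' @export
write_simplex_json <- function(p, path) {
  jsonlite::write_json(as.numeric(simplex_point(p)), path, digits = NA)
  invisible(path)
}
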