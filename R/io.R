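#' Write / read an expression matrix as TSV
#'
#' The canonical interchange format: tab-delimited UTF-8 text, a header row
#' of sample ids, first column `probe_id`, `.` decimal separator.
#'
#' @param m Numeric matrix (probes x samples) with dimnames.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed comment lines
#'   written before the table (e.g. a config hash and seed).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path, header = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @return For the reader: the numeric matrix with probe ids as rownames and
#'   sample ids as colnames. Duplicate probe ids, non-numeric cells and
#'   empty files are rejected with an informative message.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)
  if (ncol(df) < 2L) stop("no sample columns in ", path, call. = FALSE)
  probes <- as.character(df[[1]])
  dup <- unique(probes[duplicated(probes)])
  if (length(dup)) {
    stop("duplicated probe id(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  body <- df[, -1, drop = FALSE]
  non_num <- !vapply(body, is.numeric, logical(1))
  if (any(non_num)) {
    stop("non-numeric cells in column(s): ",
         paste(names(body)[non_num], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(body)
  rownames(m) <- probes
  m
}

#' Write / read a sample-metadata table as TSV
#'
#' @param meta Data.frame with at least `sample_id`, `patient_id`,
#'   `histology`, `site_class`, `group_role`.
#' @param path File path.
#' @param header Optional `#`-prefixed comment lines.
#' @return `path` (writer) or the data.frame (reader).
#' @export
write_sample_meta <- function(meta, path, header = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(meta, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, check.names = FALSE, quote = "",
                            comment.char = "#", stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) {
    stop("metadata needs a 'sample_id' column", call. = FALSE)
  }
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup)) {
    stop("duplicated sample id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  meta
}

#' Read a GEO series-matrix text file
#'
#' Convenience reader for the series-matrix format distributed by the Gene
#' Expression Omnibus: `!Sample_*` annotation lines followed by an
#' expression table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`. Only an optional real-data entry point — the
#' pipeline itself runs on plain TSV matrices.
#'
#' @param path Path to an (uncompressed) series-matrix file.
#' @return A list: `expr` (numeric matrix, probes x samples) and `meta` (a
#'   partial data.frame with `sample_id` plus whatever `!Sample_title` /
#'   `!Sample_characteristics_ch1` lines the file carries).
#' @export
read_geo_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop("missing or malformed series_matrix_table sentinels in ", path,
         call. = FALSE)
  }
  tab <- utils::read.delim(
    text = lines[(begin + 1L):(end - 1L)],
    check.names = FALSE, stringsAsFactors = FALSE
  )
  probes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression table in ", path,
                           call. = FALSE)
  rownames(m) <- probes
  gsm <- gsub('"', "", colnames(m))
  colnames(m) <- gsm
  meta <- data.frame(sample_id = gsm, stringsAsFactors = FALSE)
  for (field in c("!Sample_title", "!Sample_characteristics_ch1")) {
    hit <- grep(paste0("^", field, "\t"), lines, value = TRUE)
    if (length(hit)) {
      vals <- gsub('"', "", strsplit(hit[1], "\t")[[1]][-1])
      if (length(vals) == nrow(meta)) {
        meta[[sub("^!Sample_", "", field)]] <- vals
      }
    }
  }
  list(expr = m, meta = meta)
}

#' Write a classification report in the published table layout
#'
#' Columns `sample_id, grade, dist_to_NL, dist_to_L, classification`, with
#' distances formatted to 2 decimals.
#'
#' @param records Classification records.
#' @param path Output path.
#' @param header Optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(records, path, header = NULL) {
  out <- data.frame(
    sample_id = records$sample_id,
    grade = records$grade,
    dist_to_NL = sprintf("%.2f", records$dist_to_NL),
    dist_to_L = sprintf("%.2f", records$dist_to_L),
    classification = records$classification,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
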