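#' Read a raw assay table
#'
#' Reads a CSV or TSV assay table (delimiter sniffed from the header line)
#' with columns `sample_id`, `snp_id`, `a1`, `u1`, `a2`, `u2` and optional
#' `call`. `NA`, empty strings and `.` are accepted as missing calls. Rows
#' with non-numeric or negative areas/uncertainties are dropped with a
#' warning that reports their line numbers.
#'
#' @param path Path to the file.
#' @return Validated assay data frame; attribute `"rejected_lines"` lists
#'   the 1-based file line numbers of any dropped rows.
#' @export
read_assay_table <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", "", "."),
                          colClasses = "character")
  req <- c("sample_id", "snp_id", "a1", "u1", "a2", "u2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("assay table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  num <- lapply(df[c("a1", "u1", "a2", "u2")],
                function(x) suppressWarnings(as.numeric(x)))
  bad <- Reduce(`|`, lapply(num, function(x) !is.finite(x) | x < 0))
  if (any(bad)) {
    warning(sum(bad), " malformed assay row(s) dropped (file lines: ",
            paste(utils::head(which(bad) + 1L, 20), collapse = ", "), ")",
            call. = FALSE)
  }
  out <- data.frame(sample_id = df$sample_id, snp_id = df$snp_id,
                    a1 = num$a1, u1 = num$u1, a2 = num$a2, u2 = num$u2,
                    call = if ("call" %in% names(df)) df$call
                           else NA_character_,
                    stringsAsFactors = FALSE)[!bad, ]
  rownames(out) <- NULL
  attr(out, "rejected_lines") <- which(bad) + 1L
  out
}

#' Write a table deterministically
#'
#' Writes a data frame as CSV with numeric columns rounded to 6 significant
#' digits and rows sorted on the given key columns, so reruns on identical
#' inputs are byte-identical.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param sort_by Character vector of key columns (default: all
#'   non-numeric columns, left to right).
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, sort_by = NULL) {
  if (is.null(sort_by))
    sort_by <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(sort_by) && nrow(df))
    df <- df[do.call(order, df[sort_by]), , drop = FALSE]
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a run report as JSON
#'
#' @param report Named list of scalar counts and settings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
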