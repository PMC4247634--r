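# Cohort file I/O.  Dialect: RFC-4180 delimited text (comma default, tab
# accepted), UTF-8, '.' decimal, header row with the documented column
# schema.  Unknown columns are preserved but ignored by the toolkit.

#' Read a patient-episode cohort from delimited text
#'
#' Expects a header with columns `ps`, `os`, `urgency`
#' (`elective`/`emergency`/`non_elective`...), `specialty`, `died_30d`,
#' `directly_admitted`, `data_complete` (each 0/1 or TRUE/FALSE). A missing
#' required column is a schema error listing the missing names; invalid
#' values are reported with their row numbers.
#'
#' @param path File path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @param provenance Label for the cohort; defaults to the file name.
#' @param strict Error (default) or warn on out-of-bounds scores.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, sep = ",", provenance = basename(path),
                        strict = TRUE) {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols))
    stop_schema("missing required column(s): ",
                paste(missing_cols, collapse = ", "))
  tryCatch(cohort(df, provenance = provenance, strict = strict),
           error = function(e) {
             stop(sprintf("%s [while reading %s]", conditionMessage(e), path),
                  call. = FALSE)
           })
}

#' Write a cohort as delimited text
#'
#' @param chrt A [cohort()].
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly; `read_cohort(write_cohort(x))` round-trips all
#'   schema fields.
#' @export
write_cohort <- function(chrt, path, sep = ",") {
  stopifnot(inherits(chrt, "cohort"))
  df <- as.data.frame(chrt)
  df$directly_admitted <- as.integer(df$directly_admitted)
  df$data_complete <- as.integer(df$data_complete)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
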