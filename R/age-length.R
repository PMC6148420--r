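# The canonical data container: a data.frame of individual fish records with
# columns age (whole years), length_mm (total length), source (per-record
# provenance: "observed", "simulated", ...), plus a table-level provenance
# attribute ("raw", "bolstered", "synthetic").

#' Construct an age-length table
#'
#' @param age Integer-valued ages in whole years (>= 1).
#' @param length_mm Positive finite total lengths in mm.
#' @param provenance Table-level tag, e.g. `"raw"`, `"bolstered"`,
#'   `"synthetic"`.
#' @param source Optional per-record character vector; defaults to
#'   `"observed"` for every record.
#' @return A `data.frame` of class `age_length` with columns `age`,
#'   `length_mm`, `source`.
#' @export
#' @examples
#' age_length_table(c(1, 1, 2), c(150, 160, 300))
age_length_table <- function(age, length_mm, provenance = "raw", source = NULL) {
  if (length(age) == 0L) stop("age-length table must be non-empty", call. = FALSE)
  if (length(age) != length(length_mm)) {
    stop("age and length_mm must have equal length", call. = FALSE)
  }
  age <- as.numeric(age)
  length_mm <- as.numeric(length_mm)
  if (anyNA(age) || anyNA(length_mm) || any(!is.finite(length_mm))) {
    stop("ages and lengths must be finite and non-missing", call. = FALSE)
  }
  if (any(length_mm <= 0)) stop("all lengths must be positive", call. = FALSE)
  if (any(age < 1)) stop("ages must be >= 1 (whole-year annulus counts)", call. = FALSE)
  if (is.null(source)) source <- rep("observed", length(age))
  out <- data.frame(age = age, length_mm = length_mm, source = source,
                    stringsAsFactors = FALSE)
  class(out) <- c("age_length", "data.frame")
  attr(out, "provenance") <- provenance
  out
}

#' Read an age-length table from delimited text
#'
#' The separator (comma or tab) is sniffed from the header line. A header is
#' required; by default the columns are expected to be named `age` and
#' `length_mm`, but other names can be mapped.
#'
#' @param path Path to a delimited text file.
#' @param col_age,col_length Column names holding age (years) and total
#'   length (mm).
#' @param provenance Table-level provenance tag for the result.
#' @return An [age_length_table()].
#' @export
read_age_length <- function(path, col_age = "age", col_length = "length_mm",
                            provenance = "raw") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty input file: ", path, call. = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("no records in input file: ", path, call. = FALSE)
  for (col in c(col_age, col_length)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path,
           " (columns: ", paste(names(df), collapse = ", "), ")", call. = FALSE)
    }
  }
  src <- if ("source" %in% names(df)) df$source else NULL
  age_length_table(df[[col_age]], df[[col_length]],
                   provenance = provenance, source = src)
}

#' Write an age-length table as delimited text
#'
#' @param data An [age_length_table()].
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_age_length <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "age_length"))
  utils::write.table(as.data.frame(data), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.age_length <- function(x, n = 6L, ...) {
  cat(sprintf("Age-length table: %d records, ages %g-%g, lengths %g-%g mm (%s)\n",
              nrow(x), min(x$age), max(x$age), min(x$length_mm), max(x$length_mm),
              attr(x, "provenance") %||% "unknown"))
  print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more records\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
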