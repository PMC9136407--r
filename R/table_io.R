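## Reading and validating the merged metadata + abundance table.
##
## Input layout: one header row; column 1 = unique sample ID; then n metadata
## columns (each all-string or all-numeric); then m feature-abundance columns.

MISSING_TOKENS <- c("", "NA", "na", "NaN")

#' Read a merged metadata/abundance table
#'
#' Reads a delimiter-separated table whose first column is a unique sample
#' identifier, followed by metadata columns and feature-abundance columns.
#' Every column is typed as either numeric (all non-missing entries parse as
#' decimal numbers) or string; a column mixing the two is an error, naming the
#' column and the first offending row. The tokens \code{""}, \code{"NA"},
#' \code{"na"} and \code{"NaN"} are read as missing.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param delimiter field separator; if \code{NULL} it is inferred from the
#'   file extension (\code{.csv} vs \code{.tsv}/\code{.tab}/\code{.txt}) and,
#'   failing that, by sniffing the header line.
#' @param sample_id_col index (or name) of the sample-ID column; defaults to
#'   the first column.
#' @return an object of class \code{mb_raw_table}: a list with
#'   \code{sample_ids} (character) and \code{columns} (a data.frame of the
#'   remaining, typed columns), ready for \code{\link{partition_columns}}.
#' @seealso \code{\link{partition_columns}}
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sid\tgroup\tfA", "s1\tcase\t0.4", "s2\tctrl\t0.6"), tf)
#' raw <- read_merged_table(tf)
#' raw$sample_ids
#' @export
read_merged_table <- function(path, delimiter = NULL, sample_id_col = 1L) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read input file: ", path)
  if (is.null(delimiter)) delimiter <- infer_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", strip.white = TRUE,
                          stringsAsFactors = FALSE)
  if (nrow(df) < 2L)
    stop("input table must have at least 2 data rows, found ", nrow(df))
  if (ncol(df) < 3L)
    stop("input table must have at least 3 columns (sample ID, >=1 metadata, ",
         ">=1 feature), found ", ncol(df))
  if (is.character(sample_id_col)) {
    idx <- match(sample_id_col, names(df))
    if (is.na(idx)) stop("sample-ID column not found: ", sample_id_col)
    sample_id_col <- idx
  }
  ids <- df[[sample_id_col]]
  ids[ids %in% MISSING_TOKENS] <- NA_character_
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("sample IDs must be non-empty (column '", names(df)[sample_id_col], "')")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sample IDs: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  cols <- df[-sample_id_col]
  typed <- lapply(names(cols), function(nm) type_column(cols[[nm]], nm))
  names(typed) <- names(cols)
  structure(list(sample_ids = ids,
                 columns = as.data.frame(typed, check.names = FALSE,
                                         stringsAsFactors = FALSE),
                 source = path),
            class = "mb_raw_table")
}

#' @export
print.mb_raw_table <- function(x, ...) {
  num <- vapply(x$columns, is.numeric, logical(1))
  cat("Merged sample table (untyped roles)\n")
  cat("  samples: ", length(x$sample_ids), "\n", sep = "")
  cat("  columns: ", ncol(x$columns), " (", sum(num), " numeric, ",
      sum(!num), " string)\n", sep = "")
  invisible(x)
}

# extension first, then sniff the header line; ambiguous counts are an error
infer_delimiter <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(",")
  if (ext %in% c("tsv", "tab")) return("\t")
  header <- readLines(path, n = 1L, warn = FALSE)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_com <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (n_tab > 0L && n_com == 0L) return("\t")
  if (n_com > 0L && n_tab == 0L) return(",")
  if (n_tab > n_com) return("\t")
  if (n_com > n_tab) return(",")
  stop("cannot infer delimiter for '", path,
       "': header contains ", n_tab, " tabs and ", n_com,
       " commas; pass `delimiter` explicitly")
}

# a column is numeric iff every non-missing entry parses as a decimal number;
# a mixture of parsing and non-parsing entries is a typing error
type_column <- function(x, name) {
  x <- trimws(x)
  miss <- x %in% MISSING_TOKENS
  parsed <- suppressWarnings(as.numeric(x))
  ok <- !is.na(parsed)
  if (all(miss)) return(rep(NA_character_, length(x)))
  if (all(ok[!miss])) {
    parsed[miss] <- NA_real_
    return(parsed)
  }
  if (any(ok[!miss])) {
    bad <- which(!ok & !miss)[1L]
    stop("column '", name, "' mixes numeric and string values ",
         "(each column can be either all strings or all numeric, not a ",
         "mixture); first non-numeric entry '", x[bad], "' at data row ", bad)
  }
  x[miss] <- NA_character_
  x
}

#' Partition table columns into metadata and features
#'
#' Columns named in the schema (random or fixed variables) become metadata;
#' every remaining column becomes a microbial feature. Feature columns must be
#' numeric, finite and non-negative.
#'
#' @param raw an \code{mb_raw_table} from \code{\link{read_merged_table}}.
#' @param schema a \code{\link{variable_schema}}; its level orders and
#'   reference levels are resolved against the data.
#' @return an object of class \code{sample_table}: list with
#'   \code{sample_ids}, \code{metadata} (data.frame), \code{features}
#'   (numeric matrix, samples x features), \code{n_samples}, and the resolved
#'   \code{schema}.
#' @export
partition_columns <- function(raw, schema) {
  stopifnot(inherits(raw, "mb_raw_table"), inherits(schema, "variable_schema"))
  meta_vars <- c(schema$random_vars, names(schema$fixed_vars))
  missing_cols <- setdiff(meta_vars, names(raw$columns))
  if (length(missing_cols))
    stop("schema references columns absent from the table: ",
         paste(missing_cols, collapse = ", "))
  feature_cols <- setdiff(names(raw$columns), meta_vars)
  if (!length(feature_cols))
    stop("no feature columns: every non-ID column is declared as metadata")
  bad <- feature_cols[!vapply(raw$columns[feature_cols], is.numeric, logical(1))]
  if (length(bad))
    stop("feature column(s) are string-typed (features must be numeric ",
         "abundances): ", paste(bad, collapse = ", "))
  features <- as.matrix(raw$columns[feature_cols])
  rownames(features) <- raw$sample_ids
  if (any(!is.finite(features[!is.na(features)])) || anyNA(features))
    stop("feature values must be finite (no missing abundances)")
  if (any(features < 0))
    stop("feature values must be >= 0")
  metadata <- raw$columns[meta_vars]
  rownames(metadata) <- raw$sample_ids
  schema <- resolve_schema(schema, metadata)
  structure(list(sample_ids = raw$sample_ids,
                 metadata = metadata,
                 features = features,
                 n_samples = length(raw$sample_ids),
                 schema = schema),
            class = "sample_table")
}

#' Construct a sample table from in-memory pieces
#'
#' Convenience constructor used by the synthetic-cohort generator and in
#' examples; applies the same validation as \code{\link{partition_columns}}.
#'
#' @param sample_ids unique character vector of sample identifiers.
#' @param metadata data.frame of metadata columns (one row per sample).
#' @param features numeric matrix of abundances, one row per sample.
#' @param schema a \code{\link{variable_schema}} covering the metadata columns.
#' @return a \code{sample_table}.
#' @export
sample_table <- function(sample_ids, metadata, features, schema) {
  sample_ids <- as.character(sample_ids)
  stopifnot(!anyDuplicated(sample_ids), all(nzchar(sample_ids)),
            nrow(metadata) == length(sample_ids),
            nrow(features) == length(sample_ids))
  raw <- structure(list(sample_ids = sample_ids,
                        columns = cbind(metadata,
                                        as.data.frame(features,
                                                      check.names = FALSE),
                                        stringsAsFactors = FALSE),
                        source = "<memory>"),
                   class = "mb_raw_table")
  rownames(raw$columns) <- NULL
  partition_columns(raw, schema)
}

#' @export
print.sample_table <- function(x, ...) {
  cat("sample_table: ", x$n_samples, " samples, ",
      ncol(x$metadata), " metadata variables, ",
      ncol(x$features), " features\n", sep = "")
  cat("  metadata: ", paste(names(x$metadata), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a sample table to TSV
#'
#' Writes the merged layout back out (sample ID first, then metadata, then
#' features) so that re-reading with \code{\link{read_merged_table}} and
#' \code{\link{partition_columns}} round-trips the values.
#'
#' @param table a \code{sample_table}.
#' @param path output file path.
#' @param id_name header name for the sample-ID column.
#' @return \code{path}, invisibly.
#' @export
write_sample_table <- function(table, path, id_name = NULL) {
  stopifnot(inherits(table, "sample_table"))
  if (is.null(id_name)) id_name <- table$schema$sample_id_col
  out <- cbind(stats::setNames(data.frame(table$sample_ids,
                                          stringsAsFactors = FALSE), id_name),
               table$metadata,
               as.data.frame(table$features, check.names = FALSE))
  write_tsv(out, path)
}

# canonical TSV writer for all tabular outputs: fixed significant-digit
# rendering so identical runs are byte-identical
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE,
                                              trim = TRUE)
    }, character(1))
    out
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
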