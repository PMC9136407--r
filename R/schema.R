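## Variable roles and typing: which metadata columns are random-effect
## grouping factors, which are fixed effects, categorical vs continuous,
## level ordering and reference levels.

#' Declare the roles of metadata variables
#'
#' A schema names the sample-ID column, the random-effect grouping variables
#' (accounted for, never tested), and the fixed-effect variables with their
#' kind. Kinds left as \code{NA} are inferred from the data when the schema is
#' resolved against a table: string columns are categorical, and numeric
#' columns with four or fewer distinct non-missing values are treated as
#' categorical, five or more as continuous.
#'
#' @param sample_id name of the sample-ID column (informational; the first
#'   table column is the ID by default).
#' @param random character vector of random-effect variable names. These are
#'   always treated as grouping factors for random intercepts, whatever their
#'   storage type.
#' @param fixed named character vector mapping each fixed-effect variable to
#'   \code{"categorical"}, \code{"continuous"}, or \code{NA} (infer). An
#'   unnamed character vector declares all-inferred variables.
#' @param reference named list/character: per categorical variable, the
#'   reference level. Defaults to the alphabetically first level.
#' @param level_order named list: per categorical variable, an explicit level
#'   order. Defaults to lexicographic order.
#' @return an object of class \code{variable_schema}.
#' @examples
#' variable_schema("sample", random = "subject",
#'                 fixed = c(disease = "categorical", age = "continuous"),
#'                 reference = c(disease = "control"))
#' @export
variable_schema <- function(sample_id = "sample_id", random = character(),
                            fixed = character(), reference = list(),
                            level_order = list()) {
  random <- as.character(random)
  if (is.null(names(fixed)) && length(fixed)) {
    fixed <- stats::setNames(rep(NA_character_, length(fixed)), as.character(fixed))
  }
  fixed <- vapply(fixed, as.character, character(1))
  bad_kind <- !(is.na(fixed) | fixed %in% c("categorical", "continuous"))
  if (any(bad_kind))
    stop("fixed-variable kind must be 'categorical' or 'continuous': ",
         paste(names(fixed)[bad_kind], collapse = ", "))
  overlap <- intersect(random, names(fixed))
  if (length(overlap))
    stop("variables declared both random and fixed: ",
         paste(overlap, collapse = ", "))
  if (sample_id %in% c(random, names(fixed)))
    stop("the sample-ID column cannot be a model variable: ", sample_id)
  structure(list(sample_id_col = sample_id,
                 random_vars = random,
                 fixed_vars = fixed,
                 level_order = as.list(level_order),
                 reference = as.list(reference)),
            class = "variable_schema")
}

#' @export
print.variable_schema <- function(x, ...) {
  cat("variable_schema\n")
  cat("  sample ID : ", x$sample_id_col, "\n", sep = "")
  cat("  random    : ", if (length(x$random_vars))
    paste(x$random_vars, collapse = ", ") else "(none)", "\n", sep = "")
  for (v in names(x$fixed_vars)) {
    kind <- x$fixed_vars[[v]]
    extra <- ""
    if (identical(kind, "categorical") && !is.null(x$level_order[[v]])) {
      lv <- x$level_order[[v]]
      ref <- x$reference[[v]]
      extra <- paste0(" [", paste(lv, collapse = ", "), "; ref=", ref, "]")
    }
    cat("  fixed     : ", v, " (", if (is.na(kind)) "infer" else kind, ")",
        extra, "\n", sep = "")
  }
  invisible(x)
}

#' Infer whether a metadata column is categorical or continuous
#'
#' String columns are always categorical. Numeric columns with at most four
#' distinct non-missing values are categorical; five or more, continuous.
#' Missing values never count as a distinct level.
#'
#' @param values one metadata column (character or numeric).
#' @return \code{"categorical"} or \code{"continuous"}.
#' @export
infer_variable_kind <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("cannot infer kind of an all-missing column")
  if (!is.numeric(values)) return("categorical")
  if (length(unique(v)) <= 4L) "categorical" else "continuous"
}

#' Order the levels of a categorical variable
#'
#' Distinct non-missing levels sorted lexicographically (by their string
#' rendering for numeric-coded categoricals), the convention the reference
#' level defaults to. Locale-independent (C collation).
#'
#' @param values a categorical metadata column.
#' @return character vector of ordered levels.
#' @export
order_levels <- function(values) {
  lev <- unique(as.character(values[!is.na(values)]))
  if (length(lev) < 2L)
    stop("constant variable: a single-level categorical variable cannot be tested")
  sort_c(lev)
}

# locale-independent lexicographic sort
sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x)
}

#' Default reference level
#'
#' The first element of the ordered level list (alphabetically first unless a
#' custom order was supplied); a per-model user override takes precedence.
#'
#' @param levels ordered character vector of levels.
#' @return the reference level.
#' @export
default_reference <- function(levels) {
  if (!length(levels)) stop("empty level list")
  levels[[1L]]
}

# Fill in inferred kinds, level orders and reference levels from the data;
# validates user-supplied orders/references against observed levels.
resolve_schema <- function(schema, metadata) {
  stopifnot(inherits(schema, "variable_schema"))
  for (v in names(schema$fixed_vars)) {
    if (is.na(schema$fixed_vars[[v]]))
      schema$fixed_vars[[v]] <- infer_variable_kind(metadata[[v]])
  }
  for (v in names(schema$fixed_vars)) {
    if (schema$fixed_vars[[v]] != "categorical") {
      if (!is.null(schema$level_order[[v]]))
        stop("continuous variable '", v, "' cannot have a level order")
      next
    }
    observed <- order_levels(metadata[[v]])
    lv <- schema$level_order[[v]]
    if (is.null(lv)) {
      schema$level_order[[v]] <- observed
    } else {
      if (!setequal(lv, observed))
        stop("level_order for '", v, "' does not match observed levels (",
             paste(observed, collapse = ", "), ")")
      schema$level_order[[v]] <- as.character(lv)
    }
    ref <- schema$reference[[v]]
    if (is.null(ref)) {
      schema$reference[[v]] <- default_reference(schema$level_order[[v]])
    } else if (!as.character(ref) %in% schema$level_order[[v]]) {
      stop("reference level '", ref, "' is not a level of '", v, "'")
    }
  }
  schema
}

#' Read a variable schema from a YAML or JSON file
#'
#' The file declares \code{sample_id}, \code{random} (list), \code{fixed}
#' (map of name to \code{categorical}/\code{continuous}/\code{infer}), and
#' optionally \code{reference} (map of name to level) and \code{level_order}.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a \code{\link{variable_schema}}.
#' @export
read_variable_schema <- function(path) {
  ext <- tolower(tools::file_ext(path))
  spec <- switch(ext,
                 yaml = , yml = yaml::read_yaml(path),
                 json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                 stop("schema file must be .yaml/.yml or .json: ", path))
  fixed <- unlist(spec$fixed %||% character())
  fixed[fixed == "infer"] <- NA_character_
  variable_schema(sample_id = spec$sample_id %||% "sample_id",
                  random = unlist(spec$random %||% character()),
                  fixed = fixed,
                  reference = as.list(spec$reference %||% list()),
                  level_order = as.list(spec$level_order %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
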