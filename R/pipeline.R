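## End-to-end pipeline driver and report export: read -> type -> preprocess ->
## fit per model -> compare, with TSV/figure outputs and a run log.

#' Read a run configuration file
#'
#' YAML or JSON with fields: \code{input} (table path), \code{schema} (schema
#' file path or inline schema map), \code{models} (list of model definitions:
#' \code{name}, \code{fixed}, \code{random}, \code{reference}, \code{add});
#' optional \code{q_threshold} (default 0.2), \code{ast} (default true),
#' \code{filter_threshold}, \code{delimiter}, \code{out}. A model definition
#' without \code{fixed} inherits the previous model's variables; \code{add}
#' appends fixed variables to the inherited set. Unnamed models are called
#' \code{model_1..k}.
#'
#' @param path configuration file path.
#' @return a named list ready for \code{\link{run_pipeline}}.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = FALSE),
                stop("run config must be .yaml/.yml or .json: ", path))
  base <- dirname(normalizePath(path))
  for (f in c("input", "schema")) {
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]]) &&
        file.exists(file.path(base, cfg[[f]])))
      cfg[[f]] <- file.path(base, cfg[[f]])
  }
  cfg
}

# turn config model definitions into model_spec objects, honouring
# most-recently-defined-model inheritance
build_model_specs <- function(defs, ast = TRUE, q_threshold = 0.2) {
  if (!length(defs)) stop("run config defines 0 models; at least 1 required")
  if (length(defs) > 10L)
    stop("run config defines ", length(defs),
         " models; at most 10 supported (3-5 is the practical range)")
  specs <- vector("list", length(defs))
  prev_fixed <- NULL; prev_random <- character(); prev_ref <- list()
  for (i in seq_along(defs)) {
    d <- defs[[i]]
    if (inherits(d, "model_spec")) {
      specs[[i]] <- d
      prev_fixed <- d$fixed; prev_random <- d$random; prev_ref <- d$reference
      next
    }
    fixed <- unlist(d$fixed %||% prev_fixed)
    if (is.null(fixed))
      stop("model ", i, " defines no fixed variables and has no predecessor ",
           "to inherit from")
    if (!is.null(d$add)) fixed <- unique(c(fixed, unlist(d$add)))
    random <- unlist(d$random %||% prev_random)
    reference <- as.list(d$reference %||% prev_ref)
    name <- d$name %||% paste0("model_", i)
    specs[[i]] <- model_spec(name, fixed = fixed,
                             random = random %||% character(),
                             reference = reference,
                             ast = d$ast %||% ast,
                             q_threshold = d$q_threshold %||% q_threshold)
    prev_fixed <- fixed; prev_random <- random %||% character()
    prev_ref <- reference
  }
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  specs
}

#' Run the full association pipeline
#'
#' Reads the merged table, partitions columns by the schema, fits every model
#' over the preprocessed features, and compares the models. Writes per-model
#' results TSVs (\code{results_<name>.tsv}), the long comparison TSV
#' (\code{comparison.tsv}), the comparison heatmap
#' (\code{heatmap.pdf}/\code{.png}) and a run log (\code{run_log.txt}).
#' Re-running an identical configuration on identical inputs reproduces the
#' TSV outputs byte for byte. On failure, partial outputs are removed.
#'
#' @param config path to a config file (see \code{\link{read_run_config}}) or
#'   an equivalent named list; list elements \code{input}/\code{schema} may
#'   also be in-memory objects (\code{sample_table} or raw table + schema).
#' @param out output directory; overrides \code{config$out}.
#' @return invisibly, list(fits, comparison, paths).
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- out %||% config$out
  if (is.null(out_dir)) stop("no output directory: set `out`")
  q_threshold <- config$q_threshold %||% 0.2
  ast <- config$ast %||% TRUE
  filter_threshold <- config$filter_threshold %||% 1e-4
  specs <- build_model_specs(config$models, ast = ast,
                             q_threshold = q_threshold)
  if (inherits(config$input, "sample_table")) {
    table <- config$input
  } else {
    schema <- if (inherits(config$schema, "variable_schema")) config$schema
              else read_variable_schema(config$schema)
    raw <- read_merged_table(config$input, delimiter = config$delimiter)
    table <- partition_columns(raw, schema)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  log_lines <- c(paste0("mbassoc ", as.character(utils::packageVersion("mbassoc"))),
                 paste0("samples: ", table$n_samples,
                        "; metadata: ", ncol(table$metadata),
                        "; features: ", ncol(table$features)),
                 paste0("q_threshold: ", q_threshold, "; AST: ", ast,
                        "; abundance filter: ", filter_threshold))
  fits <- vector("list", length(specs))
  names(fits) <- names(specs)
  for (nm in names(specs)) {
    fit <- withCallingHandlers(
      run_model(table, specs[[nm]], filter_threshold = filter_threshold),
      warning = function(w) {
        log_lines <<- c(log_lines, paste0("[", nm, "] warning: ",
                                          conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    fits[[nm]] <- fit
    path <- file.path(out_dir, paste0("results_", nm, ".tsv"))
    write_results(fit, path)
    written <- c(written, path)
    log_lines <- c(log_lines, sprintf(
      "[%s] dropped samples: %d; removed features: %d; failed fits: %d; constant features skipped: %d; significant (q < %s): %d",
      nm, length(fit$dropped_samples), length(fit$removed_features),
      sum(fit$results$status == "fit_failed"),
      sum(fit$results$status == "skipped_constant"), q_threshold,
      sum(fit$results$q < q_threshold, na.rm = TRUE)))
  }
  cmp <- compare_models(fits, q_threshold = q_threshold)
  cmp_path <- file.path(out_dir, "comparison.tsv")
  write_comparison(cmp, cmp_path)
  written <- c(written, cmp_path)
  heat_fmt <- config$heatmap_format %||% "pdf"
  heat_path <- file.path(out_dir, paste0("heatmap.", heat_fmt))
  switch(heat_fmt,
         pdf = grDevices::pdf(heat_path, width = 8, height = 6),
         png = grDevices::png(heat_path, width = 8, height = 6,
                              units = "in", res = 150),
         stop("unsupported heatmap format: ", heat_fmt))
  plot(cmp)
  grDevices::dev.off()
  written <- c(written, heat_path)
  log_lines <- c(log_lines, paste0("comparison rows (significant in >= 1 ",
                                   "model): ", length(cmp$features)))
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  written <- c(written, log_path)
  ok <- TRUE
  invisible(list(fits = fits, comparison = cmp,
                 paths = stats::setNames(written, basename(written))))
}

#' Export a combined report
#'
#' One PDF containing the comparison heatmap followed by any requested detail
#' plots, in order.
#'
#' @param comparison an \code{assoc_comparison}.
#' @param details list of detail requests: each either an
#'   \code{\link{association_detail}} record set or a list with elements
#'   \code{records} and optional \code{facet}/\code{color}/\code{label}.
#' @param file output PDF path.
#' @return \code{file}, invisibly.
#' @export
export_report <- function(comparison, details = list(), file) {
  if (is.null(comparison) || !inherits(comparison, "assoc_comparison") ||
      !length(comparison$features))
    stop("nothing significant to report")
  grDevices::pdf(file, width = 8, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(comparison)
  for (d in details) {
    if (inherits(d, "assoc_detail")) {
      plot(d)
    } else {
      plot(d$records, facet = d$facet %||% NULL, color = d$color %||% NULL,
           label = d$label %||% NULL)
    }
  }
  invisible(file)
}
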