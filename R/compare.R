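## Cross-model comparison: align several fitted models over the same data
## into the significance matrix behind the birds-eye heatmap.

#' Compare association results across candidate models
#'
#' Builds the comparison matrix: rows are the features significant (q strictly
#' below the threshold) in at least one model; columns are (model, variable,
#' level) triples in model-definition order. Entries carry the q-value for
#' every tested term of every retained feature, including non-significant
#' ones; rendering decides colouring. A feature absent from one model's
#' feature universe (e.g. filtered out under different preprocessing flags)
#' has missing entries there, rendered "not tested".
#'
#' @param fits list of \code{\link{run_model}} fits over the same sample
#'   table and schema.
#' @param q_threshold FDR significance cutoff used to select rows (strict
#'   \code{<}); default 0.2.
#' @return an object of class \code{assoc_comparison}.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 20, n_features = 8, seed = 1))
#' f1 <- run_model(coh$table, model_spec("m1", fixed = "disease", random = "subject"))
#' f2 <- run_model(coh$table, model_spec("m2", fixed = c("disease", "age"),
#'                                       random = "subject"))
#' cmp <- compare_models(list(f1, f2))
#' @export
compare_models <- function(fits, q_threshold = 0.2) {
  if (!length(fits)) stop("empty model list")
  stopifnot(all(vapply(fits, inherits, logical(1), "mbassoc_fit")))
  ids <- lapply(fits, function(f) sort(f$sample_ids))
  if (!all(vapply(ids, identical, logical(1), ids[[1L]])))
    stop("models were fitted on different sample sets; compare_models ",
         "requires fits over the same table")
  model_names <- vapply(fits, function(f) f$spec$name, character(1))
  if (anyDuplicated(model_names)) stop("duplicate model names")
  long <- do.call(rbind, c(lapply(fits, function(f) {
    r <- f$results
    data.frame(model = f$spec$name, feature = r$feature,
               variable = r$variable, level = r$level, q = r$q,
               stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  columns <- do.call(rbind, c(lapply(fits, function(f) {
    data.frame(model = f$spec$name, variable = f$terms$variable,
               level = f$terms$level, stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  build_comparison(long, columns, model_names, q_threshold)
}

# shared constructor: applies the row rule (significant anywhere, strict <)
build_comparison <- function(long, columns, model_names, q_threshold) {
  sig <- long$q < q_threshold & !is.na(long$q)
  features <- unique(long$feature[sig])
  if (!length(features))
    stop("nothing significant: no feature has q < ", q_threshold,
         " in any model")
  features <- sort_c(features)
  structure(list(long = long[long$feature %in% features, , drop = FALSE],
                 all = long,
                 columns = columns,
                 features = features,
                 models = model_names,
                 q_threshold = q_threshold),
            class = "assoc_comparison")
}

#' @export
print.assoc_comparison <- function(x, ...) {
  cat("assoc_comparison: ", length(x$features), " features significant in >= 1 of ",
      length(x$models), " models (q < ", x$q_threshold, ")\n", sep = "")
  cat("  models: ", paste(x$models, collapse = ", "), "\n", sep = "")
  n_sig <- sum(x$long$q < x$q_threshold, na.rm = TRUE)
  cat("  ", n_sig, " significant cells of ", nrow(x$long), " retained entries\n",
      sep = "")
  invisible(x)
}

#' Wide q-value matrix of a model comparison
#'
#' @param x an \code{assoc_comparison}.
#' @param ... unused.
#' @return numeric matrix, features x "model: variable[level]" columns in
#'   model-definition order; NA marks terms the feature was not tested for.
#' @export
as.matrix.assoc_comparison <- function(x, ...) {
  col_id <- function(m, v, l) paste0(m, ": ", v, ifelse(nzchar(l),
                                                        paste0("[", l, "]"), ""))
  cols <- col_id(x$columns$model, x$columns$variable, x$columns$level)
  m <- matrix(NA_real_, length(x$features), length(cols),
              dimnames = list(x$features, cols))
  key <- col_id(x$long$model, x$long$variable, x$long$level)
  idx <- cbind(match(x$long$feature, x$features), match(key, cols))
  keep <- !is.na(idx[, 1L]) & !is.na(idx[, 2L])
  m[idx[keep, , drop = FALSE]] <- x$long$q[keep]
  m
}

#' Subset a comparison matrix
#'
#' Restricts the comparison to chosen features and/or models and/or a new
#' significance threshold; the row rule (significant in at least one retained
#' model) is re-applied under the new selection.
#'
#' @param x an \code{assoc_comparison}.
#' @param features optional character vector of features to keep.
#' @param models optional character vector of model names to keep.
#' @param q_threshold optional replacement threshold.
#' @return a new \code{assoc_comparison}.
#' @export
filter_matrix <- function(x, features = NULL, models = NULL,
                          q_threshold = NULL) {
  stopifnot(inherits(x, "assoc_comparison"))
  long <- x$all
  columns <- x$columns
  model_names <- x$models
  if (!is.null(models)) {
    unknown <- setdiff(models, model_names)
    if (length(unknown))
      stop("unknown model(s): ", paste(unknown, collapse = ", "))
    model_names <- model_names[model_names %in% models]
    long <- long[long$model %in% models, , drop = FALSE]
    columns <- columns[columns$model %in% models, , drop = FALSE]
  }
  if (!is.null(features)) {
    unknown <- setdiff(features, unique(x$all$feature))
    if (length(unknown))
      stop("unknown feature(s): ", paste(unknown, collapse = ", "))
    long <- long[long$feature %in% features, , drop = FALSE]
  }
  thr <- q_threshold %||% x$q_threshold
  build_comparison(long, columns, model_names, thr)
}

#' Write the long-format comparison table to TSV
#'
#' Columns: model, feature, variable, level, q, significant (0/1, strict
#' \code{q <} threshold).
#'
#' @param x an \code{assoc_comparison}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_comparison <- function(x, path) {
  stopifnot(inherits(x, "assoc_comparison"))
  out <- x$long
  out$significant <- as.integer(out$q < x$q_threshold & !is.na(out$q))
  write_tsv(out, path)
}

#' Comparison heatmap
#'
#' Features on rows, model-blocked (model, variable, level) columns; cells
#' with q below the display threshold are coloured by significance depth
#' (-log10 q), non-significant cells are white, and untested cells grey.
#'
#' @param x an \code{assoc_comparison}.
#' @param q_threshold display threshold; defaults to the matrix's.
#' @param main plot title.
#' @param ... unused.
#' @return invisibly, the wide q matrix drawn.
#' @export
plot.assoc_comparison <- function(x, q_threshold = x$q_threshold,
                                  main = "Associations significant in >= 1 model",
                                  ...) {
  m <- as.matrix(x)
  nr <- nrow(m); nc <- ncol(m)
  depth <- -log10(pmax(m, 1e-20))
  depth[!(m < q_threshold)] <- NA      # colour only significant cells
  pal <- grDevices::colorRampPalette(c("#fddbc7", "#b2182b"))(64)
  rng <- range(depth, na.rm = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  if (rng[1L] == rng[2L]) rng[2L] <- rng[1L] + 1
  old <- graphics::par(mar = c(9, 10, 3, 1))
  on.exit(graphics::par(old), add = TRUE)
  graphics::plot(NA, xlim = c(0.5, nc + 0.5), ylim = c(0.5, nr + 0.5),
                 xlab = "", ylab = "", axes = FALSE, main = main)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    col <- if (is.na(m[i, j])) "grey85"
           else if (is.na(depth[i, j])) "white"
           else pal[1L + floor(63 * (min(depth[i, j], rng[2L]) - rng[1L]) /
                               (rng[2L] - rng[1L]))]
    graphics::rect(j - 0.5, nr - i + 0.5, j + 0.5, nr - i + 1.5,
                   col = col, border = "grey70")
  }
  blocks <- cumsum(table(factor(x$columns$model, levels = x$models)))
  for (b in blocks[-length(blocks)])
    graphics::lines(c(b + 0.5, b + 0.5), c(0.5, nr + 0.5), lwd = 2)
  graphics::axis(1, at = seq_len(nc), labels = colnames(m), las = 2,
                 cex.axis = 0.7, tick = FALSE)
  graphics::axis(2, at = rev(seq_len(nr)), labels = rownames(m), las = 2,
                 cex.axis = 0.7, tick = FALSE)
  graphics::mtext(paste0("coloured: q < ", q_threshold,
                         "; grey: not tested"), side = 1, line = 7.5,
                  cex = 0.8)
  invisible(m)
}
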