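## Detail view of one association: per-sample records, reference-vs-level
## q-value brackets, within-facet Welch t-tests, box/scatter rendering.

#' Per-sample detail records for one association
#'
#' Returns one record per sample: the transformed abundance used for fitting
#' (AST applied iff the model applied it), the value of the selected variable,
#' and all other metadata columns (so the records can be faceted, coloured or
#' labelled downstream). Samples with a missing value of the selected
#' categorical variable form an explicit \code{"NA"} category: they appear in
#' the plot but never enter a statistic. The model's q-values for each
#' reference-vs-level bracket are attached, including non-significant ones.
#'
#' @param fit an \code{\link{run_model}} fit.
#' @param feature feature name (must have been fitted).
#' @param variable fixed-effect variable of the fit's model.
#' @return data.frame of class \code{assoc_detail} with columns
#'   \code{sample_id}, \code{y}, \code{x} plus all metadata columns;
#'   attributes \code{brackets} (level, reference, coefficient, q),
#'   \code{kind}, \code{feature}, \code{variable}, \code{model},
#'   \code{levels} (plot order, "NA" last when present) and \code{reference}.
#' @export
association_detail <- function(fit, feature, variable) {
  stopifnot(inherits(fit, "mbassoc_fit"))
  if (!feature %in% colnames(fit$feature_matrix))
    stop("unknown feature (or removed by the abundance filter): ", feature)
  if (!variable %in% fit$spec$fixed)
    stop("variable '", variable, "' was not tested under model '",
         fit$spec$name, "'")
  kind <- fit$schema$fixed_vars[[variable]]
  y <- fit$feature_matrix[, feature]
  x_raw <- fit$metadata[[variable]]
  rec <- data.frame(sample_id = fit$sample_ids, y = as.numeric(y),
                    stringsAsFactors = FALSE)
  rec <- cbind(rec, fit$metadata, stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  br <- fit$results[fit$results$feature == feature &
                      fit$results$variable == variable, , drop = FALSE]
  if (kind == "categorical") {
    ref <- unique(br$reference)[1L]
    lev <- c(ref, setdiff(fit$schema$level_order[[variable]], ref))
    x <- as.character(x_raw)
    x[is.na(x)] <- "NA"
    if (any(x == "NA")) lev <- c(lev, "NA")
    rec$x <- factor(x, levels = lev)
    brackets <- br[order(match(br$level, lev)),
                   c("level", "reference", "coefficient", "q"), drop = FALSE]
  } else {
    ref <- ""
    lev <- NULL
    rec$x <- as.numeric(x_raw)
    brackets <- br[, c("level", "reference", "coefficient", "q"), drop = FALSE]
  }
  rownames(brackets) <- NULL
  structure(rec,
            class = c("assoc_detail", "data.frame"),
            brackets = brackets, kind = kind, feature = feature,
            variable = variable, model = fit$spec$name,
            levels = lev, reference = ref,
            ast = fit$spec$ast_enabled)
}

#' @export
print.assoc_detail <- function(x, ...) {
  cat("assoc_detail: ", attr(x, "feature"), " ~ ", attr(x, "variable"),
      " (model '", attr(x, "model"), "', ",
      if (attr(x, "kind") == "categorical") "box plot" else "scatter",
      ")\n", sep = "")
  if (attr(x, "kind") == "categorical") {
    tab <- table(x$x)
    cat("  groups: ", paste(sprintf("%s (n=%d)", names(tab), tab),
                            collapse = ", "), "\n", sep = "")
    br <- attr(x, "brackets")
    for (i in seq_len(nrow(br)))
      cat(sprintf("  bracket %s vs %s: q = %.3g\n", br$level[i],
                  br$reference[i], br$q[i]))
  }
  cat("  ", nrow(x), " samples (all plotted; model used complete cases only)\n",
      sep = "")
  invisible(x)
}

#' Within-facet Welch t-tests
#'
#' Splits the detail records by the levels of a categorical facet variable
#' and, within each facet, compares the reference level of x against each
#' other level with a two-sided Welch (unequal-variance) t-test over all
#' plotted samples — no model-based complete-case masking. Samples whose x or
#' facet value is missing sit in the "NA" group/panel and never enter a test;
#' when faceting, the model's q-values are dropped in favour of these nominal
#' p-values. A comparison with fewer than two samples on either side (or
#' constant values on both sides) is reported untestable rather than failing.
#'
#' @param records an \code{assoc_detail} with categorical x.
#' @param facet_var name of a categorical metadata column in the records.
#' @return data.frame: facet, level, reference, n_ref, n_level, p, status
#'   (\code{ok}/\code{untestable}).
#' @export
facet_ttest <- function(records, facet_var) {
  stopifnot(inherits(records, "assoc_detail"))
  if (attr(records, "kind") != "categorical")
    stop("facet t-tests require a categorical x variable")
  if (!facet_var %in% names(records))
    stop("unknown facet variable: ", facet_var)
  fvals <- as.character(records[[facet_var]])
  fvals[is.na(fvals)] <- "NA"
  flev <- facet_levels(fvals)
  ref <- attr(records, "reference")
  lev <- setdiff(attr(records, "levels"), c(ref, "NA"))
  out <- list()
  for (f in flev) {
    in_facet <- fvals == f
    y_ref <- records$y[in_facet & records$x == ref]
    for (l in lev) {
      y_l <- records$y[in_facet & records$x == l]
      out[[length(out) + 1L]] <- data.frame(
        facet = f, level = l, reference = ref,
        n_ref = length(y_ref), n_level = length(y_l),
        p = welch_p(y_ref, y_l), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$status <- ifelse(is.na(res$p), "untestable", "ok")
  res
}

# ordered facet panels, "NA" last
facet_levels <- function(fvals) {
  lev <- unique(fvals)
  c(sort_c(setdiff(lev, "NA")), if ("NA" %in% lev) "NA")
}

# two-sided Welch t-test p; NA when a side has < 2 samples or the data are
# constant on both sides (zero variance, no test statistic)
welch_p <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (stats::var(a) == 0 && stats::var(b) == 0) return(NA_real_)
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Render a detail plot
#'
#' Box plot (categorical x; median line, interquartile box with linearly
#' interpolated quartiles, sample dots) or scatter plot (continuous x). The
#' unfaceted categorical plot annotates each reference-vs-level bracket with
#' the model's q-value; a faceted plot splits the x-axis by the facet
#' variable's levels ("NA" panel last), drops the q-values, and annotates
#' within-facet Welch t-test p-values instead. Dots can be coloured by a
#' categorical variable and labelled by a (random) grouping variable.
#'
#' @param records an \code{assoc_detail}.
#' @param file output path ending in \code{.png} or \code{.pdf}; NULL draws
#'   on the current device.
#' @param facet optional categorical variable to facet by.
#' @param color optional categorical variable to colour dots by.
#' @param label optional variable whose values label the dots.
#' @param width,height device size in inches.
#' @return invisibly, the facet t-test table when faceted, else the bracket
#'   table.
#' @export
render_detail <- function(records, file = NULL, facet = NULL, color = NULL,
                          label = NULL, width = 7, height = 5) {
  stopifnot(inherits(records, "assoc_detail"))
  if (!nrow(records)) stop("no records to plot")
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = width, height = height,
                                units = "in", res = 150),
           pdf = grDevices::pdf(file, width = width, height = height),
           stop("unsupported figure format: .", ext, " (use .png or .pdf)"))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  stats_out <- draw_detail(records, facet = facet, color = color,
                           label = label)
  invisible(stats_out)
}

#' @export
plot.assoc_detail <- function(x, facet = NULL, color = NULL, label = NULL,
                              ...) {
  invisible(draw_detail(x, facet = facet, color = color, label = label))
}

draw_detail <- function(records, facet = NULL, color = NULL, label = NULL) {
  kind <- attr(records, "kind")
  feature <- attr(records, "feature")
  variable <- attr(records, "variable")
  ylab <- if (isTRUE(attr(records, "ast"))) "relative abundance (AST)"
          else "relative abundance"
  col_map <- NULL
  dot_col <- "grey35"
  if (!is.null(color)) {
    if (!color %in% names(records)) stop("unknown colour variable: ", color)
    cv <- as.character(records[[color]]); cv[is.na(cv)] <- "NA"
    lev <- facet_levels(cv)
    pal <- grDevices::colorRampPalette(
      c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e"))(length(lev))
    col_map <- stats::setNames(pal, lev)
    dot_col <- col_map[cv]
  }
  if (kind == "continuous") {
    ok <- !is.na(records$x)
    graphics::plot(records$x[ok], records$y[ok], pch = 19, cex = 0.7,
                   col = if (length(dot_col) > 1L) dot_col[ok] else dot_col,
                   xlab = variable, ylab = ylab,
                   main = paste0(feature, " ~ ", variable,
                                 "  (model '", attr(records, "model"), "')"))
    if (!is.null(col_map))
      graphics::legend("topright", legend = names(col_map), col = col_map,
                       pch = 19, cex = 0.7, title = color)
    return(attr(records, "brackets"))
  }
  if (is.null(facet)) {
    panels <- list(all = records)
    panel_stats <- NULL
  } else {
    if (!facet %in% names(records)) stop("unknown facet variable: ", facet)
    fvals <- as.character(records[[facet]]); fvals[is.na(fvals)] <- "NA"
    flev <- facet_levels(fvals)
    panels <- lapply(flev, function(f) records[fvals == f, , drop = FALSE])
    names(panels) <- flev
    panel_stats <- facet_ttest(records, facet)
  }
  old <- graphics::par(mfrow = c(1, length(panels)),
                       mar = c(6, 4, 3, 1), oma = c(0, 0, 2, 0))
  on.exit(graphics::par(old), add = TRUE)
  lev <- attr(records, "levels")
  for (pn in names(panels)) {
    pr <- panels[[pn]]
    ylim <- range(records$y)
    ylim[2L] <- ylim[2L] + 0.25 * diff(range(c(ylim, ylim[1L] + 1e-9)))
    groups <- lapply(lev, function(l) pr$y[pr$x == l])
    names(groups) <- lev
    graphics::boxplot(groups, ylim = ylim, ylab = ylab, las = 2,
                      outline = FALSE, col = "grey92",
                      main = if (length(panels) > 1L)
                        paste0(facet, " = ", pn) else "")
    for (i in seq_along(groups)) {
      gy <- groups[[i]]
      if (!length(gy)) next
      gx <- i + stats::runif(length(gy), -0.15, 0.15)
      idx <- pr$x == lev[i]
      graphics::points(gx, gy, pch = 19, cex = 0.6,
                       col = if (length(dot_col) > 1L)
                         dot_col[rownames(records) %in% rownames(pr)][idx]
                       else dot_col)
      if (!is.null(label) && label %in% names(pr))
        graphics::text(gx, gy, labels = as.character(pr[[label]])[idx],
                       pos = 4, cex = 0.45, col = "grey50")
    }
    annotate_brackets(records, pr, pn, lev, panel_stats)
  }
  graphics::mtext(paste0(feature, " ~ ", variable, "  (model '",
                         attr(records, "model"), "')"),
                  outer = TRUE, cex = 1)
  if (!is.null(col_map)) {
    graphics::legend("topright", legend = names(col_map), col = col_map,
                     pch = 19, cex = 0.7, title = color)
  }
  if (is.null(panel_stats)) attr(records, "brackets") else panel_stats
}

# unfaceted: model q per bracket; faceted: Welch p within the panel
annotate_brackets <- function(records, pr, panel_name, lev, panel_stats) {
  ref <- attr(records, "reference")
  others <- setdiff(lev, c(ref, "NA"))
  if (!length(others)) return(invisible())
  y_top <- max(records$y)
  step <- 0.07 * max(diff(range(records$y)), 1e-9)
  i_ref <- match(ref, lev)
  for (k in seq_along(others)) {
    l <- others[k]
    i_l <- match(l, lev)
    h <- y_top + k * step
    if (is.null(panel_stats)) {
      br <- attr(records, "brackets")
      val <- br$q[br$level == l]
      lab <- sprintf("q = %.2g%s", val, if (length(val) && !is.na(val) &&
                                            val < 0.2) " *" else "")
    } else {
      row <- panel_stats[panel_stats$facet == panel_name &
                           panel_stats$level == l, ]
      lab <- if (nrow(row) && row$status == "ok")
        sprintf("p = %.2g%s", row$p, if (row$p < 0.05) " *" else "")
      else "n.s. (untestable)"
    }
    graphics::segments(i_ref, h, i_l, h)
    graphics::text((i_ref + i_l) / 2, h + 0.4 * step, lab, cex = 0.65)
  }
  invisible()
}
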