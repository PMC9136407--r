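## Per-feature multivariable association engine: treatment-coded design
## construction, OLS / random-intercept mixed-model fitting, BH-FDR.

#' Define a candidate association model
#'
#' A model spec names an ordered subset of fixed-effect variables, a set of
#' random-effect grouping variables (random intercepts), optional per-variable
#' reference-level overrides, whether the arcsine square-root transform is
#' applied, and the FDR threshold used downstream for significance display.
#'
#' @param name model label; used to identify the model in comparisons.
#' @param fixed character vector (ordered) of fixed-effect variable names;
#'   must be non-empty.
#' @param random character vector of random-effect grouping variables.
#' @param reference named list/character of per-variable reference-level
#'   overrides; variables not named fall back to the schema default
#'   (alphabetically first level).
#' @param ast logical: apply the arcsine square-root transform.
#' @param q_threshold FDR significance threshold in (0, 1); default 0.2.
#' @return an object of class \code{model_spec}.
#' @examples
#' model_spec("basic", fixed = c("disease", "delivery", "age"),
#'            random = "subject")
#' @export
model_spec <- function(name, fixed, random = character(), reference = list(),
                       ast = TRUE, q_threshold = 0.2) {
  fixed <- as.character(fixed)
  if (!length(fixed)) stop("a model needs at least one fixed-effect variable")
  if (anyDuplicated(fixed)) stop("duplicated fixed-effect variables")
  if (!is.numeric(q_threshold) || q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must lie strictly between 0 and 1")
  structure(list(name = as.character(name),
                 fixed = fixed,
                 random = as.character(random),
                 reference = as.list(reference),
                 ast_enabled = isTRUE(ast),
                 q_threshold = q_threshold),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec '", x$name, "': ", sep = "")
  cat("fixed = ", paste(x$fixed, collapse = " + "), sep = "")
  if (length(x$random))
    cat(" | random intercepts: ", paste(x$random, collapse = ", "), sep = "")
  if (!x$ast_enabled) cat(" [AST off]")
  cat("\n")
  invisible(x)
}

# reference level for variable v under spec overrides, else schema default
effective_reference <- function(spec, schema, v) {
  ref <- spec$reference[[v]]
  if (is.null(ref)) ref <- schema$reference[[v]]
  ref <- as.character(ref)
  if (!ref %in% schema$level_order[[v]])
    stop("reference level '", ref, "' is not a level of '", v, "'")
  ref
}

#' Build the fixed/random design for one model
#'
#' Constructs the treatment-coded design: an intercept, one indicator per
#' non-reference level of each categorical fixed variable (compared to the
#' reference level), one column per continuous variable, and one grouping
#' factor per random variable. A rank-deficient fixed design (perfectly
#' aliased variables) is an error reporting the aliased columns.
#'
#' @param metadata data.frame of metadata (one row per sample).
#' @param spec a \code{\link{model_spec}}.
#' @param schema a resolved \code{\link{variable_schema}}.
#' @param mask logical complete-case mask from
#'   \code{\link{complete_case_mask}} over the spec's variables.
#' @return a list with \code{data} (model frame on masked rows), \code{terms}
#'   (data.frame mapping design terms to variable/level/reference),
#'   \code{fixed_formula}, \code{formula} (including random intercepts),
#'   \code{groups} (random variable names) and \code{n}.
#' @export
build_design <- function(metadata, spec, schema, mask = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(schema, "variable_schema"))
  vars <- c(spec$fixed, spec$random)
  unknown <- setdiff(spec$fixed, names(schema$fixed_vars))
  if (length(unknown))
    stop("model '", spec$name, "' uses undeclared fixed variables: ",
         paste(unknown, collapse = ", "))
  unknown_r <- setdiff(spec$random, schema$random_vars)
  if (length(unknown_r))
    stop("model '", spec$name, "' uses undeclared random variables: ",
         paste(unknown_r, collapse = ", "))
  if (is.null(mask)) mask <- complete_case_mask(metadata, vars)
  df <- metadata[mask, vars, drop = FALSE]
  terms_list <- list()
  for (v in spec$fixed) {
    kind <- schema$fixed_vars[[v]]
    if (kind == "categorical") {
      ref <- effective_reference(spec, schema, v)
      lev <- c(ref, setdiff(schema$level_order[[v]], ref))
      present <- unique(as.character(df[[v]]))
      if (!all(present %in% lev))
        stop("variable '", v, "' has levels outside the schema: ",
             paste(setdiff(present, lev), collapse = ", "))
      df[[v]] <- factor(as.character(df[[v]]), levels = lev)
      terms_list[[v]] <- data.frame(term = paste0(v, lev[-1L]),
                                    variable = v, level = lev[-1L],
                                    reference = ref,
                                    stringsAsFactors = FALSE)
    } else {
      df[[v]] <- as.numeric(df[[v]])
      terms_list[[v]] <- data.frame(term = v, variable = v, level = "",
                                    reference = "", stringsAsFactors = FALSE)
    }
  }
  for (g in spec$random) df[[g]] <- factor(as.character(df[[g]]))
  fixed_formula <- stats::as.formula(
    paste(".mb_y ~", paste(spec$fixed, collapse = " + ")))
  full_formula <- if (length(spec$random)) {
    stats::as.formula(paste(".mb_y ~", paste(spec$fixed, collapse = " + "), "+",
                            paste(sprintf("(1 | %s)", spec$random),
                                  collapse = " + ")))
  } else fixed_formula
  X <- stats::model.matrix(stats::as.formula(
    paste("~", paste(spec$fixed, collapse = " + "))), df)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    partner <- vapply(aliased, function(a) {
      others <- setdiff(colnames(X), a)
      cors <- suppressWarnings(abs(stats::cor(X[, a], X[, others])))
      others[which.max(cors)]
    }, character(1))
    stop("rank-deficient design in model '", spec$name, "': ",
         paste(sprintf("'%s' is aliased with '%s'", aliased, partner),
               collapse = "; "))
  }
  list(data = df,
       terms = do.call(rbind, c(terms_list, list(make.row.names = FALSE))),
       fixed_formula = fixed_formula,
       formula = full_formula,
       groups = spec$random,
       n = nrow(df),
       n_fixed_cols = ncol(X))
}

#' Fit one feature against a design
#'
#' Ordinary least squares when the design has no random variables (two-sided
#' Wald t-tests on residual degrees of freedom); otherwise a linear mixed
#' model with one random intercept per grouping factor, fitted by REML, with
#' two-sided Wald tests under the normal approximation. Constant responses
#' are skipped; inestimable or non-converged fits are reported as failures
#' without aborting.
#'
#' @param y numeric response vector (transformed abundances, masked rows).
#' @param design a design from \code{\link{build_design}}.
#' @return data.frame with one row per tested term: \code{term},
#'   \code{variable}, \code{level}, \code{reference}, \code{coefficient},
#'   \code{stderr}, \code{p}, \code{status}
#'   (\code{ok}/\code{fit_failed}/\code{skipped_constant}).
#' @export
fit_feature <- function(y, design) {
  out <- design$terms
  out$coefficient <- NA_real_
  out$stderr <- NA_real_
  out$p <- NA_real_
  if (length(y) != design$n)
    stop("response length ", length(y), " does not match design rows ", design$n)
  if (length(unique(y)) <= 1L) {
    out$status <- "skipped_constant"
    return(out)
  }
  if (design$n < design$n_fixed_cols + 1L) {
    out$status <- "fit_failed"
    return(out)
  }
  df <- design$data
  df$.mb_y <- as.numeric(y)
  coefs <- if (length(design$groups)) {
    fit_mixed(design$formula, df)
  } else {
    fit <- stats::lm(design$fixed_formula, data = df)
    stats::coef(summary(fit))[, c(1L, 2L, 4L), drop = FALSE]
  }
  if (is.null(coefs) || !all(out$term %in% rownames(coefs))) {
    out$status <- "fit_failed"
    return(out)
  }
  out$coefficient <- coefs[out$term, 1L]
  out$stderr <- coefs[out$term, 2L]
  out$p <- coefs[out$term, 3L]
  out$status <- ifelse(is.finite(out$p), "ok", "fit_failed")
  out
}

# REML random-intercept fit; Wald z p-values. Boundary (singular) fits keep
# their estimates; errors and non-convergence yield NULL.
fit_mixed <- function(formula, data) {
  failed <- FALSE
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(formula, data = data, REML = TRUE,
                        control = lme4::lmerControl(calc.derivs = FALSE)),
             error = function(e) NULL),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        failed <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (is.null(fit) || failed) return(NULL)
  cc <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- cc / se
  cbind(Estimate = cc, `Std. Error` = se,
        `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with the m non-missing p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and mapped back
#' to input order. Missing entries (e.g. failed fits) pass through as missing
#' and do not count towards the family size.
#'
#' @param p numeric vector of p-values in [0, 1], NAs allowed.
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  obs <- p[!is.na(p)]
  if (length(obs) && (any(obs < 0) || any(obs > 1)))
    stop("p-values must lie in [0, 1]")
  if (!length(obs)) return(p)
  stats::p.adjust(p, method = "BH", n = length(obs))
}

#' Fit one model to every feature of a sample table
#'
#' Runs the preprocessing pipeline (TSS normalisation, low-abundance filter,
#' arcsine square-root transform if the model enables it), builds the model's
#' design over complete cases of the model variables, fits every retained
#' feature, and pools all nominal p-values of the run (every feature x every
#' tested term) into a single Benjamini-Hochberg adjustment.
#'
#' @param table a \code{\link{sample_table}}.
#' @param spec a \code{\link{model_spec}}.
#' @param schema a \code{\link{variable_schema}}; defaults to the table's.
#' @param filter_threshold low-abundance removal cutoff (see
#'   \code{\link{filter_low_abundance}}).
#' @return an object of class \code{mbassoc_fit}: the association results
#'   (one row per feature x tested term, sorted by q) plus the preprocessed
#'   feature matrix and metadata needed for detail views.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 20, n_features = 8, seed = 1))
#' fit <- run_model(coh$table, model_spec("basic", fixed = c("disease", "age"),
#'                                        random = "subject"))
#' head(summary(fit)$results)
#' @export
run_model <- function(table, spec, schema = table$schema,
                      filter_threshold = 1e-4) {
  stopifnot(inherits(table, "sample_table"), inherits(spec, "model_spec"))
  Y <- preprocess_features(table$features, ast = spec$ast_enabled,
                           filter_threshold = filter_threshold)
  dropped <- attr(Y, "dropped_samples") %||% character()
  removed <- attr(Y, "removed_features") %||% character()
  keep <- !(table$sample_ids %in% dropped)
  metadata <- table$metadata[keep, , drop = FALSE]
  sample_ids <- table$sample_ids[keep]
  vars <- c(spec$fixed, spec$random)
  mask <- complete_case_mask(metadata, vars)
  design <- build_design(metadata, spec, schema, mask)
  feats <- colnames(Y)
  res <- vector("list", length(feats))
  n_used <- design$n
  for (i in seq_along(feats)) {
    r <- fit_feature(Y[mask, feats[i]], design)
    r <- cbind(feature = feats[i], r, stringsAsFactors = FALSE)
    res[[i]] <- r
  }
  results <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (all(results$status != "ok"))
    stop("model '", spec$name, "' failed for every feature")
  results$q <- bh_adjust(results$p)
  results$n_used <- ifelse(results$status == "ok", n_used, NA_integer_)
  results$model <- spec$name
  ord <- order(results$q, results$p, results$feature, results$term,
               na.last = TRUE)
  results <- results[ord, c("feature", "variable", "level", "reference",
                            "term", "coefficient", "stderr", "p", "q",
                            "n_used", "status", "model")]
  rownames(results) <- NULL
  structure(list(results = results,
                 spec = spec,
                 schema = schema,
                 terms = design$terms,
                 feature_matrix = Y,
                 metadata = metadata,
                 sample_ids = sample_ids,
                 mask = mask,
                 dropped_samples = dropped,
                 removed_features = removed,
                 n_samples = nrow(metadata),
                 n_used = n_used),
            class = "mbassoc_fit")
}

#' @export
print.mbassoc_fit <- function(x, ...) {
  r <- x$results
  sig <- sum(r$q < x$spec$q_threshold, na.rm = TRUE)
  cat("mbassoc_fit: model '", x$spec$name, "'\n", sep = "")
  cat("  ", length(unique(r$feature)), " features x ", nrow(x$terms),
      " tested terms (", nrow(r), " associations), ", x$n_used, "/",
      x$n_samples, " samples in fit\n", sep = "")
  cat("  ", sig, " associations with q < ", x$spec$q_threshold, "\n", sep = "")
  if (length(x$removed_features))
    cat("  removed low-abundance features: ", length(x$removed_features),
        "\n", sep = "")
  if (sig) {
    top <- utils::head(r[r$status == "ok", ], min(5L, sig))
    cat("  top associations:\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %s ~ %s%s: coef %+0.3g, q = %.3g\n",
                  top$feature[i], top$variable[i],
                  ifelse(nzchar(top$level[i]), paste0("[", top$level[i], "]"), ""),
                  top$coefficient[i], top$q[i]))
  }
  invisible(x)
}

#' @export
summary.mbassoc_fit <- function(object, ...) {
  r <- object$results
  structure(list(model = object$spec$name,
                 results = r,
                 n_significant = sum(r$q < object$spec$q_threshold, na.rm = TRUE),
                 n_failed = sum(r$status == "fit_failed"),
                 n_skipped = sum(r$status == "skipped_constant"),
                 q_threshold = object$spec$q_threshold),
            class = "summary.mbassoc_fit")
}

#' @export
print.summary.mbassoc_fit <- function(x, ...) {
  cat("Model '", x$model, "': ", nrow(x$results), " associations; ",
      x$n_significant, " significant at q < ", x$q_threshold, sep = "")
  if (x$n_failed) cat("; ", x$n_failed, " failed fits", sep = "")
  if (x$n_skipped) cat("; ", x$n_skipped, " constant features skipped", sep = "")
  cat("\n")
  print(utils::head(x$results, 10L))
  invisible(x)
}

#' @export
coef.mbassoc_fit <- function(object, ...) {
  r <- object$results[object$results$status == "ok", ]
  feats <- unique(object$results$feature)
  terms <- object$terms$term
  m <- matrix(NA_real_, length(feats), length(terms),
              dimnames = list(feats, terms))
  m[cbind(match(r$feature, feats), match(r$term, terms))] <- r$coefficient
  m
}

#' @export
as.data.frame.mbassoc_fit <- function(x, ...) x$results

#' @export
plot.mbassoc_fit <- function(x, q_threshold = x$spec$q_threshold, ...) {
  cmp <- compare_models(list(x), q_threshold = q_threshold)
  plot(cmp, ...)
}

#' Write per-model association results to TSV
#'
#' Columns: feature, variable, level, reference, coefficient, stderr, p, q,
#' n_used, status.
#'
#' @param fit an \code{mbassoc_fit}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(fit, path) {
  stopifnot(inherits(fit, "mbassoc_fit"))
  cols <- c("feature", "variable", "level", "reference", "coefficient",
            "stderr", "p", "q", "n_used", "status")
  write_tsv(fit$results[cols], path)
}

# term column is internal; expose it for compare/detail modules
fit_terms <- function(fit) fit$terms
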