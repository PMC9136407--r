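## Feature-table preprocessing: total-sum scaling, low-abundance filtering,
## arcsine square-root transform, and the complete-case (NA) contract.
## A feature matrix carries a "stage" attribute: raw | tss | filtered | ast.

stage_of <- function(m) attr(m, "stage") %||% "raw"

set_stage <- function(m, stage) {
  attr(m, "stage") <- stage
  m
}

#' Total-sum-scaling normalisation
#'
#' Divides each sample row by its total so features become relative abundances
#' summing to 1. Samples whose total is zero cannot be normalised; they are
#' dropped with a warning listing their IDs (the dropped IDs are also attached
#' as attribute \code{"dropped_samples"}).
#'
#' @param m numeric matrix, samples x features, entries \eqn{\ge 0}.
#' @return the normalised matrix, stage \code{"tss"}.
#' @export
tss_normalize <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative abundance values are not allowed")
  totals <- rowSums(m)
  zero <- totals == 0
  if (any(zero)) {
    ids <- rownames(m)[zero] %||% which(zero)
    warning("dropping ", sum(zero), " sample(s) with zero total abundance: ",
            paste(ids, collapse = ", "))
    m <- m[!zero, , drop = FALSE]
    totals <- totals[!zero]
  }
  out <- m / totals
  attr(out, "dropped_samples") <- if (any(zero)) ids else character()
  set_stage(out, "tss")
}

#' Remove features with negligible total abundance
#'
#' A feature is removed iff the sum of its normalised abundances over all
#' samples is strictly less than \code{threshold} (default 0.0001, the
#' conventional post-TSS cutoff). Removed feature names are attached as
#' attribute \code{"removed_features"}.
#'
#' @param m a TSS-normalised matrix (stage \code{"tss"}).
#' @param threshold removal cutoff on the per-feature total normalised sum.
#' @return the filtered matrix, stage \code{"filtered"}.
#' @export
filter_low_abundance <- function(m, threshold = 1e-4) {
  if (!stage_of(m) %in% c("tss"))
    stop("filter_low_abundance expects a TSS-normalised matrix ",
         "(run tss_normalize first)")
  totals <- colSums(m)
  drop <- totals < threshold           # strictly less than
  if (all(drop)) stop("empty feature set: every feature falls below the ",
                      "abundance threshold ", threshold)
  removed <- colnames(m)[drop] %||% which(drop)
  out <- m[, !drop, drop = FALSE]
  attr(out, "dropped_samples") <- attr(m, "dropped_samples")
  attr(out, "removed_features") <- if (any(drop)) removed else character()
  set_stage(out, "filtered")
}

#' Arcsine square-root transformation
#'
#' Maps each relative abundance \eqn{x \in [0, 1]} to \eqn{\arcsin\sqrt{x}},
#' spreading small proportions while keeping zeros at zero; the transformed
#' range is \eqn{[0, \pi/2] \approx [0, 1.57079]}. With \code{enabled =
#' FALSE} the matrix passes through unchanged (the transform is a per-run
#' toggle).
#'
#' @param m numeric matrix with entries in \eqn{[0, 1]} when enabled.
#' @param enabled logical toggle.
#' @return the transformed matrix, stage \code{"ast"} (or the input unchanged).
#' @export
ast_transform <- function(m, enabled = TRUE) {
  if (!enabled) return(m)
  if (any(m < 0) || any(m > 1))
    stop("ast_transform requires values in [0, 1]; apply TSS normalisation ",
         "to absolute abundances first")
  out <- asin(sqrt(m))
  attr(out, "dropped_samples") <- attr(m, "dropped_samples")
  attr(out, "removed_features") <- attr(m, "removed_features")
  set_stage(out, "ast")
}

#' Complete-case mask over model variables
#'
#' TRUE for samples with no missing value in any of the given model variables.
#' The mask governs model fitting only: detail views keep the masked-out
#' samples as an explicit "NA" category, and a variable's missing values only
#' exclude a sample from models that actually include that variable.
#'
#' @param metadata data.frame of metadata columns.
#' @param variables character vector of model variable names.
#' @return logical vector, one entry per sample.
#' @export
complete_case_mask <- function(metadata, variables) {
  missing_vars <- setdiff(variables, names(metadata))
  if (length(missing_vars))
    stop("model variables absent from metadata: ",
         paste(missing_vars, collapse = ", "))
  if (!length(variables)) return(rep(TRUE, nrow(metadata)))
  stats::complete.cases(metadata[variables])
}

# tss -> filter -> ast pipeline used by run_model; keeps drop/removal logs
preprocess_features <- function(features, ast = TRUE, filter_threshold = 1e-4) {
  m <- tss_normalize(features)
  m <- filter_low_abundance(m, threshold = filter_threshold)
  ast_out <- ast_transform(m, enabled = ast)
  if (!ast) {
    attr(ast_out, "dropped_samples") <- attr(m, "dropped_samples")
    attr(ast_out, "removed_features") <- attr(m, "removed_features")
  }
  ast_out
}
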