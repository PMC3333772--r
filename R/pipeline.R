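# The end-to-end detector: per-gene two-step nulls, pooled correction,
# signed calls.

#' Full detection parameter set
#'
#' Defaults follow the two-step scheme: a strong variance prior
#' (`beta = 6`) and a tight small-component threshold (`per = 0.1`) for the
#' screening pass, then an unpenalized refit (`beta = 0`) with `per = 0.3`
#' on the cleaned profile. `pv` thresholds the Benjamini-Yekutieli adjusted
#' p-values; `alpha` is the per-gene family-wise rate of provisional
#' exclusions between the two steps (see [run_two_step()]).
#'
#' @param step1,step2 [step_params()] for the two detection passes.
#' @param pv adjusted-p-value threshold for the final calls.
#' @param correction multiple-testing method (`"BY"`, `"BH"`,
#'   `"bonferroni"`, `"none"`).
#' @param alpha provisional unadjusted threshold between steps.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(step1 = step_params(per = 0.1, beta = 6, kmax = 1),
                             step2 = step_params(per = 0.2, beta = 0),
                             pv = 0.05,
                             correction = c("BY", "BH", "bonferroni", "none"),
                             alpha = 0.05) {
  correction <- match.arg(correction)
  if (!is.numeric(pv) || pv <= 0 || pv >= 1) {
    stop_validation("pv must be in (0, 1), got %s", format(pv))
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_validation("alpha must be in (0, 1)")
  }
  stopifnot(inherits(step1, "step_params"), inherits(step2, "step_params"))
  structure(list(step1 = step1, step2 = step2, pv = pv,
                 correction = correction, alpha = alpha),
            class = "detection_params")
}

#' Detect condition-specific expression in a matrix
#'
#' Runs the two-step mixture-null procedure on every row of a log2
#' expression matrix, pools all gene-by-condition p-values, corrects them
#' for multiple testing, and emits signed specificity calls. A gene whose
#' mixture fit fails entirely is reported with `NA` p-values and zero calls
#' (logged), never aborting the run.
#'
#' @param mat numeric matrix, rows = genes (rownames = identifiers),
#'   columns = conditions (colnames), log2 scale, at least 2 columns.
#' @param params a [detection_params()] object.
#' @param seed integer master seed; per-gene fit seeds are derived from it.
#' @param verbose emit progress/log messages.
#' @return a `specificity_result` (see [call_specific()]) with additional
#'   elements `fits` (per-gene two-step summaries: selected K, component
#'   parameters, excluded components and null for each step), `params`,
#'   `seed`, and `direction` (the full genes x conditions direction matrix).
#' @export
detect_specific <- function(mat, params = detection_params(), seed = 1L,
                            verbose = FALSE) {
  mat <- validate_expression(mat)
  stopifnot(inherits(params, "detection_params"))
  log_reset(verbose = verbose)
  ng <- nrow(mat); nc <- ncol(mat)
  if (nc < 10L) {
    condspec_log("only %d conditions: mixture fits may be unstable", nc)
  }
  raw <- matrix(NA_real_, ng, nc, dimnames = dimnames(mat))
  dirs <- matrix(1L, ng, nc, dimnames = dimnames(mat))
  fits <- vector("list", ng)
  names(fits) <- rownames(mat)
  for (i in seq_len(ng)) {
    res <- tryCatch(
      run_two_step(mat[i, ], step1 = params$step1, step2 = params$step2,
                   alpha = params$alpha, seed = derive_seed(seed, i)),
      condspec_error = function(e) {
        condspec_log("gene %s: fit failed (%s); reported as NA",
                     rownames(mat)[i], conditionMessage(e))
        NULL
      }
    )
    if (is.null(res)) {
      fits[[i]] <- list(failed = TRUE)
      next
    }
    raw[i, ] <- res$p_two
    dirs[i, ] <- res$direction
    fits[[i]] <- list(
      failed = FALSE,
      step1 = step_summary(res$step1),
      step2 = if (is.null(res$step2)) NULL else step_summary(res$step2),
      null = unclass(res$null)
    )
  }
  adj <- matrix(adjust_pvalues(as.vector(raw), method = params$correction),
                ng, nc, dimnames = dimnames(mat))
  out <- call_specific(adj, dirs, pv = params$pv, raw = raw)
  out$direction <- dirs
  out$fits <- fits
  out$params <- params
  out$seed <- as.integer(seed)
  out$log <- log_lines()
  out
}

step_summary <- function(s) {
  list(K = s$fit$K,
       weights = s$fit$weights, means = s$fit$means, sds = s$fit$sds,
       bic = s$fit$bic,
       excluded_components = as.integer(s$excluded_components),
       provisional_outliers = as.integer(s$provisional_outliers),
       null = unclass(s$null))
}

validate_expression <- function(mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop_validation("input must be a numeric genes x conditions matrix")
  }
  if (ncol(mat) < 2L) stop_validation("need at least 2 conditions")
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("gene_%04d", seq_len(nrow(mat)))
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("cond_%02d", seq_len(ncol(mat)))
  }
  if (anyDuplicated(rownames(mat))) stop_validation("duplicate gene identifiers")
  if (anyDuplicated(colnames(mat))) stop_validation("duplicate condition identifiers")
  if (!all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    stop_validation("non-finite expression value at gene '%s', condition '%s'",
                    rownames(mat)[bad[1L]], colnames(mat)[bad[2L]])
  }
  mat
}
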