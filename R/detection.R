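# Mixture-tail p-values, multiple-testing correction and specificity calls.

#' Weighted mixture-tail p-values
#'
#' For each expression value `x`, the upper- and lower-tail p-values under a
#' gene's null mixture: the tail probability of each Gaussian component,
#' weighted by the component's (renormalized) proportion in the null.
#' `p_up + p_down = 1` for every value.
#'
#' @param null a `null_model` (see [build_null()]).
#' @param x numeric vector of expression values.
#' @return list with numeric vectors `p_up` and `p_down`.
#' @examples
#' nm <- structure(list(means = 0, sds = 1, weights = 1, retained = 1L),
#'                 class = "null_model")
#' mixture_tail_p(nm, 1.6449)$p_up  # ~0.05
#' @export
mixture_tail_p <- function(null, x) {
  stopifnot(inherits(null, "null_model"))
  x <- as.numeric(x)
  up <- vapply(seq_along(null$weights), function(k) {
    null$weights[k] * stats::pnorm(x, null$means[k], null$sds[k],
                                   lower.tail = FALSE)
  }, numeric(length(x)))
  dn <- vapply(seq_along(null$weights), function(k) {
    null$weights[k] * stats::pnorm(x, null$means[k], null$sds[k])
  }, numeric(length(x)))
  if (length(x) == 1L) {
    list(p_up = sum(up), p_down = sum(dn))
  } else {
    list(p_up = rowSums(matrix(up, nrow = length(x))),
         p_down = rowSums(matrix(dn, nrow = length(x))))
  }
}

#' Two-sided p-value and direction from the two tails
#'
#' Combines one-sided tail p-values into a two-sided p-value
#' `min(1, 2*min(p_up, p_down))` with a direction: `+1` when the upper tail
#' is smaller (specific expression), `-1` when the lower tail is smaller
#' (specific repression), `+1` on an exact tie.
#'
#' @param p_up,p_down numeric vectors of tail p-values (summing to 1).
#' @return list with `p_two` and integer `direction`.
#' @export
two_sided_call <- function(p_up, p_down) {
  if (length(p_up) != length(p_down)) stop_validation("tail vectors differ in length")
  list(p_two = pmin(1, 2 * pmin(p_up, p_down)),
       direction = ifelse(p_up <= p_down, 1L, -1L))
}

#' Multiple-testing correction over the pooled p-value family
#'
#' Adjusts the flat vector of all gene-by-condition p-values. The default is
#' Benjamini-Yekutieli, which controls the FDR under arbitrary dependence —
#' appropriate here because a gene's p-values across conditions share the
#' same fitted null.
#'
#' @param p numeric vector of raw p-values in \[0, 1\] (NA allowed).
#' @param method one of `"BY"`, `"BH"`, `"bonferroni"`, `"none"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BY", "BH", "bonferroni", "none")) {
  method <- match.arg(method)
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop_validation("p-values outside [0, 1] at position(s) %s",
                    paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  stats::p.adjust(p, method = method)
}

#' Signed specificity calls from adjusted p-values
#'
#' A cell is called specific (`+1` up, `-1` down) when its adjusted p-value
#' is strictly below `pv`; otherwise `0`. A gene is flagged specific when at
#' least one of its conditions is called.
#'
#' @param adjusted genes x conditions matrix of adjusted p-values.
#' @param directions conformable matrix of `+1`/`-1` directions.
#' @param pv adjusted-p-value threshold.
#' @param raw optional conformable matrix of raw p-values, carried through.
#' @return an object of class `specificity_result`: list with matrices
#'   `raw_p`, `adjusted_p`, `call` (values in `{-1, 0, 1}`), logical vector
#'   `specific` per gene, and `specific_conditions`, a per-gene list of
#'   named direction vectors.
#' @export
call_specific <- function(adjusted, directions, pv = 0.05, raw = NULL) {
  if (!is.matrix(adjusted) || !is.matrix(directions) ||
      !all(dim(adjusted) == dim(directions))) {
    stop_validation("adjusted and directions must be conformable matrices")
  }
  if (!is.numeric(pv) || pv < 0 || pv > 1) stop_validation("pv must be in [0, 1]")
  call <- matrix(0L, nrow(adjusted), ncol(adjusted),
                 dimnames = dimnames(adjusted))
  hit <- !is.na(adjusted) & adjusted < pv
  call[hit] <- as.integer(directions[hit])
  specific <- rowSums(call != 0L, na.rm = TRUE) > 0L
  spec_conds <- lapply(seq_len(nrow(call)), function(i) {
    j <- which(call[i, ] != 0L)
    stats::setNames(call[i, j], colnames(call)[j])
  })
  names(spec_conds) <- rownames(call)
  structure(list(
    raw_p = raw, adjusted_p = adjusted, call = call,
    specific = specific, specific_conditions = spec_conds,
    pv = pv
  ), class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  ng <- nrow(x$call); nc <- ncol(x$call)
  ns <- sum(x$specific)
  cat(sprintf("Specificity result: %d genes x %d conditions\n", ng, nc))
  cat(sprintf("  specific genes: %d (%d up calls, %d down calls) at pv < %g\n",
              ns, sum(x$call == 1L), sum(x$call == -1L), x$pv))
  invisible(x)
}

#' Per-condition summary of specificity calls
#'
#' Counts of specifically up-regulated, down-regulated and total specific
#' genes in each condition — the per-tissue summary table of a typical
#' multi-tissue analysis.
#'
#' @param result a `specificity_result`.
#' @return data.frame with columns `condition`, `up`, `down`, `total`.
#' @export
condition_counts <- function(result) {
  stopifnot(inherits(result, "specificity_result"))
  up <- colSums(result$call == 1L)
  down <- colSums(result$call == -1L)
  data.frame(condition = colnames(result$call), up = up, down = down,
             total = up + down, row.names = NULL)
}
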