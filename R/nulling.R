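# Outlier-component exclusion and null-distribution construction.
#
# A gene's null distribution is the mixture of components that survive three
# screening rules: (I) the component median must differ from the main
# component's median by more than `md`; given that, the component is excluded
# when it is small (assigned fraction < `per`) AND either (II) well separated
# (minimum absolute log-likelihood ratio of its values > `mlk`) or
# (III) largely spread out (sd ratio main/candidate < `rsd`).

#' Per-step detection parameters
#'
#' Bundles the thresholds governing one pass of the two-step detection:
#' the outlier-component screening rules and the variance prior used when
#' fitting this step's mixture.
#'
#' @param per maximum assigned-data fraction for a component to count as
#'   "small", in (0, 1).
#' @param md minimum absolute difference between component medians
#'   (log2 units).
#' @param mlk minimum of the absolute log-likelihood ratios (nats).
#' @param rsd standard-deviation-ratio threshold (main / candidate,
#'   dimensionless).
#' @param lambda,beta variance prior for this step's mixture fit
#'   (see [fit_gaussian_mixture()]).
#' @param kmax maximum number of mixture components fitted in this step
#'   (1 to 3). The screening pass uses a single component: fitting
#'   multi-component structure to a profile still contaminated by the very
#'   outliers being screened lets spike-absorbing components enter the null
#'   and mask detection.
#' @return an object of class `step_params`.
#' @export
step_params <- function(per = 0.1, md = 1.3, mlk = 100, rsd = 0.1,
                        lambda = 1, beta = 6, kmax = 3L) {
  if (!is.numeric(per) || per <= 0 || per >= 1) {
    stop_validation("per must be in (0, 1), got %s", format(per))
  }
  if (md < 0 || mlk < 0 || rsd < 0) {
    stop_validation("md, mlk and rsd must be nonnegative")
  }
  if (lambda < 0 || beta < 0) stop_validation("lambda and beta must be nonnegative")
  if (!kmax %in% 1:3) stop_validation("kmax must be 1, 2 or 3")
  structure(list(per = per, md = md, mlk = mlk, rsd = rsd,
                 lambda = lambda, beta = beta, kmax = as.integer(kmax)),
            class = "step_params")
}

# Finite-sample correction to the robust-z cut: with a few dozen
# conditions the robust scale estimate is noisy enough that the nominal
# normal quantile over-flags; the factor (calibrated against the null
# distribution of the maximum robust z at n ~ 32) restores the intended
# family rate.
SCREEN_CAL <- 1.16

# Robust scale for the screen: sd of the values inside the 10-90% quantile
# range, rescaled for consistency at the normal (0.6616 is the sd of a
# standard normal truncated to its central 80% mass). Resists up to ~10%
# outliers per side with considerably less sampling noise than the MAD,
# whose frequent under-estimates at this sample size turn ordinary
# extremes into apparent outliers. Falls back to the MAD when the trimmed
# set degenerates.
robust_scale <- function(v) {
  q <- stats::quantile(v, c(0.1, 0.9), names = FALSE)
  mid <- v[v >= q[1] & v <= q[2]]
  if (length(mid) < 3L) return(stats::mad(v))
  stats::sd(mid) / 0.6616076
}

# Iterative robust outlier screen: peels the most extreme value,
# re-estimates location and scale on the remainder, and repeats. Returns
# the flagged condition indices, or an empty set when values above the cut
# still remain once `cap` values have been peeled — a flagged structure
# that large is secondary background (e.g. a second expression bulk), not
# an outlier set, and is left to the mixture fit.
robust_screen <- function(x, cut, cap) {
  flagged <- integer(0)
  repeat {
    keep <- setdiff(seq_along(x), flagged)
    if (length(keep) < 4L) return(integer(0))
    s <- robust_scale(x[keep])
    if (s <= 0) break
    rz <- abs(x - stats::median(x[keep])) / s
    cand <- setdiff(which(rz > cut), flagged)
    if (length(cand) == 0L) break
    if (length(flagged) >= cap) return(integer(0))
    flagged <- c(flagged, cand[which.max(rz[cand])])
  }
  sort(flagged)
}

#' Index of the main mixture component
#'
#' The component carrying the largest mixture weight; ties break by larger
#' hard-assignment count, then by smaller distance of the component mean to
#' the overall data median. The main component is always part of the null.
#'
#' @param fit a `mixture_fit`.
#' @return integer component index.
#' @export
main_component <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$K == 1L) return(1L)
  counts <- tabulate(fit$assignments, nbins = fit$K)
  med_all <- stats::median(fit$data)
  ord <- order(-fit$weights, -counts, abs(fit$means - med_all))
  ord[1L]
}

#' Flag outlier mixture components
#'
#' Applies the three screening rules to every non-main component of a fitted
#' mixture. Rule I (median gap > `md`) is a gate; a small component
#' (assigned fraction < `per`) passing it is flagged when it is either well
#' separated from the main component (rule II, min |log-likelihood ratio| >
#' `mlk`) or much wider than it (rule III, sd_main/sd_candidate < `rsd`).
#' A component with no hard-assigned values is flagged iff its mixture
#' weight is below `per` and rule I holds using its mean in place of the
#' median (logged). With a single component the empty set is returned.
#'
#' @param fit a `mixture_fit`.
#' @param params a [step_params()] object.
#' @return integer vector of flagged component indices (possibly empty).
#' @export
flag_outlier_components <- function(fit, params) {
  stopifnot(inherits(fit, "mixture_fit"), inherits(params, "step_params"))
  if (fit$K == 1L) return(integer(0))
  x <- fit$data
  n <- fit$n
  main <- main_component(fit)
  idx_main <- which(fit$assignments == main)
  med_main <- stats::median(x[idx_main])
  flagged <- integer(0)
  for (k in seq_len(fit$K)) {
    if (k == main) next
    idx_k <- which(fit$assignments == k)
    if (length(idx_k) == 0L) {
      hit <- fit$weights[k] < params$per &&
        abs(fit$means[k] - med_main) > params$md
      condspec_log("component %d has no assigned values; weight-based rule -> %s",
                   k, if (hit) "flagged" else "kept")
      if (hit) flagged <- c(flagged, k)
      next
    }
    med_k <- stats::median(x[idx_k])
    frac_k <- length(idx_k) / n
    rule1 <- abs(med_k - med_main) > params$md
    if (!rule1 || frac_k >= params$per) next
    min_llr <- min(loglik_ratio_abs(x[idx_k],
                                    fit$means[k], fit$sds[k],
                                    fit$means[main], fit$sds[main]))
    sdr <- fit$sds[main] / fit$sds[k]
    if (min_llr > params$mlk || sdr < params$rsd) flagged <- c(flagged, k)
  }
  flagged
}

#' Build a gene's null distribution from the retained components
#'
#' Removes the excluded components and renormalizes the remaining weights.
#' If exclusion would leave nothing, the main component alone (weight 1) is
#' used. With a single fitted component its mean and standard deviation
#' define the null unchanged.
#'
#' @param fit a `mixture_fit`.
#' @param excluded integer vector of component indices to drop.
#' @return an object of class `null_model`: list with `means`, `sds`,
#'   `weights` (summing to 1) and `retained` (original component indices).
#' @export
build_null <- function(fit, excluded = integer(0)) {
  stopifnot(inherits(fit, "mixture_fit"))
  retained <- setdiff(seq_len(fit$K), excluded)
  if (length(retained) == 0L) retained <- main_component(fit)
  w <- fit$weights[retained]
  structure(list(
    means = fit$means[retained],
    sds = fit$sds[retained],
    weights = w / sum(w),
    retained = as.integer(retained)
  ), class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("Null model: %d component(s)\n", length(x$weights)))
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds))
  invisible(x)
}

#' One detection step for a single gene
#'
#' Fits a BIC-selected mixture to the gene's values outside
#' `exclude_conditions`, flags outlier components, builds the null, and
#' computes two-sided mixture-tail p-values for all conditions of the
#' profile against that null. Provisional outlier conditions are those with
#' unadjusted two-sided p below `alpha`, together with all conditions
#' hard-assigned to an excluded component.
#'
#' @param x numeric vector of a gene's log2 expression values.
#' @param params a [step_params()] object.
#' @param exclude_conditions integer indices left out of the fit (must leave
#'   at least 2 values).
#' @param alpha provisional (unadjusted) p-value threshold.
#' @param seed integer seed for the mixture fit.
#' @return a list with `fit`, `null`, `excluded_components`,
#'   `provisional_outliers` (condition indices), `p_up`, `p_down`, `p_two`,
#'   `direction`.
#' @export
detect_step <- function(x, params, exclude_conditions = integer(0),
                        alpha = 0.05, seed = 1L) {
  stopifnot(inherits(params, "step_params"))
  x <- as.numeric(x)
  m <- length(x)
  exclude_conditions <- as.integer(exclude_conditions)
  if (length(exclude_conditions) &&
      (any(exclude_conditions < 1L) || any(exclude_conditions > m))) {
    stop_validation("exclude_conditions out of range")
  }
  keep <- setdiff(seq_len(m), exclude_conditions)
  if (length(keep) < 2L) {
    stop_degenerate("excluding %d of %d conditions leaves fewer than 2 values",
                    length(exclude_conditions), m)
  }
  fit <- select_mixture_model(x[keep], Kmax = params$kmax,
                              lambda = params$lambda, beta = params$beta,
                              seed = seed)
  excl <- flag_outlier_components(fit, params)
  null <- build_null(fit, excl)
  tails <- mixture_tail_p(null, x)
  ts <- two_sided_call(tails$p_up, tails$p_down)
  assigned_excl <- keep[fit$assignments %in% excl]
  provisional <- sort(union(which(ts$p_two < alpha), assigned_excl))
  list(fit = fit, null = null, excluded_components = excl,
       provisional_outliers = as.integer(provisional),
       p_up = tails$p_up, p_down = tails$p_down,
       p_two = ts$p_two, direction = ts$direction)
}

#' Two-step detection for a single gene
#'
#' Step 1 screens the full profile (by default with a strong variance prior,
#' `beta = 6`) and marks provisional outlier conditions. Step 2 refits the
#' mixture without those conditions (by default with `beta = 0`) to obtain a
#' refined null; the final p-values and directions for all conditions come
#' from the step-2 null. If step 1 leaves too few conditions for a second
#' fit, the step-1 result is used as final (logged).
#'
#' `alpha` is the per-gene family-wise rate of provisional exclusions: the
#' per-condition threshold passed to [detect_step()] is
#' `alpha / length(x)` (Bonferroni over the gene's conditions). Excluding a
#' condition from the step-2 fit and then testing it against that fit is a
#' leave-one-out outlier test, so spurious exclusions of the sample extreme
#' must be rare for the final p-values to be honest.
#'
#' @inheritParams detect_step
#' @param step1,step2 [step_params()] for the two passes.
#' @param alpha per-gene family-wise provisional exclusion rate.
#' @return a list with `null` (final), `p_up`, `p_down`, `p_two`,
#'   `direction`, and the per-step results `step1`, `step2` (`step2` is
#'   `NULL` when the fallback was taken).
#' @export
run_two_step <- function(x, step1 = step_params(beta = 6, kmax = 1),
                         step2 = step_params(per = 0.2, beta = 0),
                         alpha = 0.05, seed = 1L, max_screen_iter = 5L) {
  m <- length(x)
  alpha_cond <- alpha / m
  # Robust pre-screen: a spike inflates the very variance estimate it is
  # tested against (and the step-1 variance prior widens it further for
  # low-variance genes), so blatant outliers are first flagged on the
  # median/robust-sd scale, which neither effect contaminates. The screen is
  # iterative (peel, re-estimate, repeat), and its flags are only trusted
  # when they form a small set (at most per1 of the conditions): a large
  # flagged set signals multi-bulk background structure, which the robust
  # scale cannot tell from contamination and which is left to the mixture
  # fit. The cut is the Bonferroni normal quantile times a finite-sample
  # factor correcting for the sampling noise of the MAD itself.
  excl <- robust_screen(x, cut = SCREEN_CAL * stats::qnorm(1 - alpha_cond / 2),
                        cap = floor(step1$per * m) + 1L)
  # Iterate the screening pass to a fixpoint: several simultaneous spikes
  # can still mask one another in the fitted null, so exclusions are
  # peeled off in rounds until no new condition is flagged.
  s1 <- NULL
  for (it in seq_len(max_screen_iter)) {
    s1_try <- tryCatch(
      detect_step(x, step1, exclude_conditions = excl,
                  alpha = alpha_cond, seed = seed),
      condspec_degenerate_error = function(e) NULL
    )
    if (is.null(s1_try)) break
    s1 <- s1_try
    new_excl <- sort(union(excl, s1$provisional_outliers))
    if (length(new_excl) == length(excl) || length(new_excl) > m / 2) break
    excl <- new_excl
  }
  if (is.null(s1)) {
    stop_degenerate("screening pass infeasible for profile of length %d", m)
  }
  s1$provisional_outliers <- excl
  s2 <- tryCatch(
    detect_step(x, step2, exclude_conditions = excl,
                alpha = alpha_cond, seed = seed),
    condspec_degenerate_error = function(e) {
      condspec_log("step 2 fit infeasible (%s); using step-1 result",
                   conditionMessage(e))
      NULL
    }
  )
  final <- if (is.null(s2)) s1 else s2
  list(null = final$null,
       p_up = final$p_up, p_down = final$p_down,
       p_two = final$p_two, direction = final$direction,
       step1 = s1, step2 = s2)
}
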