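# Synthetic expression matrices with known condition-specific spikes, and
# scoring of detector output against that truth.

#' Simulation configuration
#'
#' Describes a synthetic genes x conditions log2 expression dataset: each
#' gene has a Gaussian background (mean ~ Uniform(4, 12), sd ~
#' Uniform(0.2, 1.0) log2 units) or a skewed two-bulk background (a
#' secondary bulk shifted by `bulk_shift` carrying `bulk_weight` of the
#' conditions); a controlled fraction of genes receives 1-3 spiked
#' conditions shifted by `delta` background-sds up or down.
#'
#' @param n_genes,n_conditions matrix dimensions (default 32 conditions,
#'   the scale of a major-tissue panel).
#' @param spec_fraction fraction of genes given spikes, in \[0, 1\].
#' @param spikes_min,spikes_max range of spiked conditions per specific gene
#'   (must stay below `n_conditions / 2`).
#' @param delta spike effect size in units of the gene's background sd.
#' @param down_fraction fraction of spikes that are negative (repression).
#' @param background `"gaussian"` for a single bulk, `"skewed"` for the
#'   two-bulk background that breaks single-Gaussian null assumptions.
#' @param bulk_shift,bulk_weight location (log2 units above the main bulk)
#'   and expected condition fraction of the secondary bulk.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, n_conditions = 32L,
                       spec_fraction = 0.05, spikes_min = 1L, spikes_max = 3L,
                       delta = 6, down_fraction = 0.1,
                       background = c("gaussian", "skewed"),
                       bulk_shift = 2, bulk_weight = 0.3, seed = 1L) {
  background <- match.arg(background)
  if (n_genes < 1L || n_conditions < 4L) {
    stop_validation("need at least 1 gene and 4 conditions")
  }
  if (spec_fraction < 0 || spec_fraction > 1) {
    stop_validation("spec_fraction must be in [0, 1]")
  }
  if (delta < 0) stop_validation("delta must be nonnegative")
  if (spikes_min < 1L || spikes_max < spikes_min) {
    stop_validation("invalid spikes_min/spikes_max")
  }
  if (spikes_max >= n_conditions / 2) {
    stop_validation("spikes_max must be below n_conditions / 2")
  }
  if (down_fraction < 0 || down_fraction > 1) {
    stop_validation("down_fraction must be in [0, 1]")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_conditions = as.integer(n_conditions),
                 spec_fraction = spec_fraction,
                 spikes_min = as.integer(spikes_min),
                 spikes_max = as.integer(spikes_max),
                 delta = delta, down_fraction = down_fraction,
                 background = background,
                 bulk_shift = bulk_shift, bulk_weight = bulk_weight,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic expression dataset with known truth
#'
#' Draws per-gene backgrounds, selects exactly
#' `round(n_genes * spec_fraction)` genes to spike, and shifts the chosen
#' cells by `+/- delta * sd_g`. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (genes x conditions, named) and `truth`, a
#'   data.frame with one row per spike: `gene`, `condition`, `direction`
#'   (`+1`/`-1`) and `delta`.
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes; nc <- config$n_conditions
  gene_ids <- sprintf("gene_%05d", seq_len(ng))
  cond_ids <- sprintf("cond_%02d", seq_len(nc))
  with_seed(config$seed, {
    mu_g <- stats::runif(ng, 4, 12)
    sd_g <- stats::runif(ng, 0.2, 1.0)
    mat <- matrix(stats::rnorm(ng * nc, mean = rep(mu_g, nc),
                               sd = rep(sd_g, nc)),
                  nrow = ng, ncol = nc,
                  dimnames = list(gene_ids, cond_ids))
    if (config$background == "skewed") {
      shifted <- matrix(stats::runif(ng * nc) < config$bulk_weight, ng, nc)
      mat <- mat + shifted * config$bulk_shift
    }
    n_spec <- round(ng * config$spec_fraction)
    truth <- data.frame(gene = character(0), condition = character(0),
                        direction = integer(0), delta = numeric(0))
    if (n_spec > 0) {
      spec_genes <- sort(sample.int(ng, n_spec))
      rows <- list()
      for (g in spec_genes) {
        k <- sample(seq(config$spikes_min, config$spikes_max), 1L)
        conds <- sample.int(nc, k)
        dir <- ifelse(stats::runif(k) < config$down_fraction, -1L, 1L)
        mat[g, conds] <- mat[g, conds] + dir * config$delta * sd_g[g]
        rows[[length(rows) + 1L]] <-
          data.frame(gene = gene_ids[g], condition = cond_ids[conds],
                     direction = dir, delta = config$delta)
      }
      truth <- do.call(rbind, rows)
      rownames(truth) <- NULL
    }
    list(matrix = mat, truth = truth, config = config)
  })
}

#' Score detector output against a synthetic truth
#'
#' Gene level: a true positive is a flagged gene with at least one truth
#' spike; a false positive is a flagged background gene. Condition level: a
#' predicted call counts as correct only when gene, condition AND direction
#' match a truth spike. A ROC over a grid of adjusted-p thresholds and the
#' partial AUC up to 5% gene-level false-positive rate are also reported.
#'
#' @param result a `specificity_result` covering the same genes/conditions.
#' @param truth the `truth` data.frame from [simulate_expression()].
#' @param thresholds decreasing grid of pv thresholds for the ROC.
#' @return an object of class `eval_report`: list with `gene_sensitivity`,
#'   `gene_fp_rate`, `condition_precision`, `condition_recall`, `roc`
#'   (data.frame `threshold`, `fpr`, `tpr`) and `pauc_5fp`.
#' @export
evaluate_calls <- function(result, truth,
                           thresholds = c(10^seq(-12, -1, by = 0.5), 0.05,
                                          0.1, 0.2, 0.5, 1)) {
  stopifnot(inherits(result, "specificity_result"))
  genes <- rownames(result$call)
  if (nrow(truth) > 0 && !all(truth$gene %in% genes)) {
    stop_validation("truth contains genes absent from the result")
  }
  truth_genes <- unique(truth$gene)
  bg_genes <- setdiff(genes, truth_genes)
  flagged <- genes[result$specific]
  tp <- sum(flagged %in% truth_genes)
  fp <- sum(flagged %in% bg_genes)
  gene_sens <- if (length(truth_genes)) tp / length(truth_genes) else NA_real_
  gene_fpr <- if (length(bg_genes)) fp / length(bg_genes) else NA_real_

  key <- function(g, cond, d) paste(g, cond, d, sep = "\r")
  truth_keys <- if (nrow(truth)) {
    key(truth$gene, truth$condition, truth$direction)
  } else character(0)
  idx <- which(result$call != 0L, arr.ind = TRUE)
  pred_keys <- key(genes[idx[, 1L]], colnames(result$call)[idx[, 2L]],
                   result$call[idx])
  cond_prec <- if (length(pred_keys)) {
    mean(pred_keys %in% truth_keys)
  } else NA_real_
  cond_rec <- if (length(truth_keys)) {
    mean(truth_keys %in% pred_keys)
  } else NA_real_

  thresholds <- sort(unique(thresholds))
  adj <- result$adjusted_p
  roc <- t(vapply(thresholds, function(t) {
    hit <- rowSums(!is.na(adj) & adj < t) > 0
    c(fpr = if (length(bg_genes)) {
        sum(hit[genes %in% bg_genes]) / length(bg_genes)
      } else NA_real_,
      tpr = if (length(truth_genes)) {
        sum(hit[genes %in% truth_genes]) / length(truth_genes)
      } else NA_real_)
  }, numeric(2)))
  roc <- data.frame(threshold = thresholds, fpr = roc[, "fpr"],
                    tpr = roc[, "tpr"])

  pauc <- NA_real_
  if (all(is.finite(roc$fpr)) && all(is.finite(roc$tpr))) {
    xs <- c(0, roc$fpr, 1); ys <- c(0, roc$tpr, 1)
    keep <- xs <= 0.05
    xs2 <- c(xs[keep], 0.05)
    ys2 <- c(ys[keep], max(ys[keep]))
    o <- order(xs2, ys2)
    xs2 <- xs2[o]; ys2 <- ys2[o]
    pauc <- sum(diff(xs2) * (utils::head(ys2, -1) + utils::tail(ys2, -1)) / 2)
  }
  structure(list(gene_sensitivity = gene_sens, gene_fp_rate = gene_fpr,
                 condition_precision = cond_prec, condition_recall = cond_rec,
                 roc = roc, pauc_5fp = pauc,
                 n_truth_genes = length(truth_genes),
                 n_background_genes = length(bg_genes)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("Evaluation: gene sensitivity %.3f, gene FP rate %.4f\n",
                     "  condition precision %.3f, recall %.3f ",
                     "(%d truth genes, %d background)\n"),
              x$gene_sensitivity, x$gene_fp_rate,
              x$condition_precision, x$condition_recall,
              x$n_truth_genes, x$n_background_genes))
  invisible(x)
}
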