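# Reading expression matrices and writing result artifacts.

#' Read a genes x conditions expression table
#'
#' Expects tab-delimited UTF-8 text with a header row of condition names and
#' a first column of gene identifiers; comma-delimited files are
#' auto-detected from the header line. Values must be numeric, log2 scale.
#'
#' @param path file path.
#' @param strict if `TRUE` (default) a missing value is an error naming the
#'   offending gene and condition; if `FALSE` rows with missing values are
#'   dropped with a logged warning.
#' @return numeric matrix with gene rownames and condition colnames.
#' @export
read_expression <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_validation("input file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (!grepl("\t", header, fixed = TRUE) &&
             grepl(",", header, fixed = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 3L) stop_validation("need a gene-id column and >= 2 conditions")
  gene_ids <- df[[1L]]
  cond_ids <- colnames(df)[-1L]
  if (anyDuplicated(gene_ids)) {
    stop_validation("duplicate gene identifier(s): %s",
                    paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 3L),
                          collapse = ", "))
  }
  if (anyDuplicated(cond_ids)) stop_validation("duplicate condition names")
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  dimnames(vals) <- list(gene_ids, cond_ids)
  bad <- is.na(vals)
  if (any(bad)) {
    # distinguish truly non-numeric tokens from NA/blank cells
    raw <- as.matrix(df[-1L])
    nonnum <- bad & !(raw %in% c("NA", "", "NaN") | is.na(raw))
    if (any(nonnum)) {
      w <- which(nonnum, arr.ind = TRUE)[1L, ]
      stop_validation("non-numeric value '%s' at gene '%s', condition '%s'",
                      raw[nonnum][1L], gene_ids[w[1L]], cond_ids[w[2L]])
    }
    if (strict) {
      w <- which(bad, arr.ind = TRUE)[1L, ]
      stop_validation("missing value at gene '%s', condition '%s'",
                      gene_ids[w[1L]], cond_ids[w[2L]])
    }
    drop <- unique(which(bad, arr.ind = TRUE)[, 1L])
    condspec_log("dropping %d row(s) with missing values (permissive mode)",
                 length(drop))
    warning(sprintf("dropped %d row(s) with missing values", length(drop)))
    vals <- vals[-drop, , drop = FALSE]
  }
  validate_expression(vals)
}

#' Write an expression matrix as tab-delimited text
#'
#' @param mat genes x conditions matrix.
#' @param path output file path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt_p <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.16e", p))
}

#' Write all result artifacts for a detection run
#'
#' Emits, under `out_dir`:
#' \itemize{
#'   \item `specificity_matrix.tsv` — genes x conditions coded
#'     `1` (specifically expressed), `-1` (specifically repressed), `0`;
#'   \item `pvalues_long.tsv` — one row per gene x condition with raw and
#'     adjusted p-values (full double precision), direction and call;
#'   \item `fits.json` — per gene: selected K, component parameters,
#'     excluded components and null for both steps;
#'   \item `config.json` — the full parameter set and seed;
#'   \item `run.log` — messages collected during the run.
#' }
#' Outputs are a pure function of (input, parameters, seed): the TSV files
#' are byte-identical across re-runs with the same seed.
#'
#' @param result a `specificity_result` from [detect_specific()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named character vector of written paths.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "specificity_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_validation("cannot create out_dir: %s", out_dir)
  paths <- c(
    specificity_matrix = file.path(out_dir, "specificity_matrix.tsv"),
    pvalues_long = file.path(out_dir, "pvalues_long.tsv"),
    fits = file.path(out_dir, "fits.json"),
    config = file.path(out_dir, "config.json"),
    log = file.path(out_dir, "run.log")
  )

  sm <- data.frame(gene_id = rownames(result$call), result$call,
                   check.names = FALSE)
  utils::write.table(sm, paths[["specificity_matrix"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  genes <- rownames(result$call); conds <- colnames(result$call)
  long <- data.frame(
    gene = rep(genes, times = length(conds)),
    condition = rep(conds, each = length(genes)),
    raw_p = fmt_p(as.vector(result$raw_p)),
    adjusted_p = fmt_p(as.vector(result$adjusted_p)),
    direction = as.vector(result$direction),
    call = as.vector(result$call)
  )
  long <- long[order(long$gene, long$condition), ]
  utils::write.table(long, paths[["pvalues_long"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  jsonlite::write_json(result$fits, paths[["fits"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  cfg <- list(params = unclass_deep(result$params), pv = result$pv,
              seed = result$seed,
              n_genes = length(genes), n_conditions = length(conds))
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  writeLines(c(sprintf("condspec run: %d genes x %d conditions, seed %d",
                       length(genes), length(conds), result$seed),
               result$log), paths[["log"]])
  invisible(paths)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Reconstruct null models from a fits.json file
#'
#' Re-reads the serialized per-gene null models so their p-values can be
#' recomputed without re-fitting.
#'
#' @param path path to a `fits.json` written by [write_results()].
#' @return named list of `null_model` objects (NULL for failed genes).
#' @export
read_fits <- function(path) {
  fits <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  lapply(fits, function(f) {
    if (isTRUE(f$failed)) return(NULL)
    structure(list(means = as.numeric(f$null$means),
                   sds = as.numeric(f$null$sds),
                   weights = as.numeric(f$null$weights),
                   retained = as.integer(f$null$retained)),
              class = "null_model")
  })
}
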