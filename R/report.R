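# Self-contained HTML summary of a detection run: parameter table, counts
# of specific genes per number of conditions, per-condition up/down/total
# table, clustered specificity heatmap, and the specific-gene table.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, caption = NULL) {
  head <- paste0("<tr>", paste0("<th>", html_escape(colnames(df)), "</th>",
                                collapse = ""), "</tr>")
  rows <- apply(df, 1L, function(r) {
    paste0("<tr>", paste0("<td>", html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>")
  })
  paste0("<table>",
         if (!is.null(caption)) paste0("<caption>", caption, "</caption>"),
         head, paste(rows, collapse = "\n"), "</table>")
}

# Render a plot expression to a base64 <img>; NULL when no png device works.
plot_to_img <- function(expr, width = 760, height = 420) {
  tmp <- tempfile(fileext = ".png")
  on.exit(unlink(tmp), add = TRUE)
  ok <- tryCatch({
    grDevices::png(tmp, width = width, height = height)
    dev_open <- TRUE
    tryCatch(eval.parent(substitute(expr)),
             finally = grDevices::dev.off())
    TRUE
  }, error = function(e) {
    condspec_log("figure rendering failed: %s", conditionMessage(e))
    FALSE
  })
  if (!ok || !file.exists(tmp)) return(NULL)
  b64 <- jsonlite::base64_enc(readBin(tmp, "raw", file.info(tmp)$size))
  sprintf('<img src="data:image/png;base64,%s" />', gsub("\n", "", b64))
}

#' Render a single-page HTML summary of a detection run
#'
#' Writes a self-contained `summary.html` with the parameter table, a bar
#' chart of genes by number of specific conditions, a per-condition
#' up/down/total table and bar chart, a clustered heatmap of the
#' specificity matrix (blue = up, red = down, light grey = not specific;
#' omitted, with a note, above 5,000 specific genes), and the table of
#' specific genes. Figure rendering failures degrade to tables-only with a
#' logged warning.
#'
#' @param result a `specificity_result` from [detect_specific()].
#' @param out_dir output directory.
#' @return the path to the written HTML file.
#' @export
render_summary_html <- function(result, out_dir) {
  stopifnot(inherits(result, "specificity_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cc <- condition_counts(result)
  n_spec_conds <- rowSums(result$call != 0L)
  spec_tab <- table(factor(n_spec_conds[n_spec_conds > 0],
                           levels = seq_len(max(1, max(n_spec_conds)))))
  params <- result$params
  ptab <- data.frame(
    parameter = c("pv", "correction", "alpha",
                  "step1: per", "step1: md", "step1: mlk", "step1: rsd",
                  "step1: lambda", "step1: beta",
                  "step2: per", "step2: md", "step2: mlk", "step2: rsd",
                  "step2: lambda", "step2: beta", "seed"),
    value = c(params$pv, params$correction, params$alpha,
              params$step1$per, params$step1$md, params$step1$mlk,
              params$step1$rsd, params$step1$lambda, params$step1$beta,
              params$step2$per, params$step2$md, params$step2$mlk,
              params$step2$rsd, params$step2$lambda, params$step2$beta,
              result$seed))

  parts <- character(0)
  parts <- c(parts, "<h1>Condition-specific expression summary</h1>")
  parts <- c(parts, sprintf(
    "<p>%d genes &times; %d conditions; %d specific genes (%d up calls, %d down calls) at adjusted p &lt; %g.</p>",
    nrow(result$call), ncol(result$call), sum(result$specific),
    sum(result$call == 1L), sum(result$call == -1L), result$pv))
  parts <- c(parts, html_table(ptab, "Parameters"))

  dist_df <- data.frame(`specific conditions` = names(spec_tab),
                        genes = as.integer(spec_tab), check.names = FALSE)
  parts <- c(parts, "<h2>Genes by number of specific conditions</h2>",
             html_table(dist_df))
  img1 <- plot_to_img(graphics::barplot(as.integer(spec_tab),
                                        names.arg = names(spec_tab),
                                        xlab = "number of specific conditions",
                                        ylab = "genes", col = "steelblue"))
  if (!is.null(img1)) parts <- c(parts, img1)

  parts <- c(parts, "<h2>Specific genes per condition</h2>", html_table(cc))
  img2 <- plot_to_img({
    h <- rbind(up = cc$up, down = cc$down)
    graphics::barplot(h, names.arg = cc$condition, las = 2,
                      col = c("steelblue", "firebrick"),
                      legend.text = c("up", "down"),
                      ylab = "specific genes", cex.names = 0.6)
  })
  if (!is.null(img2)) parts <- c(parts, img2)

  parts <- c(parts, "<h2>Specificity heatmap</h2>")
  spec_idx <- which(result$specific)
  if (length(spec_idx) == 0L) {
    parts <- c(parts, "<p>No specific genes; heatmap omitted.</p>")
  } else if (length(spec_idx) > 5000L) {
    parts <- c(parts, sprintf(
      "<p>%d specific genes exceed the 5,000-gene heatmap limit; heatmap omitted.</p>",
      length(spec_idx)))
  } else {
    m <- result$call[spec_idx, , drop = FALSE]
    if (nrow(m) > 2L) {
      ord <- stats::hclust(stats::dist(m, method = "manhattan"))$order
      m <- m[ord, , drop = FALSE]
    }
    img3 <- plot_to_img({
      graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                      col = c("firebrick", "grey90", "steelblue"),
                      breaks = c(-1.5, -0.5, 0.5, 1.5),
                      axes = FALSE, xlab = "conditions", ylab = "genes")
      graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                     labels = colnames(m), las = 2, cex.axis = 0.6)
    }, height = 560)
    if (is.null(img3)) {
      parts <- c(parts, "<p>Heatmap rendering unavailable; see tables.</p>")
    } else {
      parts <- c(parts,
                 "<p>Blue = specifically expressed, red = specifically repressed, grey = not specific.</p>",
                 img3)
    }
  }

  parts <- c(parts, "<h2>Specific genes</h2>")
  if (length(spec_idx)) {
    gl <- data.frame(
      gene = rownames(result$call)[spec_idx],
      n_up = rowSums(result$call[spec_idx, , drop = FALSE] == 1L),
      n_down = rowSums(result$call[spec_idx, , drop = FALSE] == -1L),
      conditions = vapply(spec_idx, function(i) {
        sc <- result$specific_conditions[[i]]
        paste(sprintf("%s(%s)", names(sc), ifelse(sc > 0, "up", "down")),
              collapse = ", ")
      }, character(1)))
    parts <- c(parts, html_table(gl))
  } else {
    parts <- c(parts, "<p>None.</p>")
  }

  page <- paste0(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    "<title>condspec summary</title><style>",
    "body{font-family:sans-serif;margin:2em;}",
    "table{border-collapse:collapse;margin:1em 0;}",
    "td,th{border:1px solid #999;padding:2px 8px;font-size:90%;}",
    "caption{font-weight:bold;text-align:left;}",
    "</style></head><body>",
    paste(parts, collapse = "\n"),
    "</body></html>")
  path <- file.path(out_dir, "summary.html")
  writeLines(page, path)
  path
}
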