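#' @importFrom rlang .data
NULL

#' Summarize interface metrics by class
#'
#' Groups a quantification table by interaction class and orientation class
#' and reports n, mean and SD of each metric. Moran's I summaries use only
#' the interfaces where the statistic is defined (their count is reported
#' as \code{n_morans_I}). SD is NA for singleton groups.
#'
#' @param table data.frame from \code{\link{quantifySample}} (or several
#'   samples row-bound together).
#' @param metrics metric columns to summarize.
#' @return data.frame, one row per (interaction_class, orientation_class).
#' @export
summarizeClasses <- function(table,
                             metrics = c("pct_total_signal",
                                         "pct_signal_density", "area_um2",
                                         "morans_I")) {
  stopifnot(is.data.frame(table), nrow(table) > 0,
            all(c("interaction_class", "orientation_class") %in%
                  names(table)))
  metrics <- intersect(metrics, names(table))
  key <- interaction(table$interaction_class, table$orientation_class,
                     drop = TRUE, sep = "|")
  groups <- levels(key)
  out <- do.call(rbind, lapply(groups, function(g) {
    rows <- table[key == g, , drop = FALSE]
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    res <- data.frame(interaction_class = parts[1],
                      orientation_class = parts[2], n = nrow(rows))
    for (m in metrics) {
      v <- rows[[m]][!is.na(rows[[m]])]
      res[[paste0("mean_", m)]] <- if (length(v)) mean(v) else NA_real_
      res[[paste0("sd_", m)]] <- if (length(v) > 1) stats::sd(v) else
        NA_real_
      if (m == "morans_I") res$n_morans_I <- length(v)
    }
    res
  }))
  rownames(out) <- NULL
  out
}

#' Significance stars for a p value
#'
#' The star ladder used in the figure annotations: p < 0.001 gives "***",
#' p < 0.005 "**", p < 0.01 "*", otherwise "".
#'
#' @param p p value(s).
#' @return character vector of stars.
#' @export
starsForP <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.005, "**",
                                  ifelse(p < 0.01, "*", "")))
}

#' Compare two groups of samples per interface class
#'
#' Welch's two-sample two-sided t-test of the chosen metric per
#' (interaction_class, orientation_class) cell, each interface counting as
#' one observation. Classes missing from either group, or with fewer than
#' 2 defined values in either group, are skipped with a warning.
#'
#' @param a,b quantification tables for the two conditions.
#' @param metric metric column to compare.
#' @return data.frame with class keys, group means, t statistic, p value
#'   and stars.
#' @export
compareGroups <- function(a, b, metric = "pct_total_signal") {
  stopifnot(metric %in% names(a), metric %in% names(b))
  keyOf <- function(d) paste(d$interaction_class, d$orientation_class,
                             sep = "|")
  ka <- keyOf(a); kb <- keyOf(b)
  common <- intersect(unique(ka), unique(kb))
  skipped <- setdiff(union(unique(ka), unique(kb)), common)
  if (length(skipped))
    warning("classes missing from one group, skipped: ",
            paste(skipped, collapse = "; "))
  rows <- list()
  for (g in common) {
    va <- a[[metric]][ka == g]; va <- va[!is.na(va)]
    vb <- b[[metric]][kb == g]; vb <- vb[!is.na(vb)]
    if (length(va) < 2 || length(vb) < 2) {
      warning("fewer than 2 observations in a group for class ", g,
              "; skipped")
      next
    }
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    tt <- stats::t.test(va, vb, var.equal = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      interaction_class = parts[1], orientation_class = parts[2],
      metric = metric, n_a = length(va), n_b = length(vb),
      mean_a = mean(va), mean_b = mean(vb),
      t = unname(tt$statistic), p = tt$p.value,
      stars = starsForP(tt$p.value))
  }
  if (length(rows) == 0)
    return(data.frame(interaction_class = character(),
                      orientation_class = character(), metric = character(),
                      n_a = integer(), n_b = integer(), mean_a = numeric(),
                      mean_b = numeric(), t = numeric(), p = numeric(),
                      stars = character()))
  out <- do.call(rbind, rows)
  out[order(out$interaction_class, out$orientation_class), ]
}

#' Export summary tables and figures
#'
#' Writes the class summaries (and comparisons, when given) as CSV and one
#' bar chart per metric with SD error bars and star annotations.
#' Deterministic file naming; re-running on identical input reproduces
#' identical CSVs.
#'
#' @param summaries data.frame from \code{\link{summarizeClasses}}.
#' @param comparisons data.frame from \code{\link{compareGroups}}, or NULL.
#' @param outDir output directory (created if needed).
#' @param metrics metrics to plot (must have mean_/sd_ columns in
#'   \code{summaries}).
#' @return invisible character vector of the files written.
#' @export
exportReport <- function(summaries, comparisons = NULL, outDir,
                         metrics = c("pct_total_signal",
                                     "pct_signal_density")) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outDir)
  if (file.access(outDir, 2) != 0) stop("output directory not writable")
  files <- character(0)
  f <- file.path(outDir, "class_summary.csv")
  utils::write.csv(summaries, f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(comparisons) && nrow(comparisons) > 0) {
    f <- file.path(outDir, "group_comparisons.csv")
    utils::write.csv(comparisons, f, row.names = FALSE)
    files <- c(files, f)
  }
  for (m in metrics) {
    mc <- paste0("mean_", m); sc <- paste0("sd_", m)
    if (!mc %in% names(summaries)) next
    df <- summaries
    ## ASCII hyphen in plot text: the base pdf device cannot render the
    ## en dash used in interaction class names
    df$class <- gsub("\u2013", "-", paste(df$interaction_class,
                                          df$orientation_class,
                                          sep = "\n"))
    df$mean_ <- df[[mc]]
    df$sd_ <- df[[sc]]
    stars <- NULL
    if (!is.null(comparisons) && nrow(comparisons) > 0) {
      cm <- comparisons[comparisons$metric == m, , drop = FALSE]
      if (nrow(cm)) {
        cm$class <- gsub("\u2013", "-", paste(cm$interaction_class,
                                              cm$orientation_class,
                                              sep = "\n"))
        df$stars <- cm$stars[match(df$class, cm$class)]
        stars <- TRUE
      }
    }
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$class,
                                           y = .data$mean_)) +
      ggplot2::geom_col(fill = "grey70", colour = "black") +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = .data$mean_ - .data$sd_, ymax = .data$mean_ + .data$sd_),
        width = 0.25, na.rm = TRUE) +
      ggplot2::labs(x = NULL, y = m) +
      ggplot2::theme_classic() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
    if (!is.null(stars))
      gg <- gg + ggplot2::geom_text(ggplot2::aes(
        y = (.data$mean_ + ifelse(is.na(.data$sd_), 0, .data$sd_)) * 1.05,
        label = .data$stars), na.rm = TRUE)
    f <- file.path(outDir, paste0("bar_", m, ".pdf"))
    ggplot2::ggsave(f, gg, width = 6, height = 4)
    files <- c(files, f)
  }
  invisible(files)
}
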