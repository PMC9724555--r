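#' Plot a length-stratified metric report
#'
#' One panel per metric, bins on the x axis — the standard way benchmark
#' results are compared across segment lengths. Multiple reports (e.g.
#' different tools or error rates) can be overlaid by passing a named list.
#'
#' @param report A `metric_report`, or a named list of them.
#' @return A ggplot object.
#' @export
plot_metric_report <- function(report) {
  if (inherits(report, "metric_report")) report <- list(report = report)
  long <- do.call(rbind, lapply(names(report), function(nm) {
    r <- as.data.frame(report[[nm]])
    r <- r[r$bin != "all", ]
    out <- lapply(c("accuracy", "length_accuracy", "length_discrepancy_cm",
                    "recall", "power", "accumulative_power"), function(mt) {
      data.frame(set = nm, bin = r$bin, metric = mt, value = r[[mt]])
    })
    do.call(rbind, out)
  }))
  long$bin <- factor(long$bin, levels = unique(long$bin))
  ggplot2::ggplot(long, ggplot2::aes(x = bin, y = value, group = set,
                                     colour = set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "segment length bin (cM)", y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   legend.position = if (length(report) > 1) "bottom" else "none")
}

#' Plot IBD coverage profiles along the chromosome
#'
#' @param profiles Named list of `coverage_profile` objects (e.g.
#'   `list(truth = ..., toolX = ...)`).
#' @return A ggplot object.
#' @export
plot_coverage <- function(profiles) {
  if (inherits(profiles, "coverage_profile")) profiles <- list(coverage = profiles)
  long <- do.call(rbind, lapply(names(profiles), function(nm) {
    data.frame(set = nm, pos_bp = profiles[[nm]]$pos_bp,
               count = profiles[[nm]]$count)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = pos_bp, y = count, colour = set)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "position (bp)", y = "IBD segments covering site") +
    ggplot2::theme_bw()
}

#' Grouped bar plot of relatedness-degree counts
#'
#' @param counts The `counts` data frame from [relatedness_table()].
#' @param drop_unrelated Omit the (typically dominant) unrelated category.
#' @return A ggplot object.
#' @export
plot_relatedness <- function(counts, drop_unrelated = TRUE) {
  df <- counts
  if (drop_unrelated) df <- df[df$degree != "unrelated", , drop = FALSE]
  long <- rbind(
    data.frame(degree = df$degree, set = "truth", n = df$n_truth),
    data.frame(degree = df$degree, set = "reported", n = df$n_reported)
  )
  long$degree <- factor(long$degree, levels = unique(df$degree))
  ggplot2::ggplot(long, ggplot2::aes(x = degree, y = n, fill = set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "degree of relatedness", y = "individual pairs") +
    ggplot2::theme_bw()
}
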