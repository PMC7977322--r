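#' Plot genetic trends and their path partitions
#'
#' Draws, for each trait, the overall genetic trend (`Sum`, black) and
#' one partial-trend line per selection path against the grouping
#' variable of the summary. With a single path the overall trend and
#' the partition coincide by construction.
#'
#' @param x a `bv_partition_summary`.
#' @param ... ignored.
#' @return A `trend_plots` object: a named list with one ggplot per
#'   trait. Printing it prints each plot; [save_trend_plots()] writes
#'   them to files.
#' @export
plot.bv_partition_summary <- function(x, ...) {
  if (any(vapply(x$info$lT, function(tr) nrow(x[[tr]]) == 0L, logical(1L)))) {
    stop("cannot plot an empty summary")
  }
  by <- x$info$by
  plots <- lapply(x$info$lT, function(tr) {
    df <- x[[tr]]
    long <- do.call(rbind, lapply(x$info$lP, function(p) {
      data.frame(key = df[[by]], Path = p, Value = df[[p]],
                 stringsAsFactors = FALSE)
    }))
    long$Path <- factor(long$Path, levels = x$info$lP)
    overall <- data.frame(key = df[[by]], Value = df$Sum)
    ggplot2::ggplot(long, ggplot2::aes(x = .data$key, y = .data$Value)) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dotted",
                          colour = "grey60") +
      ggplot2::geom_line(ggplot2::aes(colour = .data$Path,
                                      group = .data$Path)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$Path), size = 1) +
      ggplot2::geom_line(data = overall, ggplot2::aes(group = 1),
                         colour = "black", linewidth = 1) +
      ggplot2::labs(title = tr, x = by, y = tr,
                    caption = "black: overall trend; colours: path partitions") +
      ggplot2::theme_minimal()
  })
  names(plots) <- x$info$lT
  structure(plots, class = "trend_plots")
}

#' @export
print.trend_plots <- function(x, ...) {
  for (p in x) print(p)
  invisible(x)
}

#' Save trend plots to image files
#'
#' @param plots a `trend_plots` object from [plot.bv_partition_summary()].
#' @param prefix output path prefix; files are named
#'   `<prefix>.<trait>.<format>`.
#' @param format `"png"` or `"svg"`.
#' @param width,height,dpi device size in inches and resolution.
#' @return Character vector of the written file paths, invisibly.
#' @export
save_trend_plots <- function(plots, prefix, format = c("png", "svg"),
                             width = 7, height = 5, dpi = 150) {
  format <- match.arg(format)
  stopifnot(inherits(plots, "trend_plots"))
  paths <- character(0)
  for (tr in names(plots)) {
    f <- paste0(prefix, ".", tr, ".", format)
    dev <- if (format == "png") {
      function(filename, ...) grDevices::png(filename, width = width,
                                             height = height, units = "in",
                                             res = dpi, type = "cairo")
    } else {
      function(filename, ...) grDevices::svg(filename, width = width,
                                             height = height)
    }
    ggplot2::ggsave(f, plots[[tr]], device = dev, width = width,
                    height = height)
    paths <- c(paths, f)
  }
  invisible(paths)
}
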