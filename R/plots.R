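# Fit-overlay figure: data mean +/- s.d. vs model prediction per block.

#' Plot a fitted model against the AGL8 data
#'
#' Draws, for each condition block, the AGL8 data (mean with an s.d.
#' ribbon) and the model prediction at the supplied parameters, in the
#' layout used to inspect pattern defects of knockout models. Requires
#' ggplot2.
#'
#' @inheritParams cost
#' @param title Optional plot title (defaults to the model label).
#' @return A ggplot object.
#' @export
plot_fit_overlay <- function(spec, params, data, title = NULL,
                             sd_floor = 1e-6) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_fit_overlay requires the ggplot2 package")
  }
  fr <- .model_frame(spec, data, sd_floor)
  mats <- .as_matrices(data)
  df <- data.frame(
    block = factor(as.character(fr$block), levels = .BLOCKS),
    time_days = mats$points$time_days,
    data = fr$y,
    sd = mats$sd[, .TARGET],
    model = drop(fr$X %*% params[colnames(fr$X)])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data[["time_days"]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[["data"]] - .data[["sd"]],
                                      ymax = .data[["data"]] + .data[["sd"]]),
                         fill = "red", alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data[["data"]]), color = "red") +
    ggplot2::geom_point(ggplot2::aes(y = .data[["data"]]), color = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data[["model"]]), color = "black") +
    ggplot2::facet_wrap(~block, nrow = 1) +
    ggplot2::labs(x = "time (days)", y = "AGL8 relative expression",
                  title = if (is.null(title)) spec$label else title) +
    ggplot2::theme_minimal()
}
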