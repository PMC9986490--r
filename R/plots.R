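#' Plot windowed learning curves
#'
#' Windowed success-rate curves (mean with an across-trial sd ribbon when
#' several logs per condition are supplied).
#'
#' @param logs a trial log or a list of trial logs.
#' @param window moving-average window.
#' @return a ggplot object.
#' @export
plot_learning_curve <- function(logs, window = 100) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  if (is.data.frame(logs)) logs <- list(logs)
  d <- do.call(rbind, lapply(seq_along(logs), function(i) {
    l <- logs[[i]]
    data.frame(trial = i, episode = l$episode,
               curve = windowed_average(as.numeric(l$success), window),
               condition = paste0(l$kind, ", gamma=", l$gamma,
                                  ", K=", l$lag_multiplier, "K'"))
  }))
  agg <- stats::aggregate(curve ~ episode + condition, d,
                          function(x) c(m = mean(x), s = stats::sd(x)))
  agg <- cbind(agg[c("episode", "condition")], as.data.frame(agg$curve))
  agg$s[is.na(agg$s)] <- 0
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$episode, y = .data$m,
                                    colour = .data$condition,
                                    fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$m - .data$s, 0),
                                      ymax = pmin(.data$m + .data$s, 1)),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "episode", y = sprintf("success rate (window %d)",
                                             window)) +
    ggplot2::theme_minimal()
}

#' Boxplots of onset TTC by target initial speed
#'
#' The three TTC references (agent, target first-order, target actual) per
#' initial-speed group, drawn from the precomputed summaries so whisker
#' conventions match [summarize_ttc()].
#'
#' @param summary output of [summarize_ttc()].
#' @return a ggplot object.
#' @export
plot_ttc_boxes <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  types <- c("fo", "actual", "agent")
  labels <- c(fo = "target first-order", actual = "target actual",
              agent = "agent")
  d <- do.call(rbind, lapply(types, function(ty) {
    data.frame(group = factor(summary$target_init_speed),
               type = labels[[ty]],
               median = summary[[paste0(ty, "_median")]],
               q1 = summary[[paste0(ty, "_q1")]],
               q3 = summary[[paste0(ty, "_q3")]],
               lo = summary[[paste0(ty, "_lo")]],
               hi = summary[[paste0(ty, "_hi")]])
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, fill = .data$type)) +
    ggplot2::geom_boxplot(ggplot2::aes(ymin = .data$lo, lower = .data$q1,
                                       middle = .data$median,
                                       upper = .data$q3, ymax = .data$hi),
                          stat = "identity",
                          position = ggplot2::position_dodge(width = 0.8),
                          width = 0.7) +
    ggplot2::labs(x = "target initial speed (m/s)",
                  y = "TTC at speed-change onset (s)") +
    ggplot2::theme_minimal()
}
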