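# ggplot2 displays for the main result types.

#' @export
autoplot.phaseset <- function(object, ...) {
  b <- object$blocks$blocks %>%
    mutate(row = row_number() %% 2)
  ggplot(b, aes(xmin = .data$start, xmax = .data$end,
                ymin = .data$row, ymax = .data$row + 0.8,
                fill = factor(.data$row))) +
    geom_rect(show.legend = FALSE) +
    labs(x = "position (bp)", y = NULL, title = "Phase blocks") +
    theme_minimal()
}

#' @export
autoplot.coverage_profile <- function(object, bin = 1000, ...) {
  n <- length(object$C)
  idx <- seq(1, n, by = bin)
  d <- bind_rows(
    tibble(pos = idx, depth = object$C[idx], track = "reads (C)"),
    tibble(pos = idx, depth = object$C_F[idx], track = "fragments (C_F)"))
  ggplot(d, aes(.data$pos, .data$depth)) +
    geom_step() +
    facet_wrap(~ .data$track, ncol = 1, scales = "free_y") +
    labs(x = "position (bp)", y = "depth") +
    theme_minimal()
}

#' Size spectrum of called insertions and deletions
#'
#' @param calls Final-variant tibble (or `variant_calls` object).
#' @param binwidth Histogram bin width (default 10 bp).
#' @return A ggplot.
#' @export
plot_sv_sizes <- function(calls, binwidth = 10) {
  if (inherits(calls, "variant_calls")) calls <- calls$calls
  d <- calls %>% filter(.data$type %in% c("INS", "DEL"))
  ggplot(d, aes(.data$size, fill = .data$type)) +
    geom_histogram(binwidth = binwidth, position = "dodge") +
    labs(x = "SV size (bp)", y = "count", fill = NULL) +
    theme_minimal()
}

#' @export
autoplot.variant_calls <- function(object, ...) {
  plot_sv_sizes(object, ...)
}
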