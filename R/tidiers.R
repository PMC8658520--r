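#' Tidy a stress summary
#'
#' Returns the per-design peri-implant stress results as a plain tibble,
#' one row per implant design.
#'
#' @param x a `stress_summary` from [run_sweep()].
#' @param ... unused.
#' @return A tibble with columns `diameter`, `length`, `peak_vm`, `level`,
#'   `side` and `peak_principal`.
#' @export
tidy.stress_summary <- function(x, ...) {
  tibble::as_tibble(x[, c("diameter", "length", "peak_vm", "level", "side",
                          "peak_principal")])
}

#' One-row summary of a design sweep
#'
#' @param x a `stress_summary` from [run_sweep()].
#' @param ... unused.
#' @return A one-row tibble: number of designs, peak stress range (MPa),
#'   whether the peak decreases monotonically with diameter at every fixed
#'   length and is non-increasing in length at every fixed diameter, and
#'   whether every argmax lies at the implant neck.
#' @export
glance.stress_summary <- function(x, ...) {
  tibble::tibble(
    n_designs = nrow(x),
    peak_vm_min = min(x$peak_vm),
    peak_vm_max = max(x$peak_vm),
    monotone_diameter = all(vapply(split(x, x$length), function(df) {
      all(diff(df$peak_vm[order(df$diameter)]) < 0)
    }, logical(1))),
    monotone_length = all(vapply(split(x, x$diameter), function(df) {
      all(diff(df$peak_vm[order(df$length)]) <= 0)
    }, logical(1))),
    all_neck = all(x$level == "neck")
  )
}

#' Plot the peri-implant stress surface of a design sweep
#'
#' One line per implant diameter, peak peri-implant equivalent stress
#' against intrabony length.
#'
#' @param object a `stress_summary` from [run_sweep()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.stress_summary <- function(object, ...) {
  df <- tidy.stress_summary(object)
  df$diameter <- factor(sprintf("%.1f mm", df$diameter))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$peak_vm,
                                   colour = .data$diameter,
                                   group = .data$diameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "intrabony implant length (mm)",
      y = "peak peri-implant von Mises stress (MPa)",
      colour = "implant diameter",
      title = "Peri-implant stress across the implant design grid"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.stress_summary <- function(x, ...) print(autoplot.stress_summary(x))
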