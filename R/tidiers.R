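# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pulling run
#'
#' One row per sampling point: time, brush Rg and shape factor, membrane-mean
#' P2, kinetic temperature, brush-head contact count and brush center-of-mass
#' x.
#'
#' @param x A `dpd_pull`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dpd_pull <- function(x, ...) x$series

#' One-row summary of a pulling run
#'
#' Protocol settings, landmark times, termination reason and post-transient
#' means (window `[0.2 Te, Te]`).
#'
#' @param x A `dpd_pull`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.dpd_pull <- function(x, ...) {
  tibble::tibble(
    F = x$protocol$F, abm = x$protocol$abm,
    T1 = x$landmarks$T1, T2 = x$landmarks$T2, Te = x$landmarks$Te,
    termination = x$termination,
    rg_mean = window_mean(x$series, "rg"),
    delta_mean = window_mean(x$series, "delta"),
    p2_mean = window_mean(x$series, "p2_membrane"),
    n_samples = nrow(x$series))
}

#' Tidy a force sweep
#'
#' @param x A `dpd_sweep`.
#' @param ... Unused.
#' @return The per-force results tibble.
#' @export
tidy.dpd_sweep <- function(x, ...) x$results

#' One-row summary of a force sweep
#'
#' @param x A `dpd_sweep`.
#' @param ... Unused.
#' @return A one-row tibble with the force range and trend statistics.
#' @export
glance.dpd_sweep <- function(x, ...) {
  ok <- !x$results$failed
  tibble::tibble(
    abm = x$abm, n_forces = nrow(x$results), n_failed = sum(!ok),
    F_min = min(x$results$F), F_max = max(x$results$F),
    rg_range = diff(range(x$results$rg[ok])),
    delta_range = diff(range(x$results$delta[ok])),
    p2_range = diff(range(x$results$p2_membrane[ok])))
}

#' Tidy a gyration result
#'
#' @param x A `gyration_result`.
#' @param ... Unused.
#' @return A one-row tibble: Rg, the three eigenvalues, delta.
#' @export
tidy.gyration_result <- function(x, ...) {
  tibble::tibble(rg = x$Rg, l1_sq = x$eigenvalues[1], l2_sq = x$eigenvalues[2],
                 l3_sq = x$eigenvalues[3], delta = x$delta)
}

#' Plot the observable traces of a pulling run
#'
#' Brush Rg, shape factor and membrane-mean P2 against time, faceted, with
#' detected landmark times marked.
#'
#' @param object A `dpd_pull`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dpd_pull <- function(object, ...) {
  s <- object$series
  long <- tibble::tibble(
    time = rep(s$time, 3),
    observable = rep(c("Rg (rc)", "delta", "P2 membrane"), each = nrow(s)),
    value = c(s$rg, s$delta, s$p2_membrane))
  marks <- tibble::tibble(
    time = c(object$landmarks$T1, object$landmarks$T2),
    label = c("T1", "T2"))
  marks <- marks[!is.na(marks$time), , drop = FALSE]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (tau)", y = NULL,
                  title = sprintf("Constant-force pull: F = %g, aBM = %g",
                                  object$protocol$F, object$protocol$abm))
  if (nrow(marks))
    p <- p + ggplot2::geom_vline(data = marks,
                                 ggplot2::aes(xintercept = .data$time),
                                 linetype = "dashed")
  p
}

#' Plot a force sweep
#'
#' Post-transient means of Rg, delta and membrane P2 against the pulling
#' force.
#'
#' @param object A `dpd_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dpd_sweep <- function(object, ...) {
  r <- object$results[!object$results$failed, , drop = FALSE]
  long <- tibble::tibble(
    F = rep(r$F, 3),
    observable = rep(c("Rg (rc)", "delta", "P2 membrane"), each = nrow(r)),
    value = c(r$rg, r$delta, r$p2_membrane))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$F, y = .data$value)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "pulling force (m rc / tau^2)", y = NULL,
                  title = sprintf("Force sweep at aBM = %g", object$abm))
}

#' Plot an order-parameter profile
#'
#' Per-bin membrane P2 along x; unoccupied bins are omitted.
#'
#' @param object An [order_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.order_profile <- function(object, ...) {
  d <- object[object$occupied, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_center, y = .data$p2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(-0.5, 1) +
    ggplot2::labs(x = "x (rc)", y = "P2 order parameter")
}

#' @importFrom rlang .data
NULL
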