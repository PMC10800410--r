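#' Plot an experience-sampling panel
#'
#' Spaghetti plot of the momentary variables over the study grid for a sample
#' of persons.
#'
#' @param object An `ema_panel`.
#' @param n_persons Number of persons to display (default 8).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ema_panel <- function(object, n_persons = 8, ...) {
  df <- as_tibble(object)
  ids <- utils::head(unique(df$person_id), n_persons)
  df <- df |>
    filter(.data$person_id %in% ids) |>
    mutate(occasion = 4L * .data$day + slot_offset(.data$slot)) |>
    tidyr::pivot_longer(c("stress", "na", "pa"),
                        names_to = "variable", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$occasion, .data$value,
                                   group = .data$person_id,
                                   colour = .data$person_id)) +
    ggplot2::geom_line(alpha = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "grid index (6-hour units)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a fitted model
#'
#' `type = "intervals"` shows posterior medians and 95% credible intervals of
#' the 16 between-level coefficients; `type = "trace"` shows per-chain trace
#' plots of selected parameters.
#'
#' @param object A `dsem_fit`.
#' @param type `"intervals"` or `"trace"`.
#' @param pars Parameters for the trace plot (default a representative set).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dsem_fit <- function(object, type = c("intervals", "trace"),
                              pars = c("gamma00", "gamma10", "gamma03",
                                       "sigma2_e"), ...) {
  type <- match.arg(type)
  if (type == "intervals") {
    s <- summarize_posterior(object) |>
      filter(.data$term %in% gamma_names()) |>
      mutate(term = factor(.data$term, levels = rev(gamma_names())))
    return(
      ggplot2::ggplot(s, ggplot2::aes(.data$median, .data$term)) +
        ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
        ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                              xmax = .data$upper)) +
        ggplot2::labs(x = "posterior median (95% CI)", y = NULL) +
        ggplot2::theme_minimal()
    )
  }
  tr <- purrr::imap(object$draws, function(m, i) {
    tibble(chain = factor(i), iteration = seq_len(nrow(m)),
           as_tibble(m[, pars, drop = FALSE]))
  }) |>
    bind_rows() |>
    tidyr::pivot_longer(all_of(pars), names_to = "term",
                        values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(.data$iteration, .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::theme_minimal()
}
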