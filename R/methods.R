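# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.comparison_report <- function(x, ...) {
  rows <- tibble::tibble(
    metric = c("freq_r2", "retained_fraction", "bigram_r2_within",
               "bigram_r2_sequential", "max_abs_corr_diff"),
    value = c(x$freq_r2, x$retained_fraction, x$bigram_r2_within,
              x$bigram_r2_sequential, x$correlation$max_abs_diff))
  if (!is.null(x$temporal))
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      metric = c("acf7_real", "acf7_synth", "lag7_contrast"),
      value = c(x$temporal$acf_real[7], x$temporal$acf_synth[7],
                x$temporal$lag7_contrast)))
  rows
}

#' @export
glance.generator_model <- function(x, ...) {
  tibble::tibble(n_layers = x$config$n_layers,
                 embedding_dim = x$config$embedding_dim,
                 n_heads = x$config$n_heads,
                 vocab_size = length(x$vocab),
                 epochs_trained = nrow(x$history),
                 best_val_loss = x$best_val_loss)
}

#' @export
tidy.generator_model <- function(x, ...) {
  tibble::as_tibble(x$history)
}

#' @export
tidy.tstr_result <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -"training_data",
                      names_to = "metric", values_to = "value")
}

#' @export
glance.tstr_result <- function(x, ...) x$metrics

#' @export
tidy.kde_grid <- function(x, ...) {
  g <- x$grid
  out <- lapply(rownames(x$masses), function(s) {
    tibble::tibble(stratum = s, lo = g[-length(g)], hi = g[-1],
                   mass = x$masses[s, ])
  })
  dplyr::bind_rows(out)
}

#' @export
autoplot.kde_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$lo + .data$hi) / 2,
                                   y = .data$mass,
                                   colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = object$variable, y = "interval mass",
                  title = paste("KDE grid:", object$variable)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.comparison_report <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL, title = "Realism metrics") +
    ggplot2::theme_minimal()
}

#' Scatter of per-code frequencies in real versus synthetic data
#' @param real,synth [ehr_cohort()] objects.
#' @param log_scale Use log10 axes.
#' @return A ggplot.
#' @export
plot_code_frequencies <- function(real, synth, log_scale = TRUE) {
  fr <- table(real$diagnoses$code)
  fs <- table(synth$diagnoses$code)
  codes <- union(names(fr), names(fs))
  df <- tibble::tibble(
    code = codes,
    real = as.numeric(fr[codes]) / sum(fr),
    synth = as.numeric(fs[codes]) / sum(fs))
  df[is.na(df)] <- 0
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$real, y = .data$synth)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "real frequency", y = "synthetic frequency",
                  title = "Diagnosis code frequencies") +
    ggplot2::theme_minimal()
  if (log_scale)
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' ACF comparison plot for daily event counts
#' @param temporal A `temporal_fidelity()` result.
#' @return A ggplot.
#' @export
plot_temporal_fidelity <- function(temporal) {
  lags <- seq_along(temporal$acf_real)
  df <- dplyr::bind_rows(
    tibble::tibble(lag = lags, acf = temporal$acf_real, cohort = "real"),
    tibble::tibble(lag = lags, acf = temporal$acf_synth, cohort = "synthetic"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$acf,
                                   fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = c(7, 14, 21, 28), linetype = 3,
                        colour = "grey60") +
    ggplot2::labs(title = "Daily-count autocorrelation",
                  y = "ACF", x = "lag (days)") +
    ggplot2::theme_minimal()
}
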