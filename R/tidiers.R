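# broom-style tidiers and ggplot2 autoplot methods for fitted models and
# evaluation reports.

#' @export
tidy.synexpr_fit <- function(x, ...) x$history

#' @export
glance.synexpr_gan <- function(x, ...) {
  h <- x$history
  tibble::tibble(kind = x$kind, layer_family = if (!is.null(x$spec))
    x$spec$layer_family else NA_character_,
    n_genes = length(x$gene_ids), epochs = nrow(h),
    final_critic_loss = h$critic_loss[nrow(h)],
    final_generator_loss = h$generator_loss[nrow(h)],
    final_wasserstein = h$wasserstein[nrow(h)],
    checksum = x$checksum)
}

#' @export
glance.synexpr_cvae <- function(x, ...) {
  h <- x$history
  tibble::tibble(kind = "cvae", n_genes = length(x$gene_ids),
                 epochs = nrow(h), final_loss = h$loss[nrow(h)],
                 final_reconstruction = h$reconstruction[nrow(h)],
                 final_kl = h$kl[nrow(h)], checksum = x$checksum)
}

#' @export
tidy.evaluation_report <- function(x, ...) {
  det <- x$detectability %>%
    dplyr::group_by(.data$classifier, .data$space) %>%
    dplyr::summarise(value = mean(.data$f1), .groups = "drop") %>%
    dplyr::mutate(metric = paste0("detectability_f1_", .data$classifier,
                                  "_", .data$space)) %>%
    dplyr::select("metric", "value")
  base <- tibble::tibble(
    metric = c("precision", "recall", "correlation_coefficient",
               "mean_gene_wasserstein", "ks_frac_significant"),
    value = c(x$precision, x$recall, x$correlation_coefficient,
              x$mean_gene_wasserstein,
              mean(x$ks$p_adjusted < 0.05)))
  out <- dplyr::bind_rows(base, det)
  if (!x$tstr_skipped) {
    ts <- x$tstr %>%
      tidyr::pivot_longer(c("balanced_accuracy", "macro_f1"),
                          names_to = "which", values_to = "value") %>%
      dplyr::mutate(metric = paste0("tstr_", .data$which, "_",
                                    .data$classifier)) %>%
      dplyr::select("metric", "value")
    out <- dplyr::bind_rows(out, ts)
  }
  out
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(precision = x$precision, recall = x$recall,
                 correlation_coefficient = x$correlation_coefficient,
                 mean_gene_wasserstein = x$mean_gene_wasserstein,
                 mean_detectability_f1 = mean(x$detectability$f1),
                 tstr_skipped = x$tstr_skipped,
                 n_real = x$meta$n_real, n_syn = x$meta$n_syn,
                 n_genes = x$meta$n_genes)
}

#' Plot the training history of an adversarial fit
#' @param object a `synexpr_gan` or `synexpr_cvae` fit.
#' @param ... unused.
#' @export
autoplot.synexpr_gan <- function(object, ...) {
  h <- object$history %>%
    tidyr::pivot_longer(-"epoch", names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Adversarial training history") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.synexpr_cvae <- autoplot.synexpr_gan

#' Plot an evaluation report
#'
#' Bar chart of the scalar metrics from [tidy.evaluation_report()].
#' @param object an `evaluation_report`.
#' @param ... unused.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value,
                                  y = stats::reorder(.data$metric,
                                                     .data$value))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "value", y = NULL,
                  title = "Synthetic-data evaluation metrics") +
    ggplot2::theme_minimal()
}
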