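#' Tidy the trained edge classifier
#'
#' @param x A `technique_likelihoods` object from [train_classifier()].
#' @param ... Unused.
#' @return Per-technique tibble with the class-conditional probabilities and
#'   the likelihood ratio.
#' @method tidy technique_likelihoods
#' @export
tidy.technique_likelihoods <- function(x, ...) {
  x$likelihoods
}

#' @rdname tidy.technique_likelihoods
#' @method glance technique_likelihoods
#' @export
glance.technique_likelihoods <- function(x, ...) {
  tibble(prior_true = x$prior_true, smoothing = x$smoothing,
         n_pos = x$n_pos, n_neg = x$n_neg,
         n_techniques = nrow(x$likelihoods))
}

#' Likelihood-ratio plot of the trained edge classifier
#'
#' @param object A `technique_likelihoods`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot technique_likelihoods
#' @export
autoplot.technique_likelihoods <- function(object, ...) {
  df <- arrange(object$likelihoods, .data$likelihood_ratio)
  df$technique <- factor(df$technique, levels = df$technique)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$likelihood_ratio,
                                   y = .data$technique)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "technique likelihood ratio P(t | true) / P(t | false)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a hit selection
#'
#' @param x A `hit_selection` from [select_hits()].
#' @param ... Unused.
#' @return Long tibble with `gene` and `hit_class`.
#' @method tidy hit_selection
#' @export
tidy.hit_selection <- function(x, ...) {
  bind_rows(tibble(gene = x$morphology_hits, hit_class = "morphology"),
            tibble(gene = x$size_hits, hit_class = "size"),
            tibble(gene = x$extra_wrinkly_hits, hit_class = "extra_wrinkly"))
}

#' @rdname tidy.hit_selection
#' @method glance hit_selection
#' @export
glance.hit_selection <- function(x, ...) {
  tibble(n_morphology = length(x$morphology_hits),
         n_size = length(x$size_hits),
         n_extra_wrinkly = length(x$extra_wrinkly_hits),
         n_excluded = length(x$excluded),
         n_ambiguous = length(x$ambiguous))
}
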