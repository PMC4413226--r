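#' Plot per-individual refined posteriors
#'
#' Posterior alternative-allele dosage for every individual, coloured by the
#' hard call.
#'
#' @param object A [refine_variant()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot refined_variant
#' @export
autoplot.refined_variant <- function(object, ...) {
  df <- object$posteriors
  ggplot2::ggplot(df, ggplot2::aes(x = .data$individual, y = .data$dosage,
                                   colour = .data$gt)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 2)) +
    ggplot2::labs(x = "individual", y = "posterior dosage",
                  colour = "hard call",
                  title = sprintf("refined variant: freq %.3f, info %.2f",
                                  object$frequency, object$info)) +
    ggplot2::theme_minimal()
}

#' Plot copying posteriors along the scaffold
#'
#' Heat map of the stored donor weights gamma over markers.
#'
#' @param object A [copying_posteriors()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot copying_posteriors
#' @export
autoplot.copying_posteriors <- function(object, ...) {
  df <- generics::tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = factor(.data$donor),
                                   fill = .data$gamma)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "position (bp)", y = "donor haplotype",
                  fill = expression(gamma),
                  title = sprintf("copying posteriors for haplotype %d", object$h)) +
    ggplot2::theme_minimal()
}

#' Plot an indel length spectrum
#'
#' Bar chart of indel counts by signed length, in-frame changes highlighted,
#' faceted by coding context when present.
#'
#' @param spectrum Output of [indel_length_spectrum()].
#' @return A ggplot object.
#' @export
plot_indel_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$length, y = .data$n,
                                         fill = .data$frame)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~coding) +
    ggplot2::scale_fill_manual(values = c(in_frame = "black",
                                          frameshift = "grey60")) +
    ggplot2::labs(x = "indel length (bp; deletions negative)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot imputation accuracy by frequency bin
#'
#' @param object A [concordance_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concordance_report
#' @export
autoplot.concordance_report <- function(object, ...) {
  ggplot2::ggplot(object$per_variant,
                  ggplot2::aes(x = .data$freq, y = .data$r2,
                               colour = .data$info)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "allele frequency", y = expression(r^2),
                  colour = "info") +
    ggplot2::theme_minimal()
}
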