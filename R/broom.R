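#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained sub-model's training log
#' @param x A `loc_model`.
#' @param ... Unused.
#' @return Tibble `alternation, phase, mean_loss`.
#' @exportS3Method generics::tidy
tidy.loc_model <- function(x, ...) x$log

#' @exportS3Method generics::glance
glance.loc_model <- function(x, ...) {
  lv2 <- x$log$mean_loss[x$log$phase == "lv2"]
  tibble(cycles = x$cycles, heads = x$cfg$heads, hidden = 2 * x$cfg$hidden,
         flatten_len = x$cfg$flatten_len,
         final_loss = if (length(lv2)) utils::tail(lv2, 1) else NA_real_)
}

#' Tidy an ensemble: the tuned per-cell thresholds
#' @param x A `loc_ensemble`.
#' @param ... Unused.
#' @return Tibble `suborganelle, threshold, tuned`.
#' @exportS3Method generics::tidy
tidy.loc_ensemble <- function(x, ...) x$thresholds

#' @exportS3Method generics::glance
glance.loc_ensemble <- function(x, ...) {
  tibble(n_models = length(x$models), cycles = x$cycles,
         n_classes = x$hierarchy$n_class,
         n_tuned = sum(x$thresholds$tuned),
         heads = x$cfg$heads, flatten_len = x$cfg$flatten_len)
}

#' Plot a per-residue attention profile
#' @param object A `loc_attention`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.loc_attention <- function(object, ...) {
  gap <- attr(object, "gap")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                            y = .data$weight)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "sequence position (N- to C-terminus)",
                  y = "attention weight",
                  title = attr(object, "accession")) +
    ggplot2::theme_minimal()
  if (!is.null(gap))
    p <- p + ggplot2::annotate("rect", xmin = gap[["from"]],
                               xmax = gap[["to"]], ymin = -Inf, ymax = Inf,
                               alpha = 0.15)
  p
}

#' Plot a terminus- or cleavage-aligned group attention profile
#' @param object A `loc_group_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.loc_group_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                            y = .data$mean_attention)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("aligned position (%s)", attr(object, "anchor")),
                  y = "mean attention") +
    ggplot2::theme_minimal()
  if (identical(attr(object, "anchor"), "cleavage"))
    p <- p + ggplot2::geom_vline(xintercept = 0, linetype = "dashed")
  p
}

#' Export a sequence-logo-ready position-by-letter weight matrix
#'
#' Position-wise residue frequencies of a terminus-aligned group profile,
#' scaled by the mean attention, in long format for logo tools.
#'
#' @param profile A `loc_group_profile` from [terminus_profile()].
#' @param weight_by_attention Multiply frequencies by the positional mean
#'   attention.
#' @return Tibble `position, letter, weight`.
#' @export
logo_matrix <- function(profile, weight_by_attention = TRUE) {
  freq <- attr(profile, "freq")
  if (is.null(freq)) .stopf("profile carries no residue frequencies")
  w <- if (weight_by_attention) profile$mean_attention else rep(1, nrow(freq))
  out <- as_tibble(as.data.frame(freq))
  out$position <- profile$position
  out <- tidyr::pivot_longer(out, cols = -"position",
                             names_to = "letter", values_to = "weight")
  out$weight <- out$weight * w[match(out$position, profile$position)]
  out
}

#' Export a group profile as TSV
#' @param profile A `loc_group_profile`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  invisible(path)
}
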