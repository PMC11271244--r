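# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point coord_equal
#'   scale_fill_viridis_c labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Tidy a detector annotation
#'
#' @param x A `spot_annotation`.
#' @param ... Unused.
#' @return Tibble with `spot_id`, `label`, and one feature column per channel.
#' @method tidy spot_annotation
#' @export
tidy.spot_annotation <- function(x, ...) {
  dplyr::bind_cols(x$labels, tibble::as_tibble(x$features))
}

#' Tidy an EM fit: fitted marker overexpression factors
#'
#' @param x An `em_fit`.
#' @param ... Unused.
#' @return Tibble `gene`, `pattern`, `delta` for the marker entries.
#' @method tidy em_fit
#' @export
tidy.em_fit <- function(x, ...) x$delta

#' One-row EM fit summary
#'
#' @param x An `em_fit`.
#' @param ... Unused.
#' @return Tibble with sweep count, final Q, and model dimensions.
#' @method glance em_fit
#' @export
glance.em_fit <- function(x, ...) {
  tibble::tibble(
    sweeps = length(x$q_trace),
    q_final = x$q_trace[length(x$q_trace)],
    n_spots = nrow(x$posterior),
    n_genes = length(x$genes),
    n_patterns = length(x$patterns)
  )
}

#' Tidy a pipeline result: per-spot labels and posterior
#'
#' @param x A `spotanno_result`.
#' @param ... Unused.
#' @return Tibble with coordinates, initial and final labels, and posterior
#'   probabilities per pattern.
#' @method tidy spotanno_result
#' @export
tidy.spotanno_result <- function(x, ...) {
  dplyr::bind_cols(x$spots, tibble::as_tibble(x$posterior))
}

#' One-row pipeline summary
#'
#' @param x A `spotanno_result`.
#' @param ... Unused.
#' @return Tibble with spot/gene/pattern counts, EM sweeps, final Q, and mean
#'   posterior confidence.
#' @method glance spotanno_result
#' @export
glance.spotanno_result <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$fit),
    tibble::tibble(mean_max_posterior = mean(apply(x$posterior, 1, max)))
  )
}

#' Plot per-spot labels
#'
#' @param object A `spotanno_result` (or `spot_annotation`).
#' @param which `"final"` or `"initial"` labels for results.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spotanno_result
#' @export
autoplot.spotanno_result <- function(object, which = c("final", "initial"), ...) {
  which <- match.arg(which)
  col <- if (which == "final") "label" else "label_initial"
  ggplot(object$spots, aes(x = .data$x, y = .data$y, colour = .data[[col]])) +
    geom_point(size = 1) +
    coord_equal() +
    labs(colour = "pattern", title = paste(which, "annotation")) +
    theme_minimal()
}

#' @method autoplot spot_annotation
#' @export
autoplot.spot_annotation <- function(object, ...) {
  df <- dplyr::left_join(object$pmap$map, object$labels, by = "spot_id")
  ggplot(df, aes(x = .data$j, y = .data$i, fill = .data$label)) +
    geom_tile() +
    coord_equal() +
    labs(fill = "pattern", x = "column", y = "row") +
    theme_minimal()
}

#' Plot a feature or pattern image stack
#'
#' @param stack I x J x R array.
#' @param channel_names Optional channel names.
#' @return A ggplot of the channels as faceted heatmaps.
#' @export
plot_image_stack <- function(stack, channel_names = NULL) {
  R <- dim(stack)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(R))
  df <- purrr::map_dfr(seq_len(R), function(r) {
    m <- stack[, , r]
    tibble::tibble(row = as.integer(row(m)), col = as.integer(col(m)),
                   channel = channel_names[r], value = as.numeric(m))
  })
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c() +
    facet_wrap(~channel) +
    coord_equal() +
    theme_minimal()
}
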