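#' Plot ROH segments per sample
#'
#' One horizontal bar per detected segment, samples on the y axis, with an
#' optional anchor position marked.
#'
#' @param object An `roh_segments` tibble from [detect_roh()].
#' @param anchor_bp Optional anchor position to mark (vertical line).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roh_segments
#' @export
autoplot.roh_segments <- function(object, anchor_bp = NULL, ...) {
  p <- ggplot2::ggplot(object) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
        y = .data$sample_id, yend = .data$sample_id
      ),
      linewidth = 4, colour = "grey20"
    ) +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = "Runs of homozygosity") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x")
  if (!is.null(anchor_bp)) {
    p <- p + ggplot2::geom_vline(xintercept = anchor_bp / 1e6,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot a genetic map
#'
#' Cumulative genetic position against physical position, knots marked.
#'
#' @param object A `genetic_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot genetic_map
#' @export
autoplot.genetic_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$bp / 1e6, .data$cm)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free") +
    ggplot2::labs(x = "physical position (Mb)",
                  y = "genetic position (cM, sex-averaged)")
}

#' Plot a founder-age estimate
#'
#' Point estimate with its confidence interval, on the generations scale
#' and (when set) the years scale.
#'
#' @param object A `founder_age`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot founder_age
#' @export
autoplot.founder_age <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high)
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$term), ncol = 1,
                        scales = "free") +
    ggplot2::labs(x = "estimate", y = NULL,
                  title = "Founder-allele age",
                  subtitle = sprintf("%d segments, %.0f%% CI", object$n,
                                     100 * object$conf.level))
}

#' Sketch a restriction gel
#'
#' Draws fragment-size patterns as lanes of bands (size on a reversed log
#' scale, as fragments migrate), for eyeballing simulated digests against
#' expected genotype patterns.
#'
#' @param lanes Named list of numeric fragment-size vectors, one per lane.
#' @return A ggplot.
#' @examples
#' fx <- make_rflp_fixture()
#' plot_gel(list(
#'   uncut = 357, `WT/WT` = fx$wt_pattern, `mut/mut` = fx$mut_pattern,
#'   `WT/mut` = union(fx$wt_pattern, fx$mut_pattern)
#' ))
#' @export
plot_gel <- function(lanes) {
  if (!is.list(lanes) || is.null(names(lanes))) {
    stop_input("`lanes` must be a named list of fragment-size vectors")
  }
  df <- purrr::imap_dfr(lanes, function(sizes, lane) {
    tibble(lane = lane, size = as.numeric(sizes))
  })
  df$lane <- factor(df$lane, levels = names(lanes))
  ggplot2::ggplot(df, ggplot2::aes(.data$lane, .data$size)) +
    ggplot2::geom_tile(width = 0.6, height = 0.012 * df$size,
                       fill = "grey15") +
    ggplot2::scale_y_continuous(trans = "log10") +
    ggplot2::labs(x = NULL, y = "fragment size (bp)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank())
}
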