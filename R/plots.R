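#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point geom_tile
#'   geom_text geom_rect geom_hline facet_wrap labs scale_fill_gradient2
#'   theme_minimal autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the DE family composition
#'
#' Side-by-side view of each family's share of the DE set and its DE
#' rate within the family - the contrast that separates enriched
#' families from merely abundant ones.
#'
#' @param fd A tibble from [family_distribution()].
#' @return A ggplot object.
#' @export
plot_family_distribution <- function(fd) {
  long <- fd |>
    select("family", "share_of_de", "rate_in_family") |>
    pivot_longer(-"family", names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$family, y = .data$value,
                   fill = .data$family)) +
    geom_col(show.legend = FALSE) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "TE family", y = NULL) +
    theme_minimal()
}

#' @describeIn consensus_profile Conservation track of a consensus
#'   profile; low-coverage columns are marked.
#' @param object A `consensus_profile`.
#' @param ... Unused.
#' @export
autoplot.consensus_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$position, y = .data$conservation)) +
    geom_line() +
    geom_point(data = filter(object, .data$low_coverage), colour = "red",
               size = 0.8) +
    labs(x = "reference column", y = "conservation (modal frequency)") +
    theme_minimal()
}

#' Compare DE and non-DE conservation profiles
#'
#' Both conservation tracks with the detected conserved regions shaded.
#'
#' @param profile_de,profile_nonde Two [consensus_profile()]s.
#' @param regions Optional tibble from [conserved_regions()].
#' @return A ggplot object.
#' @export
plot_conservation <- function(profile_de, profile_nonde, regions = NULL) {
  both <- bind_rows(mutate(profile_de, set = "DE"),
                    mutate(profile_nonde, set = "non-DE"))
  p <- ggplot(both, aes(x = .data$position, y = .data$conservation,
                        colour = .data$set)) +
    geom_line() +
    labs(x = "reference column", y = "conservation", colour = NULL) +
    theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + geom_rect(data = regions,
                       aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5),
                       ymin = -Inf, ymax = Inf, alpha = 0.15,
                       fill = "red", inherit.aes = FALSE)
  }
  p
}

#' @describeIn assoc_matrix Heat-tile view of the measure-by-phenotype
#'   correlation matrix with r printed in each cell.
#' @param object An `assoc_matrix`.
#' @param ... Unused.
#' @export
autoplot.assoc_matrix <- function(object, ...) {
  ggplot(object, aes(x = .data$phenotype, y = .data$measure,
                     fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = ifelse(is.na(.data$r), "",
                                 sprintf("%.2f", .data$r))), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1), low = "blue", mid = "white",
                         high = "red", na.value = "grey90") +
    labs(x = NULL, y = NULL, fill = "r") +
    theme_minimal()
}

#' @describeIn cis_correlate Per-group correlation of each tested pair:
#'   control against case r, significant pairs highlighted.
#' @param object A `te_correlation`.
#' @param ... Unused.
#' @export
autoplot.te_correlation <- function(object, ...) {
  rec <- object$records
  ggplot(rec, aes(x = .data$r_ctrl, y = .data$r_case,
                  colour = .data$sig_all)) +
    geom_point(alpha = 0.6, size = 0.9) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    labs(x = "r (control)", y = "r (case)",
         colour = sprintf("padj < %g (all)", object$fdr)) +
    theme_minimal()
}
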