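#' Plot a volume-model fit
#'
#' `type = "networks"` shows each network's posterior sigma (point) with its
#' 5-95% HPD interval, ordered from most to least explanatory. `type =
#' "regions"` shows region coefficients with intervals, colored by flag.
#'
#' @param object An `lb_volume_fit`.
#' @param type `"networks"` or `"regions"`.
#' @param prob Interval mass.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lb_volume_fit <- function(object, type = c("networks", "regions"),
                                   prob = 0.90, ...) {
  type <- match.arg(type)
  td <- tidy(object, prob = prob)
  if (type == "networks") {
    if (object$model != "network") {
      abort("network sigma plot needs a network-level fit")
    }
    sg <- td[td$kind == "sigma", ]
    sg$network <- factor(sg$network,
                         levels = rev(sg$network[order(-sg$mean)]))
    p <- ggplot2::ggplot(sg, ggplot2::aes(x = .data$mean, y = .data$network)) +
      ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$hpd_low,
                                            xmax = .data$hpd_high)) +
      ggplot2::labs(x = "posterior network sigma (5-95% HPD)", y = NULL)
    if (object$stratify_sex) p <- p + ggplot2::facet_wrap(~group)
    return(p)
  }
  be <- td[td$kind == "beta", ]
  be$region <- factor(be$region, levels = be$region[order(be$mean)])
  p <- ggplot2::ggplot(be, ggplot2::aes(x = .data$mean, y = .data$region,
                                        color = .data$flag)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$hpd_low,
                                          xmax = .data$hpd_high),
                             linewidth = 0.3, size = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_color_manual(values = c(positive = "#e0a100",
                                           negative = "#1b7837",
                                           none = "grey70")) +
    ggplot2::labs(x = "posterior region coefficient (5-95% HPD)", y = NULL) +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
  if (object$stratify_sex) p <- p + ggplot2::facet_wrap(~group)
  p
}

#' Plot a connectivity mode as network-block averages
#'
#' Heatmap of the 7 x 7 network-block summary of the edge weights (mean mode
#' weight within and between networks).
#'
#' @param object An `lb_pls_mode`.
#' @param atlas Atlas used to assign edges to networks.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lb_pls_mode <- function(object, atlas = load_atlas(), ...) {
  blk <- network_block_summary(object, atlas)
  df <- as.data.frame(as.table(blk))
  names(df) <- c("network_a", "network_b", "weight")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$network_a, y = .data$network_b,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean\nweight") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the permutation null with the observed mode correlation
#'
#' @param object An `lb_permutation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lb_permutation <- function(object, ...) {
  df <- tibble(null = object$null_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey75", color = "white") +
    ggplot2::geom_vline(xintercept = object$observed, color = "#b2182b",
                        linewidth = 1) +
    ggplot2::labs(x = "permutation null: |cor(scores, shuffled labels)|",
                  y = "count",
                  subtitle = sprintf("observed = %.4f, p = %.4g (B = %d)",
                                     object$observed, object$p_value, object$B))
}

#' Plot tract associations ordered from strongest to weakest
#'
#' Bars show the Pearson correlation per tract with 5-95% bootstrap interval
#' whiskers; tracts surviving Bonferroni correction at p < 0.001 are marked.
#'
#' @param object An `lb_tract_assoc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lb_tract_assoc <- function(object, ...) {
  df <- dplyr::arrange(as_tibble(object), .data$rank)
  df$tract <- factor(df$tract, levels = rev(df$tract))
  df$sig <- df$p_bonferroni < 0.001
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pearson_rho, y = .data$tract,
                                   fill = .data$sig)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.3, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "grey70"),
                               name = "Bonferroni p < 0.001") +
    ggplot2::labs(x = "Pearson rho with loneliness (5-95% bootstrap CI)",
                  y = NULL) +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Tidy the edge weights of a connectivity mode
#'
#' @param x An `lb_pls_mode`.
#' @param atlas Atlas for region/network annotation (NULL to skip).
#' @param ... Unused.
#' @return Tibble: `edge`, `i`, `j`, `weight` plus region/network columns when
#'   an atlas is given.
#' @export
tidy.lb_pls_mode <- function(x, atlas = NULL, ...) {
  E <- length(x$x_weights)
  R <- as.integer((1 + sqrt(1 + 8 * E)) / 2)
  ei <- edge_index(R)
  out <- dplyr::mutate(ei, weight = x$x_weights)
  if (!is.null(atlas)) {
    out$region_i <- atlas$name[out$i]
    out$region_j <- atlas$name[out$j]
    out$network_i <- atlas$network[out$i]
    out$network_j <- atlas$network[out$j]
  }
  out
}

#' @export
glance.lb_pls_mode <- function(x, ...) {
  tibble(n = x$n, k = x$k, mode_corr = x$mode_corr)
}

#' @export
glance.lb_permutation <- function(x, ...) {
  tibble(observed = x$observed, p_value = x$p_value, B = x$B)
}

#' @export
tidy.lb_permutation <- function(x, ...) {
  tibble(iteration = seq_len(x$B), null_stat = x$null_stats)
}

#' @export
tidy.lb_tract_assoc <- function(x, ...) {
  dplyr::arrange(as_tibble(x), .data$rank)
}

#' @export
glance.lb_tract_assoc <- function(x, ...) {
  tibble(n_tracts = nrow(x),
         n_significant = sum(x$p_bonferroni < 0.05),
         top_tract = x$tract[x$rank == 1],
         top_rho = x$pearson_rho[x$rank == 1])
}
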