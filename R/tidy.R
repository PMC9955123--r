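#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the estimated memberships of a fit
#'
#' One row per (node, community) pair on each side, long format.
#'
#' @param x a `dimsc_fit`.
#' @param ... unused.
#' @return tibble with columns `side` ("row"/"column"), `node`, `community`,
#'   `weight`, and `pure` (whether the estimated row is degenerate).
#' @export
tidy.dimsc_fit <- function(x, ...) {
  one_side <- function(pi, side) {
    n <- nrow(pi); K <- ncol(pi)
    tibble::tibble(
      side = side,
      node = rep(seq_len(n), each = K),
      community = rep(seq_len(K), times = n),
      weight = as.vector(t(pi)),
      pure = rep(apply(pi, 1, max) >= 1 - 1e-12, each = K)
    )
  }
  dplyr::bind_rows(one_side(x$pi_r, "row"), one_side(x$pi_c, "column"))
}

#' One-row summary of a fit
#'
#' @param x a `dimsc_fit`.
#' @param ... unused.
#' @return tibble with network dimensions, K, the K-th/1st singular value
#'   ratio, clipping diagnostics and the corner indices (list columns).
#' @export
glance.dimsc_fit <- function(x, ...) {
  tibble::tibble(
    nr = nrow(x$pi_r),
    nc = nrow(x$pi_c),
    K = x$K,
    oracle = isTRUE(x$oracle),
    sigma_1 = x$svd$d[1],
    sigma_K = x$svd$d[x$K],
    clipped_row = if (is.null(x$clipped_row)) 0L else x$clipped_row,
    clipped_col = if (is.null(x$clipped_col)) 0L else x$clipped_col,
    corners_row = list(x$corners_row$indices),
    corners_col = list(x$corners_col$indices)
  )
}

#' Membership composition plot for a fit
#'
#' Stacked per-node membership weights, one panel per side; the standard way
#' to eyeball how mixed the recovered communities are.
#'
#' @param object a `dimsc_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dimsc_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$node, y = .data$weight,
                                   fill = factor(.data$community))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~side, ncol = 1, scales = "free_x") +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "community") +
    ggplot2::labs(y = "membership weight") +
    ggplot2::theme_minimal()
}
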