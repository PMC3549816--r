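#' Write and read the cluster report table
#'
#' One row per cluster (singletons included, flagged as below the support
#' threshold), tab-separated with a header and a leading `#` comment stating
#' the coordinate convention. Coordinates are reported 1-based inclusive.
#' Rows are ordered by (chrom, region, cluster left boundary). Numeric
#' columns are written at full precision, so reading the table back
#' reconstructs the cluster parameters exactly.
#'
#' @param fit a `delclust_fit` from [cluster_deletions()].
#' @param path output path.
#' @return `write_cluster_table()` invisibly returns the number of cluster
#'   rows written; `read_cluster_table()` returns the report tibble.
#' @export
write_cluster_table <- function(fit, path) {
  stopifnot(inherits(fit, "delclust_fit"))
  tab <- tidy(fit) |> select(-"members")
  readr::write_lines(
    "# delclust cluster report; start/end are 1-based inclusive breakpoint boundaries",
    path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(nrow(tab))
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Write the cluster membership companion file
#'
#' Lists, for each cluster, the ids of its member mappings as a
#' comma-separated list (tab-separated: `cluster_id`, `n`, `members`).
#'
#' @inheritParams write_cluster_table
#' @return Invisibly, the number of rows written.
#' @export
write_cluster_members <- function(fit, path) {
  stopifnot(inherits(fit, "delclust_fit"))
  tab <- fit$clusters |>
    transmute(.data$cluster_id, .data$n,
              members = purrr::map_chr(.data$members, paste, collapse = ","))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(nrow(tab))
}

# Sutherland-Hodgman clipping of a convex polygon against a*x + b*y <= c
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  out_x <- numeric(0); out_y <- numeric(0)
  inside <- a * poly$x + b * poly$y <= c + 1e-9
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      out_x <- c(out_x, poly$x[i]); out_y <- c(out_y, poly$y[i])
    }
    if (inside[i] != inside[j]) {
      d1 <- a * poly$x[i] + b * poly$y[i] - c
      d2 <- a * poly$x[j] + b * poly$y[j] - c
      t <- d1 / (d1 - d2)
      out_x <- c(out_x, poly$x[i] + t * (poly$x[j] - poly$x[i]))
      out_y <- c(out_y, poly$y[i] + t * (poly$y[j] - poly$y[i]))
    }
  }
  tibble(x = out_x, y = out_y)
}

# band { max(smin, 0) <= y - x <= smax } clipped to the triangle over [l, r)
band_polygon <- function(l, r, smin, smax) {
  tri <- tibble(x = c(l, l, r), y = c(l, r, r))
  poly <- clip_halfplane(tri, -1, 1, smax)       # y - x <= smax
  poly <- clip_halfplane(poly, 1, -1, -max(smin, 0))  # y - x >= smin
  if (nrow(poly) < 3) return(NULL)
  poly
}

#' Plot one region in the (deletion start, deletion end) plane
#'
#' Draws every mapping of the region as a triangle outlined in its sample's
#' color, with gray interior bands whose darkness follows the Gaussian
#' height over the deletion size (binned into at most `bins` levels at equal
#' probability quantiles). Each cluster with at least `min_support` member
#' mappings is overlaid as a yellow trapezoid spanned by `l`, `r` and the
#' size band `mu - 3 sigma` to `mu + 3 sigma` (clipped to the diagonal and
#' to the triangle), labeled with its membership count. Mappings belonging
#' to smaller clusters are drawn with dotted outlines: isolated singletons
#' are typically erroneous mappings.
#'
#' @param fit a `delclust_fit`.
#' @param region_id the region to draw.
#' @param config optional sample configuration ([read_sample_config()])
#'   supplying per-sample colors; defaults to a fixed palette.
#' @param min_support support threshold for highlighting clusters; defaults
#'   to the fit's.
#' @param bins maximum number of gray shading levels per triangle (<= 16).
#' @return A ggplot object.
#' @export
plot_region <- function(fit, region_id, config = NULL,
                        min_support = fit$min_support, bins = 12) {
  stopifnot(inherits(fit, "delclust_fit"))
  bins <- min(bins, 16L)
  maps <- fit$mappings[fit$mappings$region_id == region_id, ]
  if (nrow(maps) == 0) abort(paste0("no such region: ", region_id))
  cl <- fit$clusters[fit$clusters$region_id == region_id, ]
  samples <- sort(unique(fit$models$sample_id))
  colors <- setNames(default_palette[((seq_along(samples) - 1) %%
                                        length(default_palette)) + 1], samples)
  if (!is.null(config) && all(c("sample_id", "color") %in% names(config))) {
    colors[config$sample_id] <- config$color
  }
  supported <- cl[cl$n >= min_support, ]
  small_members <- unlist(cl$members[cl$n < min_support])
  sing <- singleton_clusters(maps, fit$models)
  # gray shading: per-triangle bands between equal-probability quantiles of
  # the size distribution, darker where the density is higher
  qs <- stats::qnorm(seq(0, 1, length.out = bins + 1))
  shade <- purrr::pmap_dfr(
    list(sing$cluster_id, sing$l, sing$r, sing$mu, sing$sigma),
    function(id, l, r, mu, sigma) {
      edges <- pmin(pmax(mu + qs * sigma, 0), r - l)
      purrr::map_dfr(seq_len(bins), function(b) {
        if (edges[b + 1] - edges[b] <= 0) return(NULL)
        poly <- band_polygon(l, r, edges[b], edges[b + 1])
        if (is.null(poly)) return(NULL)
        mid <- (edges[b] + edges[b + 1]) / 2
        poly |> mutate(grp = paste0(id, "_", b),
                       level = dnorm(mid, mu, sigma) / dnorm(mu, mu, sigma))
      })
    })
  outlines <- purrr::pmap_dfr(
    list(sing$cluster_id, sing$l, sing$r),
    function(id, l, r) {
      tibble(x = c(l, l, r), y = c(l, r, r), id = id)
    }) |>
    left_join(maps |> select(id = "id", sample = "sample_id"), by = "id") |>
    mutate(dotted = .data$id %in% small_members)
  trapezoids <- purrr::pmap_dfr(
    list(supported$cluster_id, supported$l, supported$r, supported$mu,
         supported$sigma),
    function(id, l, r, mu, sigma) {
      poly <- band_polygon(l, r, mu - 3 * sigma, mu + 3 * sigma)
      if (is.null(poly)) return(NULL)
      poly |> mutate(grp = id)
    })
  p <- ggplot2::ggplot()
  if (nrow(shade) > 0) {
    p <- p + ggplot2::geom_polygon(
      data = shade,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$grp,
                   alpha = .data$level),
      fill = "black", show.legend = FALSE) +
      ggplot2::scale_alpha_continuous(range = c(0.02, 0.35))
  }
  if (nrow(trapezoids) > 0) {
    p <- p + ggplot2::geom_polygon(
      data = trapezoids,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$grp),
      fill = "yellow", alpha = 0.6, color = "goldenrod3")
  }
  p <- p + ggplot2::geom_polygon(
    data = outlines,
    ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                 color = .data$sample, linetype = .data$dotted),
    fill = NA, linewidth = 0.3) +
    ggplot2::scale_color_manual(values = colors, name = "sample") +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dotted"),
                                   guide = "none")
  if (nrow(supported) > 0) {
    p <- p + ggplot2::annotate(
      "text",
      x = (pmax(supported$l, supported$l) + supported$r) / 2,
      y = (supported$l + supported$r) / 2 +
        pmin(supported$mu, supported$r - supported$l) / 2,
      label = supported$n, fontface = "bold")
  }
  p + ggplot2::geom_abline(slope = 1, intercept = 0, linewidth = 0.2,
                           color = "gray60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "deletion start", y = "deletion end",
                  title = paste0(maps$chrom[1], ", region ", region_id)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_region
#' @param object a `delclust_fit` (for `autoplot`).
#' @param ... passed on to [plot_region()].
#' @importFrom ggplot2 autoplot
#' @export
autoplot.delclust_fit <- function(object, region_id, ...) {
  plot_region(object, region_id, ...)
}

#' Render region plots to image files
#'
#' `render_region()` writes the plot of one region to `path` (format chosen
#' by the file extension: png, pdf, or svg). `render_regions()` writes one
#' file per region that has at least one cluster meeting the support
#' threshold.
#'
#' @inheritParams plot_region
#' @param path output file for a single region.
#' @param dir output directory for `render_regions()`.
#' @param format image format for `render_regions()` (`"png"` or `"pdf"`).
#' @param width,height device size in inches.
#' @return The path(s) of the rendered file(s), invisibly.
#' @export
render_region <- function(fit, region_id, path, config = NULL,
                          min_support = fit$min_support, width = 7,
                          height = 7) {
  p <- plot_region(fit, region_id, config = config, min_support = min_support)
  ggplot2::ggsave(path, plot = p, width = width, height = height)
  invisible(path)
}

#' @rdname render_region
#' @export
render_regions <- function(fit, dir, format = c("png", "pdf"), config = NULL,
                           min_support = fit$min_support, width = 7,
                           height = 7) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rids <- fit$clusters |>
    filter(.data$n >= min_support) |>
    distinct(.data$region_id) |>
    pull()
  paths <- purrr::map_chr(rids, function(rid) {
    path <- file.path(dir, paste0("region_", rid, ".", format))
    render_region(fit, rid, path, config = config, min_support = min_support,
                  width = width, height = height)
    path
  })
  invisible(paths)
}
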