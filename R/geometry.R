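# Discrete volume of the Gaussian ridge over a triangle base [l, r).
# The height of the volume is constant along anti-diagonals (lines of
# constant deletion size s = end - start), so the volume is computed by
# traversing the triangle from its hypotenuse towards the upper-left corner
# and summing line length (w - s) times the normal density at s, for integer
# s = 0 .. w-1. The sqrt(2) anti-diagonal line-length constant is omitted:
# it cancels in the similarity ratio.
tri_vol <- function(l, r, mu, sigma) {
  bump_op("triangle_volume")
  w <- r - l
  if (!is.finite(w) || w <= 0) return(0)
  s <- seq(0, w - 1)
  sum((w - s) * dnorm(s, mean = mu, sd = sigma))
}

# Volume of the pointwise minimum of two ridges over the intersected base.
inter_vol <- function(l1, r1, mu1, sigma1, l2, r2, mu2, sigma2) {
  li <- max(l1, l2)
  ri <- min(r1, r2)
  w <- ri - li
  if (w <= 0) return(0)
  s <- seq(0, w - 1)
  sum((w - s) * pmin(dnorm(s, mu1, sigma1), dnorm(s, mu2, sigma2)))
}

# score on raw parameters with pre-computed full volumes v1, v2
sim_raw <- function(l1, r1, mu1, sigma1, v1, l2, r2, mu2, sigma2, v2) {
  bump_op("similarity")
  vmax <- max(v1, v2)
  if (vmax <= 0) {
    abort("similarity is undefined: both clusters have zero volume.")
  }
  iv <- inter_vol(l1, r1, mu1, sigma1, l2, r2, mu2, sigma2)
  min(iv / vmax, 1)
}

#' Triangle volume of a deletion cluster
#'
#' A cluster with boundaries `l`, `r` and size distribution
#' `Normal(mu, sigma)` defines a volume over the triangle of allowed
#' (deletion start, deletion end) coordinates, with height given by the
#' normal density of the deletion size. The volume is evaluated as a
#' discrete sum over integer deletion sizes `s = 0 .. (r - l) - 1` of the
#' anti-diagonal line length `(r - l - s)` times `dnorm(s, mu, sigma)`.
#'
#' @param cluster a one-row cluster tibble (see [singleton_clusters()]).
#' @return A single non-negative number; 0 when `r - l <= 0`.
#' @seealso [intersection_volume()], [cluster_similarity()]
#' @export
triangle_volume <- function(cluster) {
  stopifnot(is.data.frame(cluster), nrow(cluster) == 1)
  tri_vol(cluster$l, cluster$r, cluster$mu, cluster$sigma)
}

#' Intersection volume of two deletion clusters
#'
#' The volume of the pointwise minimum of the two Gaussian ridges over the
#' intersection of the two triangle bases, `[max(l1, l2), min(r1, r2))`.
#' Zero when the bases do not overlap.
#'
#' @param c1,c2 one-row cluster tibbles.
#' @return A single non-negative number.
#' @export
intersection_volume <- function(c1, c2) {
  stopifnot(is.data.frame(c1), nrow(c1) == 1, is.data.frame(c2), nrow(c2) == 1)
  inter_vol(c1$l, c1$r, c1$mu, c1$sigma, c2$l, c2$r, c2$mu, c2$sigma)
}

#' Similarity score between two deletion clusters
#'
#' The similarity of two clusters is the intersection of their volumes
#' normalized by the larger of the two,
#' \deqn{sim(C_1, C_2) = \frac{V(C_1) \cap V(C_2)}{\max\{V(C_1), V(C_2)\}}.}
#' It lies in \[0, 1\]; it is 0 exactly when the triangles do not overlap
#' (no deletion location is compatible with both clusters) and 1 exactly
#' when the clusters are equal. Because the ridge runs parallel to the main
#' diagonal, the score is more sensitive to disagreement in deletion size
#' than to a shift in location -- staggered mappings covering the same
#' breakpoint still score high.
#'
#' @param c1,c2 one-row cluster tibbles. If a cached `volume` column is
#'   present it is used; otherwise volumes are computed on the fly.
#' @return A single number in \[0, 1\].
#' @examples
#' ms <- tibble::tibble(id = c("a", "b"), sample_id = "s", chrom = "chr1",
#'                      left_inner = c(100, 150), right_inner = c(900, 800),
#'                      span_d = c(700, 710))
#' cl <- singleton_clusters(ms, fragment_model("s", 300, 35))
#' cluster_similarity(cl[1, ], cl[2, ])
#' @export
cluster_similarity <- function(c1, c2) {
  stopifnot(is.data.frame(c1), nrow(c1) == 1, is.data.frame(c2), nrow(c2) == 1)
  v1 <- if ("volume" %in% names(c1)) c1$volume else tri_vol(c1$l, c1$r, c1$mu, c1$sigma)
  v2 <- if ("volume" %in% names(c2)) c2$volume else tri_vol(c2$l, c2$r, c2$mu, c2$sigma)
  sim_raw(c1$l, c1$r, c1$mu, c1$sigma, v1, c2$l, c2$r, c2$mu, c2$sigma, v2)
}
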