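#' Pairwise planar distances between colonies
#'
#' Euclidean centre-to-centre distances in the local planar frame. Only
#' planar area, not colony shape, is recorded, so centre-to-centre is the
#' supported distance.
#'
#' @param colonies A colony table (see [read_colony_table()]).
#' @return A symmetric numeric matrix (m) with zero diagonal, dimnames =
#'   colony ids.
#' @export
pairwise_distances <- function(colonies) {
  stopifnot(nrow(colonies) >= 1)
  d <- as.matrix(stats::dist(cbind(colonies$x, colonies$y)))
  dimnames(d) <- list(colonies$colony_id, colonies$colony_id)
  d
}

#' Distance to the nearest gravid neighbour
#'
#' Minimum distance from a focal colony to any *other* gravid colony;
#' non-gravid colonies are ignored. An isolated focal colony (no other
#' gravid colony on the map) is an error: its nearest-neighbour distance is
#' undefined, not infinite.
#'
#' @param target_id Focal colony id.
#' @param colonies Colony table containing the focal colony.
#' @param dists Optional precomputed [pairwise_distances()] matrix.
#' @return Distance in metres.
#' @export
nearest_gravid_neighbor <- function(target_id, colonies, dists = NULL) {
  if (is.null(dists)) dists <- pairwise_distances(colonies)
  others <- colonies$colony_id[colonies$gravid &
                                 colonies$colony_id != target_id]
  if (!length(others))
    stop("isolated colony: no other gravid colony for '", target_id,
         "'; nearest-neighbour distance undefined", call. = FALSE)
  min(dists[target_id, others])
}

#' Count of gravid colonies within a radius
#'
#' Number of *other* gravid colonies at distance <= `radius` (closed
#' boundary: a neighbour exactly at the radius counts).
#'
#' @inheritParams nearest_gravid_neighbor
#' @param radius Radius in metres, > 0.
#' @return Integer count.
#' @export
density_within <- function(target_id, colonies, radius, dists = NULL) {
  stopifnot(radius > 0)
  if (is.null(dists)) dists <- pairwise_distances(colonies)
  others <- colonies$colony_id[colonies$gravid &
                                 colonies$colony_id != target_id]
  sum(dists[target_id, others] <= radius)
}

#' Distance-weighted gravid colony area within a radius
#'
#' Total planar area of other gravid colonies within `radius`, with each
#' neighbour's area down-weighted exponentially with distance,
#' `area * exp(-d / lambda)`, to reflect the dilution of gametes expected
#' with increasing separation. The focal colony's own area is excluded.
#'
#' @inheritParams density_within
#' @param lambda Exponential decay length in metres, > 0.
#' @return Weighted area in m^2.
#' @export
weighted_colony_area <- function(target_id, colonies, radius, lambda = 5,
                                 dists = NULL) {
  stopifnot(radius > 0, lambda > 0)
  if (is.null(dists)) dists <- pairwise_distances(colonies)
  keep <- colonies$gravid & colonies$colony_id != target_id
  d <- dists[target_id, colonies$colony_id[keep]]
  a <- colonies$planar_area[keep]
  sum(a[d <= radius] * exp(-d[d <= radius] / lambda))
}

#' Neighbourhood metrics for a set of focal colonies
#'
#' Assembles, for each focal colony, the nearest-gravid-neighbour distance,
#' the gravid-colony counts within each configured radius and the
#' distance-weighted gravid area, from a single pairwise-distance matrix.
#'
#' @param targets Character vector of focal colony ids (default: all gravid
#'   colonies in `colonies`).
#' @param colonies Colony table.
#' @param config A [run_config()]; supplies radii, weighted-area window and
#'   decay length.
#' @return A `data.frame` with columns `colony_id`, `nn_m`,
#'   `density_<r>m` for each radius, and `weighted_area_<R>m_m2`; the
#'   weighting settings are attached as attribute `"meta"`.
#' @export
compute_all_metrics <- function(targets = NULL, colonies,
                                config = run_config()) {
  if (is.null(targets)) targets <- colonies$colony_id[colonies$gravid]
  stopifnot(all(targets %in% colonies$colony_id))
  dists <- pairwise_distances(colonies)
  out <- data.frame(colony_id = targets, stringsAsFactors = FALSE)
  out$nn_m <- vapply(targets, nearest_gravid_neighbor, numeric(1),
                     colonies = colonies, dists = dists)
  for (r in config$radii)
    out[[paste0("density_", r, "m")]] <-
      vapply(targets, density_within, numeric(1), colonies = colonies,
             radius = r, dists = dists)
  out[[paste0("weighted_area_", config$wa_radius, "m_m2")]] <-
    vapply(targets, weighted_colony_area, numeric(1), colonies = colonies,
           radius = config$wa_radius, lambda = config$lambda, dists = dists)
  attr(out, "meta") <- list(radii = config$radii,
                            wa_radius = config$wa_radius,
                            lambda = config$lambda)
  class(out) <- c("neighborhood_metrics", "data.frame")
  out
}
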