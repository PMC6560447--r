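#' Constrained mixture region
#'
#' A mixture region is the set \{l_i <= x_i <= u_i, sum(x_i) = total\}: a
#' simplex truncated by per-component lower and upper bounds. Doses are
#' expressed in percent of flour weight; the hydrocolloid study this package
#' ships as reference data fixes the total at 4\% flour weight with xanthan
#' and guar in [0.04, 0.60] and HPMC in [2.80, 3.60].
#'
#' @param lower named numeric vector of per-component lower bounds. Names
#'   become the component names.
#' @param upper numeric vector of upper bounds, same length/order as `lower`.
#' @param total fixed mixture total (same units as the bounds).
#' @return An object of class `mixture_region` with elements `components`,
#'   `lower`, `upper`, `total`.
#' @examples
#' hydrocolloid_region()
#' mixture_region(c(a = 0, b = 0, c = 0), c(4, 4, 4), total = 4)
#' @export
mixture_region <- function(lower, upper, total) {
  if (is.null(names(lower))) {
    names(lower) <- paste0("x", seq_along(lower))
  }
  if (length(upper) != length(lower)) {
    stop("`lower` and `upper` must have the same length")
  }
  upper <- stats::setNames(as.numeric(upper), names(lower))
  lower <- stats::setNames(as.numeric(lower), names(lower))
  if (any(lower > upper)) {
    stop("infeasible region: lower bound exceeds upper bound for ",
         paste(names(lower)[lower > upper], collapse = ", "))
  }
  if (sum(lower) > total + 1e-9 || sum(upper) < total - 1e-9) {
    stop("infeasible region: total ", total,
         " is outside [sum(lower), sum(upper)] = [",
         sum(lower), ", ", sum(upper), "]")
  }
  structure(
    list(components = names(lower), lower = lower, upper = upper,
         total = as.numeric(total)),
    class = "mixture_region"
  )
}

#' @export
print.mixture_region <- function(x, ...) {
  cat("Mixture region (", length(x$components), " components, total = ",
      x$total, ")\n", sep = "")
  print(data.frame(lower = x$lower, upper = x$upper, row.names = x$components))
  invisible(x)
}

#' Bounded region of the reference hydrocolloid study
#'
#' Convenience constructor for the xanthan/guar/HPMC region used throughout
#' the package: XG, GG in [0.04, 0.60]\%, HPMC in [2.80, 3.60]\%, total 4\%
#' flour weight.
#' @return A `mixture_region`.
#' @export
hydrocolloid_region <- function() {
  mixture_region(
    lower = c(xanthan = 0.04, guar = 0.04, hpmc = 2.80),
    upper = c(xanthan = 0.60, guar = 0.60, hpmc = 3.60),
    total = 4.0
  )
}

#' Membership test for a mixture region
#'
#' @param region a `mixture_region`.
#' @param x numeric vector of doses (one per component) or a matrix/data frame
#'   with one row per point.
#' @param tol numeric tolerance on bounds and total.
#' @return logical vector, one entry per point.
#' @export
region_contains <- function(region, x, tol = 1e-9) {
  x <- as_dose_matrix(x, region)
  within_bounds <- apply(x, 1, function(p) {
    all(p >= region$lower - tol) && all(p <= region$upper + tol)
  })
  within_bounds & abs(rowSums(x) - region$total) <= tol
}

# coerce points (vector, matrix, data frame possibly with extra columns)
# to a numeric matrix with one column per region component
as_dose_matrix <- function(x, region) {
  k <- length(region$components)
  if (is.null(dim(x))) {
    x <- matrix(as.numeric(x), ncol = k, byrow = TRUE)
    colnames(x) <- region$components
    return(x)
  }
  x <- as.data.frame(x)
  if (all(region$components %in% names(x))) {
    x <- x[, region$components, drop = FALSE]
  } else {
    x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE][, seq_len(k), drop = FALSE]
    names(x) <- region$components
  }
  as.matrix(x)
}

#' Extreme vertices of a bounded mixture region
#'
#' Enumerates the corner points of the polytope \{l <= x <= u, sum(x) = total\}
#' by fixing all but one component at a bound, solving the remaining component
#' from the total, and keeping feasible points. For three components this is
#' the closed-form pairwise active-bound construction; the same enumeration
#' applies to more components (every vertex has at least k-1 active bounds).
#'
#' @param region a `mixture_region`.
#' @param tol feasibility/deduplication tolerance.
#' @return A data frame with the component doses, one row per vertex, in
#'   lexicographic dose order, with a `role` column set to `"vertex"`.
#' @examples
#' extreme_vertices(hydrocolloid_region())
#' @export
extreme_vertices <- function(region, tol = 1e-9) {
  k <- length(region$components)
  fixed_sets <- utils::combn(k, k - 1, simplify = FALSE)
  pts <- list()
  for (fixed in fixed_sets) {
    free <- setdiff(seq_len(k), fixed)
    levels <- expand.grid(rep(list(c(FALSE, TRUE)), k - 1)) # FALSE=lower
    for (r in seq_len(nrow(levels))) {
      p <- numeric(k)
      p[fixed] <- ifelse(unlist(levels[r, ]),
                         region$upper[fixed], region$lower[fixed])
      p[free] <- region$total - sum(p[fixed])
      if (p[free] >= region$lower[free] - tol &&
          p[free] <= region$upper[free] + tol) {
        pts[[length(pts) + 1L]] <- pmin(pmax(p, region$lower), region$upper)
      }
    }
  }
  if (length(pts) == 0L) {
    stop("infeasible region: no extreme vertices")
  }
  m <- do.call(rbind, pts)
  m <- m[!duplicated(round(m / tol) * tol), , drop = FALSE]
  m <- m[do.call(order, as.data.frame(m)), , drop = FALSE]
  out <- as.data.frame(m)
  names(out) <- region$components
  out$role <- "vertex"
  rownames(out) <- NULL
  out
}

# active-bound signature of points: list of character vectors like "xanthan-"
# (lower active) / "hpmc+" (upper active)
active_bounds <- function(points, region, tol = 1e-9) {
  m <- as_dose_matrix(points, region)
  lapply(seq_len(nrow(m)), function(i) {
    p <- m[i, ]
    c(paste0(region$components[abs(p - region$lower) <= tol], "-"),
      paste0(region$components[abs(p - region$upper) <= tol], "+"))
  })
}

#' Edge centroids of a bounded mixture region
#'
#' Midpoints of the polytope edges. Two vertices of a three-component bounded
#' mixture region are joined by an edge exactly when they share one active
#' bound (same component, same side).
#'
#' @param vertices data frame of vertices as returned by [extreme_vertices()].
#' @param region the `mixture_region` the vertices belong to.
#' @param tol active-bound tolerance.
#' @return Data frame of deduplicated edge midpoints with `role`
#'   `"edge-centroid"`.
#' @export
edge_centroids <- function(vertices, region, tol = 1e-9) {
  m <- as_dose_matrix(vertices, region)
  if (nrow(m) < 2) stop("need at least two vertices")
  act <- active_bounds(m, region, tol)
  mids <- list()
  for (i in seq_len(nrow(m) - 1)) {
    for (j in seq(i + 1, nrow(m))) {
      if (length(intersect(act[[i]], act[[j]])) >= 1) {
        mids[[length(mids) + 1L]] <- (m[i, ] + m[j, ]) / 2
      }
    }
  }
  if (length(mids) == 0L) {
    return(stats::setNames(
      cbind(as.data.frame(matrix(numeric(0), ncol = ncol(m))),
            data.frame(role = character(0))),
      c(region$components, "role")))
  }
  mm <- do.call(rbind, mids)
  mm <- mm[!duplicated(round(mm / 1e-9) * 1e-9), , drop = FALSE]
  mm <- mm[do.call(order, as.data.frame(mm)), , drop = FALSE]
  out <- as.data.frame(mm)
  names(out) <- region$components
  out$role <- "edge-centroid"
  rownames(out) <- NULL
  out
}

#' Overall centroid of a vertex set
#'
#' @param vertices data frame or matrix of vertices.
#' @param region the `mixture_region`.
#' @return One-row data frame with `role` `"overall-centroid"`.
#' @export
overall_centroid <- function(vertices, region) {
  m <- as_dose_matrix(vertices, region)
  if (nrow(m) < 1) stop("need at least one vertex")
  out <- as.data.frame(t(colMeans(m)))
  names(out) <- region$components
  out$role <- "overall-centroid"
  out
}

#' Candidate set for constrained mixture designs
#'
#' Stacks extreme vertices, edge centroids and the overall centroid of the
#' region — the classical candidate geometry for D-optimal point selection in
#' bounded mixture experiments.
#'
#' @param region a `mixture_region`.
#' @return Data frame of candidate points with a `role` column.
#' @examples
#' candidate_points(hydrocolloid_region())
#' @export
candidate_points <- function(region) {
  v <- extreme_vertices(region)
  rbind(v, edge_centroids(v, region), overall_centroid(v, region))
}

#' Convert between actual doses and coded fractions
#'
#' Coded fractions are actual doses divided by the mixture total, so that the
#' coded components of any blend sum to one.
#'
#' @param x doses (vector, matrix or data frame) for `to_coded`; coded
#'   fractions for `to_actual`.
#' @param region a `mixture_region`.
#' @return Matrix of coded fractions (or actual doses), one row per point.
#' @examples
#' to_coded(c(0.36, 0.04, 3.60), hydrocolloid_region())
#' @export
to_coded <- function(x, region) {
  as_dose_matrix(x, region) / region$total
}

#' @rdname to_coded
#' @export
to_actual <- function(x, region) {
  as_dose_matrix(x, region) * region$total
}
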