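#' Grayscale crumb image with spatial calibration
#'
#' Wraps an 8-bit grayscale intensity matrix (0-255) together with its
#' spatial resolution in pixels per cm. Scanned bread slices in the reference
#' study use 138 px/cm; pores (cells) image darker than the crumb matrix.
#'
#' @param x numeric matrix of intensities in [0, 255], or a path to a PNG or
#'   TIFF file (color inputs are converted by luminance).
#' @param ppcm spatial resolution, pixels per cm (default 138).
#' @param provenance free-text provenance tag.
#' @return Object of class `crumb_image` with elements `pixels`, `ppcm`,
#'   `provenance`.
#' @export
crumb_image <- function(x, ppcm = 138, provenance = "") {
  if (is.character(x)) {
    img <- EBImage::readImage(x)
    if (EBImage::colorMode(img) != EBImage::Grayscale) {
      img <- EBImage::channel(img, "luminance")
    }
    x <- EBImage::imageData(img) * 255
    if (length(dim(x)) > 2) x <- x[, , 1]
  }
  x <- as.matrix(x)
  if (!length(x)) stop("empty image")
  if (ppcm <= 0) stop("resolution must be positive")
  structure(list(pixels = x, ppcm = as.numeric(ppcm),
                 provenance = provenance),
            class = "crumb_image")
}

#' @export
print.crumb_image <- function(x, ...) {
  cat("Crumb image ", nrow(x$pixels), " x ", ncol(x$pixels), " px at ",
      x$ppcm, " px/cm (", round(nrow(x$pixels) / x$ppcm, 2), " x ",
      round(ncol(x$pixels) / x$ppcm, 2), " cm)\n", sep = "")
  invisible(x)
}

#' Write a crumb image to PNG or TIFF
#'
#' @param image a `crumb_image`.
#' @param path output path; format follows the file extension.
#' @export
write_crumb_image <- function(image, path) {
  EBImage::writeImage(EBImage::Image(pmin(pmax(image$pixels / 255, 0), 1)),
                      path)
  invisible(path)
}

#' Centered square crop of a crumb image
#'
#' Crops a `side_cm` x `side_cm` field of view (rounded to whole pixels) from
#' the image center — the standard 3.9 cm field used for crumb-grain
#' analysis.
#'
#' @param image a `crumb_image`.
#' @param side_cm side of the square field of view in cm (default 3.9).
#' @return A cropped `crumb_image`.
#' @export
crop_center <- function(image, side_cm = 3.9) {
  px <- round(side_cm * image$ppcm)
  d <- dim(image$pixels)
  if (any(d < px)) {
    stop("image (", d[1], " x ", d[2], " px) smaller than the ", px,
         " px crop")
  }
  r0 <- floor((d[1] - px) / 2)
  c0 <- floor((d[2] - px) / 2)
  crumb_image(image$pixels[(r0 + 1):(r0 + px), (c0 + 1):(c0 + px)],
              image$ppcm, image$provenance)
}

# k-means++ initial centers for 1-D intensities, deterministic given the
# current RNG state
kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  if (k > 1) {
    for (i in 2:k) {
      d2 <- vapply(x, function(v) min((v - centers[1:(i - 1)])^2), numeric(1))
      if (sum(d2) == 0) {
        centers[i] <- x[sample.int(length(x), 1)]
      } else {
        centers[i] <- x[sample.int(length(x), 1, prob = d2)]
      }
    }
  }
  centers
}

# merge 4-connected labels that touch diagonally, giving 8-connectivity
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab)
  nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  n <- max(lab)
  if (n == 0 || nrow(pairs) == 0) return(lab)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1])
    rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# drop components below min_size px and relabel contiguously from 1
filter_small <- function(lab, min_size) {
  if (max(lab) == 0) return(lab)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_size)
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Binary k-means segmentation of a crumb image
#'
#' Clusters pixel intensities with k-means (k-means++ seeding); the cluster
#' with the lower mean intensity becomes the cell (pore) phase, since pores
#' image darker in reflected scans. Connected cells are labeled with
#' 8-connectivity and components below the minimum size are discarded.
#' Deterministic given `seed`.
#'
#' @param image a `crumb_image`.
#' @param k number of intensity clusters (default 2).
#' @param seed integer seed.
#' @param max_iter k-means iteration cap.
#' @param min_size minimum component size in pixels (default 4).
#' @param dark_cells `TRUE` (default) takes the darker cluster as cells.
#' @return Object of class `crumb_segmentation`: list with `mask` (logical
#'   matrix, cell = TRUE), `labels` (integer matrix, 0 = background),
#'   `centroids` (cluster mean intensities), `n_cells`, `min_size`,
#'   `degenerate` flag.
#' @export
kmeans_segment <- function(image, k = 2, seed = 1L, max_iter = 100L,
                           min_size = 4L, dark_cells = TRUE) {
  px <- image$pixels
  v <- as.vector(px)
  if (length(unique(v)) < k) {
    warning("degenerate image: fewer than k distinct intensities")
    lab <- matrix(0L, nrow(px), ncol(px))
    return(structure(list(mask = lab > 0, labels = lab,
                          centroids = rep(mean(v), k), n_cells = 0L,
                          min_size = min_size, degenerate = TRUE),
                     class = "crumb_segmentation"))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  # seed k-means++ on a subsample for speed; exact assignment comes from the
  # Lloyd iterations over all pixels
  sub <- if (length(v) > 20000) v[sample.int(length(v), 20000)] else v
  centers <- kmeanspp_centers(sub, k)
  km <- suppressWarnings(
    stats::kmeans(v, centers = matrix(centers, ncol = 1),
                  iter.max = max_iter, algorithm = "Lloyd"))
  cents <- as.vector(km$centers)
  cell_cluster <- if (dark_cells) which.min(cents) else which.max(cents)
  mask <- matrix(km$cluster == cell_cluster, nrow(px), ncol(px))
  lab4 <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(px), ncol(px)))
  lab <- merge_diagonal_labels(matrix(as.integer(lab4), nrow(px), ncol(px)))
  lab <- filter_small(lab, min_size)
  mask <- lab > 0
  structure(list(mask = mask, labels = lab, centroids = cents,
                 n_cells = max(lab), min_size = min_size, degenerate = FALSE),
            class = "crumb_segmentation")
}

#' @export
print.crumb_segmentation <- function(x, ...) {
  cat("Crumb segmentation: ", x$n_cells, " cells, ",
      round(100 * mean(x$mask), 1), "% of field",
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Crumb-grain features from a segmented image
#'
#' Mean cell area MCA (mm^2, average labeled-component area), cell density
#' CDE (components per mm^2 of field) and void fraction VFR (fraction of the
#' field occupied by cells). VFR = CDE x MCA holds by construction.
#'
#' @param seg a `crumb_segmentation`.
#' @param image the `crumb_image` it was computed from (supplies the
#'   calibration).
#' @return Object of class `grain_features`: list with `mca`, `cde`, `vfr`,
#'   `n_cells`, `field_mm2` and a `no_cells` flag (MCA reported as 0 when the
#'   mask is empty).
#' @export
grain_features <- function(seg, image) {
  if (!identical(dim(seg$mask), dim(image$pixels))) {
    stop("segmentation does not match the image")
  }
  px_area_mm2 <- (10 / image$ppcm)^2
  n_px <- length(image$pixels)
  field_mm2 <- n_px * px_area_mm2
  n_cells <- seg$n_cells
  cell_px <- sum(seg$mask)
  if (n_cells == 0) {
    out <- list(mca = 0, cde = 0, vfr = 0, n_cells = 0L,
                field_mm2 = field_mm2, no_cells = TRUE)
  } else {
    mca <- (cell_px / n_cells) * px_area_mm2
    cde <- n_cells / field_mm2
    out <- list(mca = mca, cde = cde, vfr = cell_px / n_px,
                n_cells = as.integer(n_cells), field_mm2 = field_mm2,
                no_cells = FALSE)
  }
  class(out) <- "grain_features"
  out
}

#' @export
print.grain_features <- function(x, ...) {
  cat(sprintf(
    "Grain features: MCA %.3f mm^2, CDE %.4f cells/mm^2, VFR %.3f (%d cells)\n",
    x$mca, x$cde, x$vfr, x$n_cells))
  invisible(x)
}

#' Synthetic crumb image of dark quasi-circular cells
#'
#' Generates a bright background (intensity ~200) scattered with dark
#' (~60) circular cells of lognormal-ish radius spread, optional Gaussian
#' pixel noise, and returns the exact geometric ground truth computed from
#' the noiseless mask. Cells are placed without overlap (bounded retries)
#' unless `allow_overlap`.
#'
#' @param n_cells number of cells to place.
#' @param radius_px mean cell radius in pixels.
#' @param radius_sd_px SD of the cell radius in pixels.
#' @param field_cm side of the square field in cm (default 3.9).
#' @param ppcm resolution in px/cm (default 138).
#' @param noise_sd Gaussian pixel-noise SD in intensity units.
#' @param seed integer seed.
#' @param bg,fg background and cell intensities.
#' @param allow_overlap allow cells to overlap (ground truth then counts the
#'   merged geometry as drawn).
#' @param max_tries placement retries per cell before failing.
#' @return List with `image` (a `crumb_image`), `mask` (logical ground-truth
#'   mask) and `truth` (a `grain_features` computed from the clean mask).
#' @export
synth_crumb_image <- function(n_cells, radius_px = 5, radius_sd_px = 0,
                              field_cm = 3.9, ppcm = 138, noise_sd = 0,
                              seed = 1L, bg = 200, fg = 60,
                              allow_overlap = FALSE, max_tries = 200L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  side <- round(field_cm * ppcm)
  mask <- matrix(FALSE, side, side)
  centers <- matrix(numeric(0), ncol = 3) # x, y, r
  if (n_cells > 0) {
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r <- max(1, stats::rnorm(1, radius_px, radius_sd_px))
        cx <- stats::runif(1, r + 1, side - r)
        cy <- stats::runif(1, r + 1, side - r)
        ok <- allow_overlap || nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                centers[, 3] + r + 1)
        if (ok) {
          centers <- rbind(centers, c(cx, cy, r))
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place cell ", i, " after ", max_tries,
                        " tries; reduce n_cells or radius")
    }
    xs <- matrix(rep(seq_len(side), side), side, side)
    ys <- t(xs)
    for (i in seq_len(nrow(centers))) {
      mask <- mask | ((xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <=
                        centers[i, 3]^2)
    }
  }
  clean <- matrix(bg, side, side)
  clean[mask] <- fg
  noisy <- clean + stats::rnorm(length(clean), 0, noise_sd)
  img <- crumb_image(pmin(pmax(noisy, 0), 255), ppcm,
                     provenance = "synthetic")
  lab <- merge_diagonal_labels(
    matrix(as.integer(EBImage::bwlabel(matrix(as.numeric(mask),
                                              side, side))), side, side))
  seg <- structure(list(mask = mask, labels = lab, centroids = c(fg, bg),
                        n_cells = max(lab), min_size = 0L,
                        degenerate = FALSE),
                   class = "crumb_segmentation")
  truth <- grain_features(seg, crumb_image(clean, ppcm))
  list(image = img, mask = mask, truth = truth)
}
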