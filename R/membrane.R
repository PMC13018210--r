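# Membrane-deformation statistic and protein-membrane distance analysis on
# coordinate frames (trajectory snapshots or synthetic surfaces).
#
# The deformation index D tiles the x-y plane into square patches, fits a
# plane to each occupied patch by total least squares, and averages the
# absolute dot product between the patch unit normals and the z axis:
# D = 1 for a flat bilayer, smaller the more the surface is deformed.

#' Construct a coordinate frame
#'
#' @param membrane Numeric matrix (n x 3) of membrane marker positions
#'   (e.g. lipid headgroup beads).
#' @param protein Optional numeric matrix (m x 3) of protein positions.
#' @param time Frame time (arbitrary units).
#' @param box Optional periodic extents `c(Lx, Ly)` for minimum-image
#'   distance calculations.
#' @return Object of class `membrane_frame`.
#' @export
membrane_frame <- function(membrane, protein = NULL, time = 0, box = NULL) {
  membrane <- as.matrix(membrane)
  if (ncol(membrane) != 3 || nrow(membrane) < 3)
    stopf("membrane must be an n x 3 matrix with n >= 3")
  if (!all(is.finite(membrane))) stopf("non-finite membrane coordinates")
  if (!is.null(protein)) {
    protein <- as.matrix(protein)
    if (ncol(protein) != 3) stopf("protein must be an m x 3 matrix")
    if (!all(is.finite(protein))) stopf("non-finite protein coordinates")
  }
  structure(list(time = time, membrane = membrane, protein = protein,
                 box = box), class = "membrane_frame")
}

#' Read coordinate frames from CSV
#'
#' Expected columns: `frame`, `role` (`membrane` or `protein`), `x`, `y`,
#' `z`. One `membrane_frame` is returned per distinct `frame` value, in
#' order.
#'
#' @param path CSV path.
#' @param box Optional periodic extents `c(Lx, Ly)` applied to every frame.
#' @return List of `membrane_frame` objects.
#' @export
read_membrane_csv <- function(path, box = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "role", "x", "y", "z")
  if (!all(need %in% names(df)))
    stopf("frames CSV must have columns: %s", paste(need, collapse = ", "))
  lapply(split(df, factor(df$frame, levels = unique(df$frame))), function(g) {
    mem <- as.matrix(g[g$role == "membrane", c("x", "y", "z")])
    pro <- g[g$role == "protein", c("x", "y", "z")]
    membrane_frame(mem, if (nrow(pro)) as.matrix(pro) else NULL,
                   time = g$frame[1], box = box)
  })
}

# total-least-squares patch normal: smallest principal direction of the
# centred covariance, oriented to positive z; NULL if degenerate.
# A reliable plane fit needs a two-dimensional x-y footprint: patches whose
# points line up (minor/major footprint spread below 1e-6) leave the normal
# tilt unidentified and are skipped.
patch_normal <- function(pts) {
  if (nrow(pts) < 3) return(NULL)
  centered <- sweep(pts, 2, colMeans(pts))
  xy <- crossprod(centered[, 1:2, drop = FALSE]) / nrow(pts)
  exy <- eigen(xy, symmetric = TRUE, only.values = TRUE)$values
  if (exy[1] <= 0 || exy[2] <= 1e-6 * exy[1]) return(NULL)
  cov <- crossprod(centered) / nrow(pts)
  ev <- eigen(cov, symmetric = TRUE)
  n <- ev$vectors[, 3]
  if (n[3] < 0) n <- -n
  n
}

#' Membrane deformation index
#'
#' Tiles the x-y plane into `patch_size` squares, fits a plane to the
#' membrane points of each occupied patch by total least squares (the
#' smallest principal direction of the centred covariance is the patch
#' normal, oriented to positive z), and returns the mean absolute dot
#' product between patch normals and the z axis. A flat membrane gives
#' `D = 1`; deformation lowers D. Patches with fewer than 3 points or with
#' collinear points are skipped and counted in `n_skipped`.
#'
#' @param frame A `membrane_frame` or an n x 3 matrix of membrane points.
#' @param patch_size Patch edge length in the coordinate units.
#' @return List of class `deformation_result`: `D` (in `[0, 1]`), `normals`
#'   (k x 3 matrix), `n_patches`, `n_skipped`, `grid_dim`.
#' @export
deformation_index <- function(frame, patch_size) {
  pts <- if (inherits(frame, "membrane_frame")) frame$membrane else
    as.matrix(frame)
  stopifnot(patch_size > 0)
  ix <- floor((pts[, 1] - min(pts[, 1])) / patch_size)
  iy <- floor((pts[, 2] - min(pts[, 2])) / patch_size)
  key <- paste(ix, iy)
  patches <- split.data.frame(pts, factor(key, levels = unique(key)))
  normals <- list(); skipped <- 0L
  for (p in patches) {
    n <- patch_normal(as.matrix(p))
    if (is.null(n)) skipped <- skipped + 1L else
      normals[[length(normals) + 1L]] <- n
  }
  if (!length(normals))
    stopf("all %d patches degenerate (collinear or < 3 points)",
          length(patches))
  nm <- do.call(rbind, normals)
  structure(list(D = mean(abs(nm[, 3])), normals = nm,
                 n_patches = length(normals), n_skipped = skipped,
                 grid_dim = c(length(unique(ix)), length(unique(iy)))),
            class = "deformation_result")
}

#' @export
print.deformation_result <- function(x, ...) {
  cat(sprintf(
    "deformation index D = %.6f over %d patches (%d skipped as degenerate)\n",
    x$D, x$n_patches, x$n_skipped))
  invisible(x)
}

#' Minimum protein-membrane distance per frame
#'
#' For each frame, the minimum Euclidean distance between any protein point
#' and any membrane point. When a frame carries periodic `box` extents, the
#' minimum-image convention is applied in x and y.
#'
#' @param frames A `membrane_frame` or list of them (each with protein
#'   points).
#' @return Data.frame with columns `time` and `d_min`.
#' @export
min_distance_series <- function(frames) {
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  rows <- lapply(frames, function(f) {
    if (is.null(f$protein)) stopf("frame at time %s has no protein points",
                                  format(f$time))
    d2min <- Inf
    for (i in seq_len(nrow(f$protein))) {
      dx <- f$membrane[, 1] - f$protein[i, 1]
      dy <- f$membrane[, 2] - f$protein[i, 2]
      dz <- f$membrane[, 3] - f$protein[i, 3]
      if (!is.null(f$box)) {
        dx <- dx - f$box[1] * round(dx / f$box[1])
        dy <- dy - f$box[2] * round(dy / f$box[2])
      }
      d2 <- dx * dx + dy * dy + dz * dz
      d2min <- min(d2min, min(d2))
    }
    data.frame(time = f$time, d_min = sqrt(d2min))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample a surface z = f(x, y) on a regular grid
#'
#' Convenience generator for synthetic membrane surfaces (flat, tilted,
#' sinusoidal) used in validation.
#'
#' @param f Function of `(x, y)` returning z.
#' @param xlim,ylim Extents.
#' @param step Grid spacing.
#' @return n x 3 matrix of points.
#' @export
grid_surface <- function(f, xlim = c(0, 10), ylim = c(0, 10), step = 0.5) {
  g <- expand.grid(x = seq(xlim[1], xlim[2], by = step),
                   y = seq(ylim[1], ylim[2], by = step))
  cbind(x = g$x, y = g$y, z = mapply(f, g$x, g$y))
}
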