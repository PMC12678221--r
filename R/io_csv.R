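#' Lumen surface point cloud
#'
#' Container for unordered lumen-surface points in mm as exported by a
#' segmentation tool. The x axis is the image slice direction (right-handed
#' frame); `slice_spacing_dx` is the spacing between image slices.
#'
#' @param points numeric matrix or data frame with columns x, y, z (mm).
#' @param slice_spacing_dx slice spacing in mm; when `NULL`, the median gap
#'   between distinct sorted x values is used.
#' @param meta free-form provenance text.
#' @return object of class `raw_point_cloud`.
#' @export
raw_point_cloud <- function(points, slice_spacing_dx = NULL, meta = "") {
  pts <- as.matrix(points[, 1:3, drop = FALSE])
  storage.mode(pts) <- "double"
  colnames(pts) <- c("x", "y", "z")
  if (nrow(pts) < 4L) stop("point cloud needs at least 4 points")
  if (!all(is.finite(pts))) stop("point cloud has non-finite coordinates")
  if (is.null(slice_spacing_dx)) {
    ux <- sort(unique(pts[, "x"]))
    if (length(ux) < 2L) stop("cannot infer slice spacing from a single slice")
    slice_spacing_dx <- stats::median(diff(ux))
  }
  if (!is.finite(slice_spacing_dx) || slice_spacing_dx <= 0)
    stop("slice_spacing_dx must be > 0")
  structure(list(points = pts, slice_spacing_dx = slice_spacing_dx,
                 meta = as.character(meta)),
            class = "raw_point_cloud")
}

#' @export
print.raw_point_cloud <- function(x, ...) {
  cat(sprintf("raw_point_cloud: %d points, slice spacing %.4g mm\n",
              nrow(x$points), x$slice_spacing_dx))
  invisible(x)
}

#' Read a lumen point cloud from CSV
#'
#' Expects a header `x,y,z` with coordinates in mm. When `slice_spacing_dx`
#' is not given it defaults to the median spacing of the distinct sorted x
#' values.
#'
#' @param path CSV file path.
#' @param slice_spacing_dx optional slice spacing (mm).
#' @return a [raw_point_cloud()].
#' @export
read_point_cloud_csv <- function(path, slice_spacing_dx = NULL) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) stop("CSV must have columns x,y,z")
  m <- as.matrix(df[, need])
  if (!is.numeric(m) || anyNA(m)) stop("non-numeric rows in point cloud CSV")
  raw_point_cloud(m, slice_spacing_dx, meta = path)
}

#' Write a lumen point cloud to CSV
#' @param cloud a `raw_point_cloud`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_point_cloud_csv <- function(cloud, path) {
  utils::write.csv(as.data.frame(cloud$points), path, row.names = FALSE)
  invisible(path)
}

#' Per-facet wall-shear field
#'
#' Holds one wall-shear sample per mesh facet, either as the full shear
#' vector (Pa) or as the signed flow-direction component tau_x (positive
#' opposite to the flow).
#'
#' @param facet_area facet areas (mm^2), all > 0.
#' @param tau_vec optional n x 3 matrix of shear vectors (Pa).
#' @param tau_x optional signed flow-direction component (Pa).
#' @param time_stamp optional time stamp (s).
#' @return object of class `wall_field`.
#' @export
wall_field <- function(facet_area, tau_vec = NULL, tau_x = NULL,
                       time_stamp = NULL) {
  facet_area <- as.numeric(facet_area)
  if (any(!is.finite(facet_area)) || any(facet_area <= 0))
    stop("facet areas must be finite and > 0")
  n <- length(facet_area)
  if (is.null(tau_vec) && is.null(tau_x))
    stop("one of tau_vec or tau_x is required")
  if (!is.null(tau_vec)) {
    tau_vec <- as.matrix(tau_vec)
    if (nrow(tau_vec) != n) stop("tau_vec length must equal facet count")
  }
  if (!is.null(tau_x)) {
    tau_x <- as.numeric(tau_x)
    if (length(tau_x) != n) stop("tau_x length must equal facet count")
  }
  structure(list(facet_area = facet_area, tau_vec = tau_vec, tau_x = tau_x,
                 time_stamp = time_stamp),
            class = "wall_field")
}

#' Read a per-facet wall-shear field from CSV
#'
#' Accepts `area,tau_x` (signed flow-direction component) or
#' `area,tx,ty,tz` (full shear vector), areas in mm^2 and stresses in Pa.
#'
#' @param path CSV file path.
#' @return a [wall_field()].
#' @export
read_wall_field_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"area" %in% names(df)) stop("CSV must have an 'area' column")
  if (all(c("tx", "ty", "tz") %in% names(df))) {
    wall_field(df$area, tau_vec = as.matrix(df[, c("tx", "ty", "tz")]))
  } else if ("tau_x" %in% names(df)) {
    wall_field(df$area, tau_x = df$tau_x)
  } else stop("CSV must have tau_x or tx,ty,tz columns")
}
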