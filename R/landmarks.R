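#' Bony landmark vocabulary
#'
#' Eight region landmarks are analyzed for local reconstruction accuracy:
#' five femoral (posterior lateral/medial condyle, lateral/medial distal
#' condyle, anterior cortex) and three tibial (lateral/medial plateau,
#' tuberosity). The femoral epicondyles are additionally carried as
#' axis-endpoint landmarks: they define the trans-epicondylar axis but are
#' not part of the region analysis.
#'
#' @param bone `"femur"`, `"tibia"` or `"all"`.
#' @param role `"region"` (default), `"axis"` or `"all"`.
#' @return character vector of landmark names.
#' @export
landmark_names <- function(bone = c("all", "femur", "tibia"),
                           role = c("region", "axis", "all")) {
  bone <- match.arg(bone)
  role <- match.arg(role)
  tab <- landmark_table()
  if (bone != "all") tab <- tab[tab$bone == bone, ]
  if (role != "all") tab <- tab[tab$role == role, ]
  tab$landmark
}

landmark_table <- function() {
  data.frame(
    landmark = c("posterior_lateral_condyle", "posterior_medial_condyle",
                 "lateral_distal_condyle", "medial_distal_condyle",
                 "anterior_cortex",
                 "lateral_plateau", "medial_plateau", "tuberosity",
                 "lateral_epicondyle", "medial_epicondyle"),
    bone = c(rep("femur", 5L), rep("tibia", 3L), rep("femur", 2L)),
    role = c(rep("region", 8L), rep("axis", 2L))
  )
}

#' Observer landmark annotations
#'
#' Validates and normalizes a table of single-point landmark annotations:
#' one row per (landmark, observer, repeat) on one model. The study design
#' emulated here presents each model twice to each of three observers, so a
#' complete set carries 6 annotations per landmark.
#'
#' @param df data.frame with columns `patient_id`, `bone`, `side`,
#'   `model_source`, `landmark`, `observer_id`, `repeat_index`, `x`, `y`,
#'   `z` (mm).
#' @return the validated data.frame with class `landmark_annotations`.
#' @export
landmark_annotations <- function(df) {
  need <- c("patient_id", "bone", "side", "model_source", "landmark",
            "observer_id", "repeat_index", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("annotation table lacks columns: ", paste(missing_cols, collapse = ", "))
  tab <- landmark_table()
  bad <- !df$landmark %in% tab$landmark
  if (any(bad)) stop("unknown landmark names: ",
                     paste(unique(df$landmark[bad]), collapse = ", "))
  expected_bone <- tab$bone[match(df$landmark, tab$landmark)]
  if (any(df$bone != expected_bone))
    stop("landmark/bone mismatch: ",
         paste(unique(df$landmark[df$bone != expected_bone]), collapse = ", "))
  if (!all(df$model_source %in% c("prediction", "ground_truth")))
    stop("model_source must be prediction or ground_truth")
  if (any(duplicated(df[, c("patient_id", "bone", "model_source", "landmark",
                            "observer_id", "repeat_index")])))
    stop("duplicate (landmark, observer, repeat) annotation")
  stopifnot(all(is.finite(df$x)), all(is.finite(df$y)), all(is.finite(df$z)))
  class(df) <- c("landmark_annotations", "data.frame")
  df
}

#' Read landmark annotations from JSON
#'
#' Expects an array of objects with fields `patient_id`, `bone`, `side`,
#' `model_source`, `landmark`, `observer_id`, `repeat_index` and
#' `point_mm` (length-3 array).
#'
#' @param path JSON file path.
#' @return a [landmark_annotations()] table.
#' @export
read_annotations_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  pts <- do.call(rbind, raw$point_mm)
  df <- data.frame(patient_id = raw$patient_id, bone = raw$bone,
                   side = raw$side, model_source = raw$model_source,
                   landmark = raw$landmark, observer_id = raw$observer_id,
                   repeat_index = as.integer(raw$repeat_index),
                   x = pts[, 1L], y = pts[, 2L], z = pts[, 3L])
  landmark_annotations(df)
}

#' Write landmark annotations to JSON
#'
#' @param annotations a [landmark_annotations()] table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_annotations_json <- function(annotations, path) {
  recs <- lapply(seq_len(nrow(annotations)), function(i) {
    r <- annotations[i, ]
    list(patient_id = r$patient_id, bone = r$bone, side = r$side,
         model_source = r$model_source, landmark = r$landmark,
         observer_id = r$observer_id, repeat_index = r$repeat_index,
         point_mm = c(r$x, r$y, r$z))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an MITK point-set file (.mps)
#'
#' Returns the raw points; landmark/observer metadata is not part of the
#' format and must be supplied separately when building a
#' [landmark_annotations()] table.
#'
#' @param path .mps XML file path.
#' @return data.frame with columns `id`, `x`, `y`, `z`.
#' @export
read_mps <- function(path) {
  doc <- xml2::read_xml(path)
  pts <- xml2::xml_find_all(doc, ".//point")
  if (length(pts) == 0L) stop("no <point> elements in MPS file: ", path)
  num <- function(tag) as.numeric(vapply(pts, function(p)
    xml2::xml_text(xml2::xml_find_first(p, tag)), character(1)))
  data.frame(id = as.integer(num("id")), x = num("x"), y = num("y"),
             z = num("z"))
}

#' Build a consensus landmark region from repeated annotations
#'
#' A disc-shaped region of predefined radius is fitted to all annotations
#' of one landmark on one model. Outliers are discarded iteratively: the
#' point farthest from the centroid of the remaining points is dropped
#' while its distance exceeds `max(2 mm, 2 x median pairwise distance)`,
#' never reducing the inliers below half the annotations (minimum 3). The
#' region centre is the inlier centroid snapped to the nearest mesh vertex;
#' members are all mesh vertices within `radius` of the centre.
#'
#' @param annotations [landmark_annotations()] rows for a single landmark
#'   on a single model (at least 3).
#' @param mesh the host [triangle_mesh()] the annotations were placed on.
#' @param radius region radius in mm (default 5).
#' @param membership `"euclidean"` (default) or `"geodesic"` (graph
#'   distance along mesh edges; requires the igraph package).
#' @return an object of class `landmark_region` with fields `landmark`,
#'   `center` (snapped, mm), `center_vertex`, `radius`,
#'   `inlier_annotations` (row indices), `member_vertices`, `membership`
#'   and the host `mesh`.
#' @export
build_region <- function(annotations, mesh, radius = 5,
                         membership = c("euclidean", "geodesic")) {
  membership <- match.arg(membership)
  stopifnot(is_triangle_mesh(mesh))
  if (nrow(annotations) < 3L)
    stop("at least 3 annotations are required to build a region")
  if (length(unique(annotations$landmark)) != 1L)
    stop("annotations mix landmarks")
  if (length(unique(annotations$model_source)) != 1L)
    stop("annotations mix model sources")
  pts <- as.matrix(annotations[, c("x", "y", "z")])
  pd <- as.matrix(stats::dist(pts))
  if (all(pd[upper.tri(pd)] > 2 * radius))
    stop("no consensus region: all annotations mutually farther than 2*radius")

  min_inliers <- max(3L, ceiling(nrow(pts) / 2))
  inliers <- seq_len(nrow(pts))
  while (length(inliers) > min_inliers) {
    cur <- pts[inliers, , drop = FALSE]
    d_loo <- vapply(seq_along(inliers), function(i) {
      others <- colMeans(cur[-i, , drop = FALSE])
      sqrt(sum((cur[i, ] - others)^2))
    }, numeric(1))
    cur_pd <- stats::dist(cur)
    threshold <- max(2, 2 * stats::median(cur_pd))
    worst <- which.max(d_loo)
    if (d_loo[worst] > threshold) inliers <- inliers[-worst] else break
  }

  center_raw <- colMeans(pts[inliers, , drop = FALSE])
  center_vertex <- nearest_indices(matrix(center_raw, 1L, 3L),
                                   mesh$vertices)[1L]
  center <- mesh$vertices[center_vertex, ]
  member_vertices <- if (membership == "euclidean") {
    which(sqrt(rowSums(sweep(mesh$vertices, 2L, center)^2)) <= radius)
  } else {
    geodesic_ball(mesh, center_vertex, radius)
  }
  structure(list(landmark = annotations$landmark[1L], center = center,
                 center_vertex = center_vertex, radius = radius,
                 inlier_annotations = inliers,
                 member_vertices = member_vertices,
                 membership = membership, mesh = mesh),
            class = "landmark_region")
}

#' @export
print.landmark_region <- function(x, ...) {
  cat(sprintf("landmark_region %s: %d/%s inlier annotations, %d member vertices within %.1f mm (%s)\n",
              x$landmark, length(x$inlier_annotations), "set",
              length(x$member_vertices), x$radius, x$membership))
  invisible(x)
}

# vertices within geodesic (edge-graph) distance r of a seed vertex
geodesic_ball <- function(mesh, seed_vertex, r) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("geodesic membership requires the igraph package")
  f <- mesh$faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)])
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  w <- sqrt(rowSums((mesh$vertices[edges[, 1L], , drop = FALSE] -
                       mesh$vertices[edges[, 2L], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w)
  d <- igraph::distances(g, v = seed_vertex)[1L, ]
  which(d <= r)
}

#' Local RMSE of a landmark region against the ground-truth mesh
#'
#' RMS of the distances from the region's member vertices (on the
#' prediction mesh) to their closest ground-truth vertices. Both meshes
#' must already share the registered frame used for the global RMSE.
#'
#' @param region a [build_region()] result hosted on the prediction mesh.
#' @param gt_mesh the ground-truth [triangle_mesh()].
#' @return an [rmse_result()] with direction `"pred_to_gt"`.
#' @export
local_rmse <- function(region, gt_mesh) {
  stopifnot(inherits(region, "landmark_region"), is_triangle_mesh(gt_mesh))
  if (length(region$member_vertices) == 0L)
    stop("landmark region is empty")
  pts <- region$mesh$vertices[region$member_vertices, , drop = FALSE]
  d <- nearest_distances(pts, gt_mesh$vertices)
  rmse_result(sqrt(mean(d^2)), length(d), "pred_to_gt",
              per_point_distances = d)
}
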