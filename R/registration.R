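#' Root-mean-square surface error result
#'
#' @param rmse RMS of the per-point distances (mm).
#' @param n_points number of points entering the mean.
#' @param direction `"pred_to_gt"`, `"gt_to_pred"` or `"symmetric"`.
#' @param per_point_distances optional numeric vector of the distances (mm).
#' @return an object of class `rmse_result`.
#' @export
rmse_result <- function(rmse, n_points, direction = "pred_to_gt",
                        per_point_distances = NULL) {
  direction <- match.arg(direction, c("pred_to_gt", "gt_to_pred", "symmetric"))
  stopifnot(rmse >= 0)
  if (!is.null(per_point_distances)) {
    stopifnot(length(per_point_distances) == n_points)
    # RMS >= mean holds for any nonnegative sample
    stopifnot(rmse + 1e-12 >= mean(per_point_distances))
  }
  structure(list(rmse = rmse, n_points = as.integer(n_points),
                 direction = direction,
                 per_point_distances = per_point_distances),
            class = "rmse_result")
}

#' @export
print.rmse_result <- function(x, ...) {
  cat(sprintf("rmse_result: %.4f mm over %d points (%s)\n",
              x$rmse, x$n_points, x$direction))
  invisible(x)
}

# nearest-neighbour indices of each query row in ref; "kd" uses the exact
# kd-tree search from RANN, "brute" the exhaustive C++ scan. Distances are
# recomputed in R from the indices so both routes share identical
# arithmetic.
nearest_indices <- function(query, ref, method = c("kd", "brute")) {
  method <- match.arg(method)
  if (nrow(ref) == 0L) stop("reference point set is empty")
  if (method == "kd") {
    RANN::nn2(ref, query, k = 1L)$nn.idx[, 1L]
  } else {
    .nn_brute_cpp(query, ref)
  }
}

nearest_distances <- function(query, ref, method = "kd") {
  idx <- nearest_indices(query, ref, method)
  sqrt(rowSums((query - ref[idx, , drop = FALSE])^2))
}

#' Distance from each source vertex to the closest target vertex
#'
#' Vertex-to-vertex distances (not point-to-surface): for source vertex i,
#' the minimum Euclidean distance over all target vertices. This is the
#' distance entering both the global and the landmark-region RMSE.
#'
#' @param source,target [triangle_mesh()] objects, already registered.
#' @param method `"kd"` (exact kd-tree, default) or `"brute"` (exhaustive
#'   scan, the independent oracle).
#' @return numeric vector, one distance (mm) per source vertex.
#' @export
nearest_vertex_distances <- function(source, target, method = c("kd", "brute")) {
  stopifnot(is_triangle_mesh(source), is_triangle_mesh(target))
  if (nrow(target$vertices) == 0L) stop("target mesh has no vertices")
  nearest_distances(source$vertices, target$vertices, match.arg(method))
}

#' Rigid registration by iterative closest points
#'
#' Point-to-point ICP: alternate exact nearest-neighbour correspondence
#' (within `max_correspondence`) and least-squares rigid alignment of the
#' matched pairs, until the mean closest-point distance improves by less
#' than `tolerance` or `max_iterations` is reached. Deterministic for fixed
#' inputs and parameters.
#'
#' Initialization aligns centroids and principal axes; the four
#' sign-combinations of the principal axes that keep a proper rotation are
#' scored by mean closest-point distance and the best is kept, which makes
#' the method robust to large initial misalignments of elongated shapes.
#'
#' @param source,target non-empty [triangle_mesh()] objects; the returned
#'   transform maps `source` onto `target`.
#' @param max_iterations iteration cap (default 100).
#' @param tolerance convergence threshold on the mean distance improvement,
#'   mm (default 1e-6).
#' @param max_correspondence correspondence rejection radius, mm
#'   (default 10).
#' @param init `"pca"` (default) or `"identity"`.
#' @param metric `"point_to_point"` (default) or `"point_to_plane"`.
#' @param trim fraction of worst correspondences to drop each iteration
#'   (default 0, no trimming).
#' @return a [rigid_transform()] with attributes `iterations` and
#'   `mean_distance`.
#' @export
icp_register <- function(source, target, max_iterations = 100L,
                         tolerance = 1e-6, max_correspondence = 10,
                         init = c("pca", "identity"),
                         metric = c("point_to_point", "point_to_plane"),
                         trim = 0) {
  stopifnot(is_triangle_mesh(source), is_triangle_mesh(target),
            nrow(source$vertices) > 0L, nrow(target$vertices) > 0L)
  init <- match.arg(init)
  metric <- match.arg(metric)
  src <- source$vertices
  tgt <- target$vertices
  tgt_normals <- if (metric == "point_to_plane") vertex_normals(target)

  transform <- if (init == "pca") pca_initialize(src, tgt)
               else rigid_transform()
  cur <- apply_rigid(src, transform)
  prev_mean <- Inf
  iterations <- 0L
  mean_dist <- mean(nearest_distances(cur, tgt))

  for (it in seq_len(max_iterations)) {
    idx <- nearest_indices(cur, tgt)
    d <- sqrt(rowSums((cur - tgt[idx, , drop = FALSE])^2))
    keep <- d <= max_correspondence
    if (trim > 0 && any(keep)) {
      cutoff <- stats::quantile(d[keep], probs = 1 - trim, names = FALSE)
      keep <- keep & d <= cutoff
    }
    if (sum(keep) < 3L)
      stop("registration failed: no correspondences within max_correspondence")
    step <- if (metric == "point_to_point") {
      kabsch(cur[keep, , drop = FALSE], tgt[idx[keep], , drop = FALSE])
    } else {
      point_to_plane_step(cur[keep, , drop = FALSE],
                          tgt[idx[keep], , drop = FALSE],
                          tgt_normals[idx[keep], , drop = FALSE])
    }
    transform <- compose_rigid(step, transform)
    cur <- apply_rigid(src, transform)
    mean_dist <- mean(nearest_distances(cur, tgt))
    iterations <- it
    if (abs(prev_mean - mean_dist) < tolerance) break
    prev_mean <- mean_dist
  }
  attr(transform, "iterations") <- iterations
  attr(transform, "mean_distance") <- mean_dist
  transform
}

# centroid + principal-axes initialization with sign disambiguation
pca_initialize <- function(src, tgt) {
  cs <- colMeans(src)
  ct <- colMeans(tgt)
  es <- eigen(stats::cov(src), symmetric = TRUE)$vectors
  et <- eigen(stats::cov(tgt), symmetric = TRUE)$vectors
  if (det(es) < 0) es[, 3L] <- -es[, 3L]
  if (det(et) < 0) et[, 3L] <- -et[, 3L]
  # subsample for scoring so initialization stays cheap on dense meshes
  take <- if (nrow(src) > 2000L)
    as.integer(seq(1L, nrow(src), length.out = 2000L)) else seq_len(nrow(src))
  best <- NULL
  best_score <- Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    s3 <- s1 * s2  # keep det(+1)
    Rcand <- et %*% diag(c(s1, s2, s3)) %*% t(es)
    cand <- rigid_transform(Rcand, ct - as.numeric(Rcand %*% cs))
    score <- mean(nearest_distances(apply_rigid(src[take, , drop = FALSE],
                                                cand), tgt))
    if (score < best_score) {
      best_score <- score
      best <- cand
    }
  }
  best
}

# one linearized point-to-plane least-squares step (small-angle model)
point_to_plane_step <- function(p, q, n) {
  b <- rowSums((q - p) * n)
  A <- cbind(p[, 2L] * n[, 3L] - p[, 3L] * n[, 2L],
             p[, 3L] * n[, 1L] - p[, 1L] * n[, 3L],
             p[, 1L] * n[, 2L] - p[, 2L] * n[, 1L],
             n)
  x <- solve(crossprod(A), crossprod(A, b))
  R <- rotation_about_axis(x[1:3], sqrt(sum(x[1:3]^2)) * 180 / pi)
  if (sqrt(sum(x[1:3]^2)) == 0) R <- diag(3)
  rigid_transform(R, x[4:6])
}

#' Global surface RMSE between a predicted and a ground-truth bone model
#'
#' Root mean square of the distances from each prediction vertex to its
#' closest ground-truth vertex (the prediction side carries the point count
#' N). With `register = TRUE` the prediction is first rigidly aligned to
#' the ground truth by [icp_register()].
#'
#' @param pred a [bone_model()] with source `"prediction"`.
#' @param gt a [bone_model()] with source `"ground_truth"`, same bone and
#'   patient.
#' @param register run ICP before measuring (default `TRUE`).
#' @param keep_distances return per-vertex distances in the result
#'   (default `TRUE`).
#' @param ... passed to [icp_register()].
#' @return an [rmse_result()] with direction `"pred_to_gt"`.
#' @export
global_rmse <- function(pred, gt, register = TRUE, keep_distances = TRUE, ...) {
  stopifnot(inherits(pred, "bone_model"), inherits(gt, "bone_model"))
  if (pred$source != "prediction" || gt$source != "ground_truth")
    stop("global_rmse expects (prediction, ground_truth) in that order")
  if (pred$bone != gt$bone || pred$patient_id != gt$patient_id)
    stop("bone/patient mismatch between prediction and ground truth")
  mesh <- pred$mesh
  if (register) {
    transform <- icp_register(mesh, gt$mesh, ...)
    mesh <- transform_mesh(mesh, transform)
  }
  d <- nearest_vertex_distances(mesh, gt$mesh)
  rmse_result(sqrt(mean(d^2)), length(d), "pred_to_gt",
              per_point_distances = if (keep_distances) d)
}

#' Export per-vertex distances as a data frame
#'
#' Long-form record suitable for CSV export and downstream plotting.
#'
#' @param result an [rmse_result()] holding per-point distances.
#' @param patient_id,bone identifiers copied onto every row.
#' @return data.frame with columns patient_id, bone, vertex_index,
#'   distance_mm.
#' @export
distances_to_df <- function(result, patient_id, bone) {
  stopifnot(inherits(result, "rmse_result"),
            !is.null(result$per_point_distances))
  data.frame(patient_id = patient_id, bone = bone,
             vertex_index = seq_along(result$per_point_distances),
             distance_mm = result$per_point_distances)
}
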