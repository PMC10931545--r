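#' Build a 3D anatomical axis from a pair of landmark annotations
#'
#' TEA connects the lateral and medial epicondyles, PCA the posterior
#' lateral and posterior medial condyles, MLTA the lateral and medial
#' tibial plateau points. Both annotations must come from the same
#' observer, repeat and model.
#'
#' @param a,b single-row [landmark_annotations()] entries forming the
#'   correct landmark pair for `name`.
#' @param name `"TEA"`, `"PCA"` or `"MLTA"`; inferred from the landmarks
#'   when omitted.
#' @return an [axis3d()] carrying provenance (model_source, observer_id,
#'   repeat_index).
#' @export
build_axis3d <- function(a, b, name = NULL) {
  pair <- sort(c(a$landmark, b$landmark))
  expected <- list(
    TEA = sort(c("lateral_epicondyle", "medial_epicondyle")),
    PCA = sort(c("posterior_lateral_condyle", "posterior_medial_condyle")),
    MLTA = sort(c("lateral_plateau", "medial_plateau"))
  )
  inferred <- names(expected)[vapply(expected, identical, logical(1), pair)]
  if (length(inferred) != 1L)
    stop("landmarks (", paste(pair, collapse = ", "),
         ") do not form a TEA, PCA or MLTA pair")
  if (!is.null(name) && name != inferred)
    stop("landmark pair forms ", inferred, ", not ", name)
  if (a$observer_id != b$observer_id || a$repeat_index != b$repeat_index ||
        a$model_source != b$model_source || a$patient_id != b$patient_id)
    stop("axis endpoints must share observer, repeat and model")
  axis3d(inferred, c(a$x, a$y, a$z), c(b$x, b$y, b$z),
         provenance = list(model_source = a$model_source,
                           observer_id = a$observer_id,
                           repeat_index = a$repeat_index))
}

#' Build all annotated axes of one kind for one bone model
#'
#' Pairs the two endpoint landmarks per (observer, repeat); a complete
#' study-design annotation set yields 6 axes per bone model.
#'
#' @param annotations a [landmark_annotations()] table for one model.
#' @param name `"TEA"`, `"PCA"` or `"MLTA"`.
#' @param model_source `"prediction"` or `"ground_truth"`.
#' @return list of [axis3d()].
#' @export
build_annotated_axes <- function(annotations, name, model_source) {
  endpoints <- switch(name,
    TEA = c("lateral_epicondyle", "medial_epicondyle"),
    PCA = c("posterior_lateral_condyle", "posterior_medial_condyle"),
    MLTA = c("lateral_plateau", "medial_plateau"),
    stop("unknown axis name: ", name))
  sub <- annotations[annotations$model_source == model_source &
                       annotations$landmark %in% endpoints, , drop = FALSE]
  keys <- unique(sub[, c("observer_id", "repeat_index")])
  keys <- keys[order(keys$observer_id, keys$repeat_index), , drop = FALSE]
  axes <- list()
  for (i in seq_len(nrow(keys))) {
    rows <- sub[sub$observer_id == keys$observer_id[i] &
                  sub$repeat_index == keys$repeat_index[i], , drop = FALSE]
    if (nrow(rows) != 2L) next
    a <- rows[rows$landmark == endpoints[1L], , drop = FALSE]
    b <- rows[rows$landmark == endpoints[2L], , drop = FALSE]
    if (nrow(a) != 1L || nrow(b) != 1L) next
    axes[[length(axes) + 1L]] <- build_axis3d(a, b, name)
  }
  axes
}

#' Project a 3D axis onto a cutting plane
#'
#' Both endpoints are projected with [project_to_plane()] and the 2D
#' direction normalized. An axis (nearly) parallel to the plane normal has
#' no usable in-plane image and is rejected.
#'
#' @param axis an [axis3d()].
#' @param plane a [make_plane()].
#' @return an object of class `axis2d` with fields `name`, `point`,
#'   `direction`, `provenance`, `plane`.
#' @export
project_axis <- function(axis, plane) {
  stopifnot(inherits(axis, "axis3d"), inherits(plane, "cut_plane"))
  q0 <- project_to_plane(axis$p0, plane)
  q1 <- project_to_plane(axis$p1, plane)
  d <- q1 - q0
  len <- sqrt(sum(d^2))
  if (len < 1e-6) stop("axis degenerate in plane (parallel to the normal)")
  structure(list(name = axis$name, point = as.numeric(q0),
                 direction = as.numeric(d / len),
                 provenance = axis$provenance, plane = plane),
            class = "axis2d")
}

#' Undirected angle between two 2D axes
#'
#' Axes are undirected lines: `d` and `-d` are the same axis, so the angle
#' is `acos(|d_a . d_b|)`, in [0, 90] degrees.
#'
#' @param a,b `axis2d` objects in the same plane frame.
#' @return angle in degrees.
#' @export
angle_between <- function(a, b) {
  stopifnot(inherits(a, "axis2d"), inherits(b, "axis2d"))
  if (!is.null(a$plane) && !is.null(b$plane) &&
        !same_plane_frame(a$plane, b$plane))
    stop("axis frame mismatch: axes projected onto different planes")
  acos(min(1, abs(sum(a$direction * b$direction)))) * 180 / pi
}

#' Pairwise angular statistics of one axis
#'
#' @param axis_name axis the statistics describe.
#' @param angles numeric vector of pairwise angles in degrees.
#' @param kind `"baseline_ct_ct"` or `"cross_ct_xray"`.
#' @return an object of class `angle_stats` with fields `axis_name`,
#'   `mean_deg`, `sd_deg`, `n_pairs`, `kind`, `angles`.
#' @export
angle_stats <- function(axis_name, angles, kind) {
  kind <- match.arg(kind, c("baseline_ct_ct", "cross_ct_xray"))
  stopifnot(all(angles >= 0), all(angles <= 90))
  structure(list(axis_name = axis_name, mean_deg = mean(angles),
                 sd_deg = stats::sd(angles), n_pairs = length(angles),
                 kind = kind, angles = angles),
            class = "angle_stats")
}

#' @export
print.angle_stats <- function(x, ...) {
  cat(sprintf("angle_stats %s (%s): %.2f +- %.2f deg over %d pairs\n",
              x$axis_name, x$kind, x$mean_deg, x$sd_deg, x$n_pairs))
  invisible(x)
}

check_axis_set <- function(axes, source) {
  stopifnot(length(axes) >= 2L)
  name <- unique(vapply(axes, function(a) a$name, character(1)))
  if (length(name) != 1L) stop("axes mix names")
  for (i in seq_along(axes)[-1L]) {
    if (!same_plane_frame(axes[[1L]]$plane, axes[[i]]$plane))
      stop("axes projected onto different planes")
  }
  prov <- t(vapply(axes, function(a)
    c(a$provenance$model_source, as.character(a$provenance$observer_id),
      as.character(a$provenance$repeat_index)), character(3)))
  if (!all(prov[, 1L] == source))
    stop("expected all axes from model source ", source)
  if (anyDuplicated(paste(prov[, 2L], prov[, 3L])))
    stop("duplicate (observer, repeat) axis annotation")
  name
}

#' Baseline (intra/inter-observer) angular deviation of one axis
#'
#' All unordered pairs of the ground-truth (CT-based) axis annotations are
#' enumerated - C(n, 2) pairs, 15 for the study design's 6 annotations -
#' and the mean and SD of the pairwise angles returned. This is the
#' human-level baseline that cross-modality deviations are compared to.
#'
#' @param ct_axes list of `axis2d` from the ground-truth model, one per
#'   (observer, repeat).
#' @return an [angle_stats()] of kind `"baseline_ct_ct"`.
#' @export
baseline_stats <- function(ct_axes) {
  name <- check_axis_set(ct_axes, "ground_truth")
  n <- length(ct_axes)
  angles <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    angles <- c(angles, angle_between(ct_axes[[i]], ct_axes[[j]]))
  angle_stats(name, angles, "baseline_ct_ct")
}

#' Cross-modality angular deviation of one axis
#'
#' All pairs of one X-ray-based and one CT-based annotation of the same
#' axis - n x m pairs, 36 for the study design's 6 x 6 annotations.
#'
#' @param ct_axes `axis2d` list from the ground-truth model.
#' @param xray_axes `axis2d` list from the prediction model.
#' @return an [angle_stats()] of kind `"cross_ct_xray"`.
#' @export
cross_stats <- function(ct_axes, xray_axes) {
  name_ct <- check_axis_set(ct_axes, "ground_truth")
  name_xr <- check_axis_set(xray_axes, "prediction")
  if (name_ct != name_xr) stop("axis name mismatch between modalities")
  if (!same_plane_frame(ct_axes[[1L]]$plane, xray_axes[[1L]]$plane))
    stop("modalities projected onto different planes")
  angles <- numeric(0)
  for (a in xray_axes) for (b in ct_axes)
    angles <- c(angles, angle_between(a, b))
  angle_stats(name_ct, angles, "cross_ct_xray")
}

#' Study-level axis report
#'
#' Pools the pairwise angles of each axis across bone models (all angles
#' pooled before mean/SD, the default, or per-bone means averaged) and
#' emits one row per axis with the baseline and cross-modality mean (SD).
#'
#' @param stats_list list of [angle_stats()] across bones, baseline and
#'   cross kinds mixed.
#' @param pooling `"angles"` (default) or `"bone_means"`.
#' @return data.frame with columns axis, baseline_mean, baseline_sd,
#'   cross_mean, cross_sd, n_baseline_pairs, n_cross_pairs.
#' @export
study_axis_report <- function(stats_list, pooling = c("angles", "bone_means")) {
  pooling <- match.arg(pooling)
  stopifnot(length(stats_list) >= 1L)
  axes <- unique(vapply(stats_list, function(s) s$axis_name, character(1)))
  rows <- lapply(axes, function(ax) {
    pick <- function(kind) stats_list[vapply(stats_list, function(s)
      s$axis_name == ax && s$kind == kind, logical(1))]
    summarize <- function(group) {
      if (length(group) == 0L)
        return(c(mean = NA_real_, sd = NA_real_, n = 0))
      if (pooling == "angles") {
        pooled <- unlist(lapply(group, function(s) s$angles))
        c(mean = mean(pooled), sd = stats::sd(pooled), n = length(pooled))
      } else {
        m <- vapply(group, function(s) s$mean_deg, numeric(1))
        c(mean = mean(m), sd = stats::sd(m), n = length(m))
      }
    }
    b <- summarize(pick("baseline_ct_ct"))
    x <- summarize(pick("cross_ct_xray"))
    data.frame(axis = ax, baseline_mean = b["mean"], baseline_sd = b["sd"],
               cross_mean = x["mean"], cross_sd = x["sd"],
               n_baseline_pairs = b["n"], n_cross_pairs = x["n"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}
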