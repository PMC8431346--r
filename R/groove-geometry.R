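# BH3-binding-groove geometry.
#
# The groove orientation descriptor is built from two helices on the soluble
# head: the principal (long) axis of helix alpha5 and the vector joining the
# alpha-carbon geometric centers of short windows on alpha5 and alpha6. The
# groove vector is the normal to the plane these two span, and its deviation
# angle from the membrane normal separates occluded (> 90 deg) from
# accessible (< 90 deg) groove configurations.

#' Helix definition
#'
#' @param first,last inclusive residue span of the helix (>= 3 residues).
#' @param label optional label (e.g. "a5", "a8").
#' @param chain chain identifier or NULL for any.
#' @return object of class `helix_def`.
#' @export
helix_def <- function(first, last, label = NULL, chain = NULL) {
  if (last - first + 1 < 3) stop("a helix span needs at least 3 residues")
  structure(list(first = as.integer(first), last = as.integer(last),
                 label = label, chain = chain), class = "helix_def")
}

#' Principal (long) axis of a helix from the C-alpha inertia tensor
#'
#' Builds the moment-of-inertia tensor of the helix alpha-carbons (unit
#' masses, about their centroid) and returns the eigenvector of the smallest
#' eigenvalue — the helix long axis — sign-fixed so that it points from the
#' N-terminal to the C-terminal end.
#'
#' @param model a `mol_model`.
#' @param helix a `helix_def` (or `selection_spec`/string resolving to the
#'   helix C-alphas).
#' @return unit length-3 vector.
#' @details The tensor is `I = sum_i (|r_i|^2 Id - r_i r_i^T)` over centered
#'   C-alpha positions. If the two smallest eigenvalues are degenerate
#'   (relative gap < 1e-9) the long axis is undefined and an error reports
#'   the eigenvalue gap.
#' @export
helix_principal_axis <- function(model, helix) {
  sel <- if (inherits(helix, "helix_def"))
    selection(helix$first, helix$last, atom = "CA", chain = helix$chain)
  else helix
  idx <- resolve_strict(model, sel, "helix C-alpha selection")
  if (length(idx) < 3) stop("helix selection resolves to fewer than 3 C-alphas")
  X <- coords(model)[idx, , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  r2 <- rowSums(Xc^2)
  I3 <- diag(sum(r2), 3) - crossprod(Xc)   # sum(|r|^2) Id - X^T X
  e <- eigen(I3, symmetric = TRUE)
  # eigen() sorts decreasing; smallest inertia eigenvalue = long axis
  vals <- rev(e$values)
  scale <- max(abs(e$values), .Machine$double.eps)
  if ((vals[2] - vals[1]) / scale < 1e-9)
    stop(sprintf(paste0("degenerate helix geometry: two smallest inertia ",
                        "eigenvalues within relative gap %.3g"),
                 (vals[2] - vals[1]) / scale))
  axis <- e$vectors[, 3]
  n_to_c <- X[nrow(X), ] - X[1, ]
  if (sum(axis * n_to_c) < 0) axis <- -axis
  unit_vec(axis)
}

#' Groove vector definition
#'
#' Default residue windows: helix alpha5 spans 143-153 with center window
#' 143-146; the alpha6 center window is 170-173.
#'
#' @param alpha5_span length-2 inclusive span of helix alpha5.
#' @param alpha5_center,alpha6_center length-2 inclusive spans of the
#'   C-alpha windows whose geometric centers define the inter-helix
#'   connector.
#' @param flip logical; reverse the cross-product order (maps every groove
#'   deviation angle phi to 180 - phi).
#' @param chain chain identifier or NULL.
#' @return object of class `groove_def`.
#' @export
groove_def <- function(alpha5_span = c(143, 153),
                       alpha5_center = c(143, 146),
                       alpha6_center = c(170, 173),
                       flip = FALSE, chain = NULL) {
  chk <- function(v) length(v) == 2 && v[1] <= v[2]
  if (!chk(alpha5_span) || !chk(alpha5_center) || !chk(alpha6_center))
    stop("spans must be length-2 inclusive ranges")
  if (alpha5_center[1] < alpha5_span[1] || alpha5_center[2] > alpha5_span[2])
    stop("alpha5 center window must lie within the alpha5 span")
  structure(list(alpha5_span = as.integer(alpha5_span),
                 alpha5_center = as.integer(alpha5_center),
                 alpha6_center = as.integer(alpha6_center),
                 flip = isTRUE(flip), chain = chain), class = "groove_def")
}

ca_center <- function(model, span, chain = NULL) {
  idx <- resolve_strict(model, selection(span[1], span[2], "CA", chain),
                        sprintf("C-alpha window %d-%d", span[1], span[2]))
  colMeans(coords(model)[idx, , drop = FALSE])
}

#' BH3-binding-groove vector of one configuration
#'
#' `g = unit(a x c)` where `a` is the alpha5 principal axis and `c` points
#' from the alpha5 center window to the alpha6 center window.
#'
#' @param model a `mol_model`.
#' @param def a `groove_def`.
#' @return unit length-3 vector.
#' @export
groove_vector <- function(model, def = groove_def()) {
  stopifnot(inherits(def, "groove_def"))
  a <- helix_principal_axis(model, helix_def(def$alpha5_span[1],
                                             def$alpha5_span[2],
                                             "a5", def$chain))
  cc <- ca_center(model, def$alpha6_center, def$chain) -
        ca_center(model, def$alpha5_center, def$chain)
  g <- cross3(a, unit_vec(cc))
  if (vec_norm(g) < 1e-6)
    stop("alpha5 axis and inter-helix connector are collinear; groove plane undefined")
  g <- unit_vec(g)
  if (def$flip) -g else g
}

#' Deviation angle of a vector from the membrane normal
#'
#' @param v length-3 vector (normalized internally).
#' @param frame_ref a `membrane_frame`, or a length-3 normal vector.
#' @return angle in degrees, in [0, 180].
#' @export
deviation_angle <- function(v, frame_ref = c(0, 0, 1)) {
  nrm <- if (inherits(frame_ref, "membrane_frame")) frame_ref$normal else frame_ref
  v <- unit_vec(v); nrm <- unit_vec(nrm)
  d <- max(-1, min(1, sum(v * nrm)))
  acos(d) * 180 / pi
}

#' Classify groove accessibility from the deviation angle
#'
#' Angles below 90 degrees indicate an accessible BH3-binding groove;
#' angles of 90 degrees or more an (at least partially) occluded one. The
#' boundary value 90 is classified as occluded — the conservative choice.
#'
#' @param angle numeric vector of deviation angles in degrees, each in
#'   [0, 180].
#' @return character vector, `"accessible"` or `"occluded"`.
#' @export
classify_accessibility <- function(angle) {
  if (any(!is.finite(angle)) || any(angle < 0) || any(angle > 180))
    stop("deviation angles must lie in [0, 180]")
  ifelse(angle < 90, "accessible", "occluded")
}

# ---- per-frame series --------------------------------------------------

angle_series <- function(times, values, label) {
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 180))
    stop("angle values must be finite and in [0, 180]")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label), class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series '%s'> %d frames, mean %.2f deg\n",
              x$label, length(x$values), mean(x$values)))
  invisible(x)
}

#' @export
as.data.frame.angle_series <- function(x, ...) {
  data.frame(frame = seq_along(x$times), time_us = x$times,
             angle_deg = x$values)
}

series_over_frames <- function(traj, fun, label) {
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    tryCatch(fun(get_frame(traj, k)),
             error = function(e) stop("frame ", k, ": ", conditionMessage(e),
                                      call. = FALSE))
  }, numeric(1))
  angle_series(traj$times, vals, label)
}

#' Groove deviation-angle time series
#'
#' Evaluates the groove vector on every frame and measures its deviation
#' angle from the per-frame membrane normal.
#'
#' @param traj a `trajectory`.
#' @param def a `groove_def`.
#' @param phosphorus atom-name(s) identifying lipid phosphorus beads used
#'   to build the per-frame membrane frame; `NULL` uses the fixed +z normal.
#' @return an `angle_series` labelled `"phi"`.
#' @export
groove_angle_series <- function(traj, def = groove_def(), phosphorus = "P") {
  series_over_frames(traj, function(m) {
    ref <- if (is.null(phosphorus)) c(0, 0, 1) else membrane_frame(m, phosphorus)
    deviation_angle(groove_vector(m, def), ref)
  }, "phi")
}

#' Transmembrane-helix tilt time series
#'
#' Deviation angle of the TM-helix principal axis (alpha8, default span
#' 209-231) from the membrane normal, per frame.
#'
#' @param traj a `trajectory`.
#' @param tm_span length-2 inclusive residue span of the TM helix.
#' @param phosphorus as in [groove_angle_series()].
#' @return an `angle_series` labelled `"psi"`.
#' @export
tm_tilt_series <- function(traj, tm_span = c(209, 231), phosphorus = "P") {
  hd <- helix_def(tm_span[1], tm_span[2], "a8")
  series_over_frames(traj, function(m) {
    ref <- if (is.null(phosphorus)) c(0, 0, 1) else membrane_frame(m, phosphorus)
    deviation_angle(helix_principal_axis(m, hd), ref)
  }, "psi")
}
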