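# Synthetic fixtures with known ground truth.
#
# The generator emulates the architecture of a membrane-anchored two-part
# protein: a rigid soluble head carrying the groove helices (alpha5/alpha6,
# at the production residue numbering) and a flexible 61-residue loop, a TM
# helix anchor, and a bilayer represented by two planes of phosphorus
# beads. Rigid-body trajectories rotate the head so the groove deviation
# angle follows a prescribed schedule exactly, making every downstream
# descriptor recoverable against stored truth.

#' Ideal alpha-helix C-alpha trace
#'
#' @param n_res number of residues (>= 3).
#' @param rise rise per residue in Angstrom (default 1.5).
#' @param twist twist per residue in degrees (default 100).
#' @param radius helix radius in Angstrom (default 2.3).
#' @param first_resno residue number of the first residue.
#' @param orientation 3x3 rotation applied to the helix (built along +z).
#' @param origin translation applied after rotation (helix centroid target).
#' @param n_to_c +1 builds N->C along +z (before orientation), -1 reverses.
#' @param chain,resname atom table fields.
#' @return a `mol_model` of C-alpha beads; its principal axis is the
#'   orientation's image of (0, 0, n_to_c).
#' @export
make_ideal_helix <- function(n_res = 23, rise = 1.5, twist = 100, radius = 2.3,
                             first_resno = 1, orientation = diag(3),
                             origin = c(0, 0, 0), n_to_c = 1,
                             chain = "A", resname = "ALA") {
  if (n_res < 3) stop("an ideal helix needs at least 3 residues")
  if (rise <= 0 || radius <= 0) stop("rise and radius must be positive")
  i <- seq_len(n_res) - 1
  z <- i * rise * sign(n_to_c)
  ang <- i * twist * pi / 180
  X <- cbind(radius * cos(ang), radius * sin(ang), z)
  X <- sweep(X, 2, colMeans(X))               # centroid at origin
  # phase-closure correction: an incomplete final turn leaves a residual
  # covariance between the transverse and axial coordinates, tilting the
  # inertia long axis off the nominal axis by ~0.1 deg; shear it out
  # (sub-0.05 A coordinate change) so the principal axis is exactly axial
  sz2 <- sum(X[, 3]^2)
  X[, 1] <- X[, 1] - (sum(X[, 1] * X[, 3]) / sz2) * X[, 3]
  X[, 2] <- X[, 2] - (sum(X[, 2] * X[, 3]) / sz2) * X[, 3]
  X <- X %*% t(orientation)
  X <- sweep(X, 2, origin, "+")
  mol_model(data.frame(name = "CA", element = "C", resname = resname,
                       resno = first_resno + i, chain = chain,
                       x = X[, 1], y = X[, 2], z = X[, 3]))
}

#' Phosphate-bead membrane slab
#'
#' Two square grids of phosphorus beads at z = +/- `plane_z`, with optional
#' seeded Gaussian z-noise, standing in for the lipid phosphate phosphorus
#' positions of a planar bilayer.
#'
#' @param n_per_leaflet beads per leaflet (default 100).
#' @param plane_z half-separation of the planes in Angstrom (default 14,
#'   matching the toy protein's bilayer).
#' @param noise_sd Gaussian z-noise sd in Angstrom (default 0).
#' @param half_width lateral half-width of the grid (default 40 A).
#' @param seed RNG seed used for the noise (required when noise_sd > 0 for
#'   reproducibility).
#' @return a `mol_model` of beads named "P", chain "M".
#' @export
make_membrane_slab <- function(n_per_leaflet = 100, plane_z = 14, noise_sd = 0,
                               half_width = 40, seed = NULL) {
  if (n_per_leaflet < 1 || plane_z <= 0) stop("invalid slab parameters")
  k <- ceiling(sqrt(n_per_leaflet))
  g <- seq(-half_width, half_width, length.out = k)
  xy <- as.matrix(expand.grid(x = g, y = g))[seq_len(n_per_leaflet), , drop = FALSE]
  z <- rep(c(plane_z, -plane_z), each = n_per_leaflet)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("noisy slabs need an explicit seed")
    z <- z + withr::with_seed(seed, stats::rnorm(length(z), 0, noise_sd))
  }
  n <- 2 * n_per_leaflet
  mol_model(data.frame(name = "P", element = "P", resname = "MEM",
                       resno = seq_len(n), chain = "M",
                       x = rep(xy[, 1], 2), y = rep(xy[, 2], 2), z = z))
}

# straight C-alpha segment between two points (exclusive of endpoints'
# residue numbers handled by caller)
segment_beads <- function(from, to, resnos, resname = "ALA", chain = "A") {
  n <- length(resnos)
  tfrac <- if (n == 1) 0.5 else seq(0, 1, length.out = n)
  X <- outer(tfrac, to - from) + matrix(from, n, 3, byrow = TRUE)
  data.frame(name = "CA", element = "C", resname = resname, resno = resnos,
             chain = chain, x = X[, 1], y = X[, 2], z = X[, 3])
}

#' Toy membrane-anchored two-part protein
#'
#' A C-alpha-only model using the production residue numbering, so
#' production groove/loop/TM definitions apply unchanged: helix alpha1
#' (1-20), the 61-residue loop (21-81, semicircular arc; Gly-21 and Gly-70
#' present), a head body containing helix alpha5 (143-153) and helix alpha6
#' (166-178), connectors, Gln-207 at the junction, and a TM helix alpha8
#' (209-231, Trp-213) along z spanning the bilayer planes. The TM helix
#' runs N-to-C downward (residue 209 at the top), so Trp-213 sits just
#' below the upper plane as in a C-terminal membrane anchor; with the
#' N-to-C axis sign convention its deviation angle from the (head-side)
#' membrane normal is therefore 180 degrees minus its geometric tilt.
#'
#' @param plane_z half-separation of the intended membrane planes
#'   (default 14 A; a 23-residue, 33-Angstrom TM helix spans the planes
#'   with slack); the head sits above `+plane_z`.
#' @return list with `model` (a `mol_model`), `head_range` c(1, 208),
#'   `tm_span` c(209, 231), `loop_span` c(21, 81), and `groove_angle0`,
#'   the groove deviation angle from +z of the reference pose.
#' @export
make_anchored_toy <- function(plane_z = 14) {
  up <- plane_z
  resname_for <- function(resno) {
    out <- rep("ALA", length(resno))
    out[resno %in% c(21, 70)] <- "GLY"
    out[resno == 207] <- "GLN"
    out[resno == 213] <- "TRP"
    out
  }
  # helix alpha1, roughly vertical just above the membrane
  a1 <- make_ideal_helix(20, first_resno = 1,
                         origin = c(0, -12, up + 16))$atoms
  # 61-residue loop on a semicircular arc above the head
  n_loop <- 61
  th <- seq(0, pi, length.out = n_loop)
  loop <- data.frame(name = "CA", element = "C", resname = "ALA",
                     resno = 21:81, chain = "A",
                     x = 14 * cos(th), y = -10 + 6 * sin(th),
                     z = up + 26 + 4 * sin(2 * th))
  # head body: alpha5 along +x at the groove site, alpha6 parallel,
  # displaced in y; connectors fill the remaining residue numbering
  a5 <- make_ideal_helix(11, first_resno = 143,
                         orientation = rotation_between(c(0, 0, 1), c(1, 0, 0)),
                         origin = c(0, 0, up + 12))$atoms
  a6 <- make_ideal_helix(13, first_resno = 166,
                         orientation = rotation_between(c(0, 0, 1), c(1, 0, 0)),
                         origin = c(1.5, 9, up + 16))$atoms
  seg1 <- segment_beads(c(-16, -6, up + 18), c(-14, -2, up + 13), 82:142)
  seg2 <- segment_beads(c(8, 2, up + 12), c(6, 7, up + 12), 154:165)
  seg3 <- segment_beads(c(-6, 9, up + 11), c(1, 1, up + 3), 179:208)
  # TM helix along z, centered on the bilayer midplane, N-terminus up
  tm <- make_ideal_helix(23, first_resno = 209, origin = c(2, 0, 0),
                         n_to_c = -1)$atoms
  atoms <- rbind(a1, loop, seg1, a5, seg2, a6, seg3, tm)
  atoms <- atoms[order(atoms$resno), ]
  atoms$resname <- resname_for(atoms$resno)
  model <- mol_model(atoms)
  list(model = model, head_range = c(1L, 208L), tm_span = c(209L, 231L),
       loop_span = c(21L, 81L),
       groove_angle0 = deviation_angle(groove_vector(model), c(0, 0, 1)))
}

# ---- angle schedules ---------------------------------------------------

#' Angle schedules for synthetic trajectories
#'
#' `schedule_constant` holds one level; `schedule_piecewise` holds each
#' level until its switch time (mimicking sharp transitions between
#' occluded and accessible configurations); `schedule_ou` is a stationary
#' Ornstein-Uhlenbeck process discretized with exact conditional updates,
#' so its stationary mean/sd are analytic (mimicking steady fluctuation).
#'
#' @param level,levels angle level(s) in degrees, each in (0, 180).
#' @param switch_times times (us) at which the next level takes over;
#'   length(levels) - 1 values, strictly increasing.
#' @param mean,sd,tau_us OU stationary mean (deg), stationary sd (deg > 0)
#'   and correlation time (us > 0).
#' @return object of class `angle_schedule`.
#' @export
schedule_constant <- function(level) {
  check_angles_open(level)
  structure(list(type = "constant", level = level), class = "angle_schedule")
}

#' @rdname schedule_constant
#' @export
schedule_piecewise <- function(levels, switch_times) {
  check_angles_open(levels)
  if (length(switch_times) != length(levels) - 1)
    stop("need length(levels) - 1 switch times")
  if (length(switch_times) > 1 && any(diff(switch_times) <= 0))
    stop("switch times must be strictly increasing")
  structure(list(type = "piecewise", levels = levels,
                 switch_times = switch_times), class = "angle_schedule")
}

#' @rdname schedule_constant
#' @export
schedule_ou <- function(mean, sd, tau_us) {
  check_angles_open(mean)
  if (sd <= 0 || tau_us <= 0) stop("OU sd and correlation time must be positive")
  structure(list(type = "ou", mean = mean, sd = sd, tau_us = tau_us),
            class = "angle_schedule")
}

check_angles_open <- function(a) {
  if (any(!is.finite(a)) || any(a <= 0) || any(a >= 180))
    stop("schedule angles must lie strictly inside (0, 180) degrees")
  invisible(a)
}

#' Realize an angle schedule on a time grid
#'
#' @param schedule an `angle_schedule`.
#' @param times frame times in microseconds.
#' @param seed RNG seed (required for the OU type).
#' @return numeric vector of angles (degrees), one per time.
#' @export
realize_schedule <- function(schedule, times, seed = NULL) {
  stopifnot(inherits(schedule, "angle_schedule"))
  n <- length(times)
  out <- switch(schedule$type,
    constant = rep(schedule$level, n),
    piecewise = {
      lev <- schedule$levels[findInterval(times, schedule$switch_times) + 1]
      lev
    },
    ou = {
      if (is.null(seed)) stop("the OU schedule needs an explicit seed")
      dt <- diff(times)
      if (n > 1 && any(dt <= 0)) stop("times must be strictly increasing")
      withr::with_seed(seed, {
        x <- numeric(n)
        x[1] <- stats::rnorm(1, schedule$mean, schedule$sd)
        if (n > 1) {
          rho <- exp(-dt / schedule$tau_us)
          eps <- stats::rnorm(n - 1)
          for (k in 2:n)
            x[k] <- schedule$mean + (x[k - 1] - schedule$mean) * rho[k - 1] +
              schedule$sd * sqrt(1 - rho[k - 1]^2) * eps[k - 1]
        }
        x
      })
    })
  check_angles_open(out)
  out
}

# ---- rigid-body trajectory generator -----------------------------------

#' Rigid-body synthetic trajectory with prescribed descriptors
#'
#' Each frame rotates the toy protein's head rigidly about an in-plane axis
#' so that the groove deviation angle equals the schedule value exactly;
#' the TM helix is held at a prescribed tilt; loop C-alphas are optionally
#' rescaled about their centroid to hit prescribed radii of gyration; and
#' selected residues can be pinned at prescribed heights above the upper
#' phosphate plane. Ground truth is measured from the generated (noise-free)
#' coordinates and stored alongside the trajectory.
#'
#' @param toy result of [make_anchored_toy()].
#' @param slab a phosphate slab from [make_membrane_slab()].
#' @param schedule an `angle_schedule` for the groove angle phi(t).
#' @param n_frames number of frames (default 500).
#' @param dt_us frame interval in microseconds (default 0.01; 500 frames
#'   emulate a 5-us run).
#' @param tm_tilt geometric tilt of the TM-helix line from the membrane
#'   normal, degrees in [0, 90): scalar or per-frame vector (default 15).
#'   Because the toy anchor runs N-to-C downward, the recorded deviation
#'   angle `psi_deg` of its sign-fixed principal axis is `180 - tm_tilt`.
#' @param loop_rg optional per-frame loop Rg targets (Angstrom).
#' @param z_targets optional named list: residue number -> per-frame height
#'   (Angstrom) of its C-alpha above the upper phosphate plane.
#' @param noise_sd per-atom isotropic Gaussian noise sd (Angstrom) added to
#'   the final coordinates (default 0).
#' @param seed RNG seed (required for OU schedules or noise_sd > 0).
#' @return list with `trajectory` (protein + slab beads) and `truth`, a
#'   data.frame (frame, time_us, phi_deg, psi_deg, rg_A, and z<resno>_A for
#'   each pinned residue plus residues 21 and 70) carrying the seed and
#'   schedule as attributes. Truth records noise-free values.
#' @export
make_rigid_body_trajectory <- function(toy, slab, schedule, n_frames = 500,
                                       dt_us = 0.01, tm_tilt = 15,
                                       loop_rg = NULL, z_targets = NULL,
                                       noise_sd = 0, seed = NULL) {
  stopifnot(inherits(schedule, "angle_schedule"))
  times <- (seq_len(n_frames) - 1) * dt_us
  phi <- realize_schedule(schedule, times, seed = seed)
  psi <- rep_len(tm_tilt, n_frames)
  if (any(psi < 0 | psi >= 90)) stop("TM tilt must lie in [0, 90) degrees")
  if (!is.null(loop_rg) && length(loop_rg) != n_frames)
    stop("loop_rg must have one value per frame")

  prot <- toy$model
  mem <- membrane_frame(slab)
  head_idx <- resolve_selection(prot, selection(toy$head_range[1],
                                                toy$head_range[2], atom = NULL))
  tm_idx <- resolve_selection(prot, selection(toy$tm_span[1], toy$tm_span[2],
                                              atom = NULL))
  loop_idx <- resolve_selection(prot, selection(toy$loop_span[1],
                                                toy$loop_span[2], "CA"))
  g0 <- groove_vector(prot)
  # orthonormal basis of the plane spanned by the membrane normal and g0;
  # the per-frame head rotation moves g0 within this plane so its polar
  # angle equals the schedule value exactly
  e1 <- c(0, 0, 1)
  e2 <- g0 - sum(g0 * e1) * e1
  e2 <- if (vec_norm(e2) < 1e-9) c(1, 0, 0) else unit_vec(e2)
  target_vec <- function(phi_deg) {
    th <- phi_deg * pi / 180
    cos(th) * e1 + sin(th) * e2
  }

  X0 <- coords(prot)
  head_ctr <- colMeans(X0[head_idx, , drop = FALSE])
  tm_ctr <- colMeans(X0[tm_idx, , drop = FALSE])
  nprot <- nrow(X0)
  slab_X <- coords(slab)
  all_atoms <- rbind(prot$atoms, slab$atoms)
  n_all <- nrow(all_atoms)
  arr <- array(NA_real_, c(n_all, 3, n_frames))

  z_res <- sort(unique(c(21L, 70L, as.integer(names(z_targets)))))
  z_cols <- paste0("z", z_res, "_A")
  truth <- data.frame(frame = seq_len(n_frames), time_us = times,
                      phi_deg = NA_real_, psi_deg = NA_real_, rg_A = NA_real_)
  for (cn in z_cols) truth[[cn]] <- NA_real_

  frame_model <- structure(list(atoms = prot$atoms), class = "mol_model")
  for (k in seq_len(n_frames)) {
    X <- X0
    # head rotation setting the groove angle exactly
    Rh <- rotation_between(g0, target_vec(phi[k]))
    X[head_idx, ] <- transform_coords(X[head_idx, , drop = FALSE], Rh,
                                      center = head_ctr)
    # TM tilt about an in-plane axis through the TM centroid
    if (psi[k] != 0) {
      Rt <- rotation_about_axis(c(0, 1, 0), psi[k])
      X[tm_idx, ] <- transform_coords(X[tm_idx, , drop = FALSE], Rt,
                                      center = tm_ctr)
    }
    # loop breathing: isotropic rescale about the loop centroid
    if (!is.null(loop_rg)) {
      L <- X[loop_idx, , drop = FALSE]
      ctr <- colMeans(L)
      cur <- sqrt(mean(rowSums(sweep(L, 2, ctr)^2)))
      X[loop_idx, ] <- sweep(sweep(L, 2, ctr) * (loop_rg[k] / cur), 2, ctr, "+")
    }
    # pin residues at prescribed heights above the upper plane
    if (!is.null(z_targets)) {
      for (rn in names(z_targets)) {
        ridx <- resolve_strict(prot, selection(as.integer(rn), atom = "CA"),
                               paste("pinned residue", rn))
        X[ridx, 3] <- mem$upper_plane_z + z_targets[[rn]][k]
      }
    }
    fm <- set_coords(frame_model, X)
    truth$phi_deg[k] <- deviation_angle(groove_vector(fm), mem)
    truth$psi_deg[k] <- deviation_angle(
      helix_principal_axis(fm, helix_def(toy$tm_span[1], toy$tm_span[2])), mem)
    truth$rg_A[k] <- radius_of_gyration(fm, loop_def(toy$loop_span))
    for (j in seq_along(z_res))
      truth[[z_cols[j]]][k] <- z_position(fm, z_res[j], mem)
    arr[seq_len(nprot), , k] <- X
    arr[(nprot + 1):n_all, , k] <- slab_X
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("atomic noise needs an explicit seed")
    arr <- arr + withr::with_seed(seed + 1L,
      array(stats::rnorm(length(arr), 0, noise_sd), dim(arr)))
  }
  traj <- trajectory(mol_model(all_atoms), arr, times)
  attr(truth, "seed") <- seed
  attr(truth, "schedule") <- schedule
  attr(truth, "noise_sd") <- noise_sd
  list(trajectory = traj, truth = truth)
}
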