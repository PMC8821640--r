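#' Bend specification
#'
#' A forward rigid-body model of filament bending: the straight filament
#' axis is mapped onto a circular arc of curvature `kappa` lying in the
#' plane spanned by the axis and the in-plane direction at `azimuth_deg`.
#' Each subunit travels to its arc station as one rigid body (arc length
#' along the neutral axis is preserved), so subunits on the concave side of
#' the bend are compressed together and those on the convex side stretched
#' apart. An optional hinge swing adds an extra rigid rotation of each head
#' domain about its two-residue hinge.
#'
#' @param kappa curvature in 1/Angstrom (>= 0); 0 means straight.
#' @param azimuth_deg azimuth of the bend plane, degrees. Subunits at this
#'   azimuth lie on the concave (compressed) side.
#' @param hinge_swing_deg extra head rotation about the hinge, degrees
#'   (default 0: pure arc mapping).
#' @return object of class `bend_spec`.
#' @export
bend_spec <- function(kappa, azimuth_deg = 0, hinge_swing_deg = 0) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa < 0)
    stop("bend_spec: kappa must be a single finite value >= 0", call. = FALSE)
  structure(list(kappa = kappa, azimuth_deg = azimuth_deg,
                 hinge_swing_deg = hinge_swing_deg),
            class = "bend_spec")
}

#' Bend a straight filament onto a circular arc
#'
#' Rigid-body maps each subunit: its axial station z goes to arc angle
#' theta = kappa * z on a circle of radius 1/kappa in the bend plane, and
#' its local frame is rotated to follow the local tangent. Head and tail
#' domains remain internally rigid; with `hinge_swing_deg` non-zero the head
#' is additionally rotated about the hinge midpoint (about the bend-plane
#' normal). `kappa = 0` returns coordinates identical to the input.
#'
#' @param model a straight [filament_model()].
#' @param spec a [bend_spec()]. The mapping requires
#'   `kappa * filament_radius < 1`, otherwise material on the concave side
#'   would cross the arc centre (self-intersection).
#' @return a bent [filament_model()] (attribute `bent` set).
#' @export
bend_filament <- function(model, spec) {
  stopifnot(inherits(model, "filament_model"), inherits(spec, "bend_spec"))
  if (isTRUE(attr(model, "bent")))
    stop("bend_filament: input model is already bent", call. = FALSE)
  radius <- filament_diameter(model) / 2
  if (spec$kappa * radius >= 1)
    stop("bend_filament: kappa * filament radius = ",
         format(spec$kappa * radius),
         " >= 1: arc mapping would self-intersect", call. = FALSE)
  out <- model
  if (spec$kappa > 0 || spec$hinge_swing_deg != 0) {
    kap <- spec$kappa
    beta <- spec$azimuth_deg * pi / 180
    u <- c(cos(beta), sin(beta), 0)          # in-plane direction
    nrm <- c(-sin(beta), cos(beta), 0)       # bend-plane normal
    zhat <- c(0, 0, 1)
    for (i in seq_along(out$subunits)) {
      sub <- out$subunits[[i]]
      z0 <- sub$index * model$sym$rise
      xyz <- as.matrix(sub$atoms[c("x", "y", "z")])
      if (kap > 0) {
        th <- kap * z0
        arc <- (1 - cos(th)) / kap * u + sin(th) / kap * zhat
        loc <- sweep(xyz, 2, c(0, 0, z0))    # relative to the axial station
        cu <- as.numeric(loc %*% u); cn <- as.numeric(loc %*% nrm)
        cz <- loc[, 3]
        rot <- outer(cu * cos(th) + cz * sin(th), u) + outer(cn, nrm) +
          outer(-cu * sin(th) + cz * cos(th), zhat)
        new <- sweep(rot, 2, arc, `+`)
      } else {
        new <- xyz
      }
      if (spec$hinge_swing_deg != 0) {
        ann <- model$monomers[[sub$species + 1L]]$annotation
        if (is.null(ann))
          stop("bend_filament: hinge swing needs domain annotations",
               call. = FALSE)
        dom <- domain_of(ann, sub$atoms$resno)
        pivot <- colMeans(new[dom == "hinge", , drop = FALSE])
        sel <- dom == "head"
        new[sel, ] <- rotate_about_axis(new[sel, , drop = FALSE], pivot, nrm,
                                        spec$hinge_swing_deg)
      }
      sub$atoms[c("x", "y", "z")] <- new
      sub$op <- NULL
      out$subunits[[i]] <- sub
    }
  }
  attr(out, "bent") <- TRUE
  attr(out, "bend_spec") <- spec
  out
}

# rotate points about an arbitrary axis (unit vector) through a pivot point
rotate_about_axis <- function(xyz, pivot, axis, angle_deg) {
  th <- angle_deg * pi / 180
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  Rm <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(xyz, 2, pivot) %*% t(Rm), 2, pivot, `+`)
}

subunit_domain_sel <- function(model, index, domain) {
  sub <- model$subunits[[index + 1L]]
  ann <- model$monomers[[sub$species + 1L]]$annotation
  if (is.null(ann))
    stop("domain selection needs annotated monomers", call. = FALSE)
  domain_of(ann, sub$atoms$resno) == domain
}

#' Per-subunit rigid-body motion report
#'
#' Compares two conformations of the same filament (e.g. straight vs bent)
#' and reports, per subunit: the centroid displacement vector; the head
#' centroid displacement remaining after superposing the two copies on their
#' tail atoms (head motion relative to the tail, i.e. hinge action); the
#' internal RMSD of the head domain after optimal head superposition (zero
#' when heads move as rigid bodies); the tail axial slide (signed
#' displacement of the tail centroid along the reference filament axis, +z
#' of `frameA`); and the tail rotation about that axis.
#'
#' @param frameA,frameB [filament_model()] objects with identical topology.
#'   `frameA` is the reference frame whose axis defines slide and rotation.
#' @return data.frame of class `motion_report`: columns `subunit`,
#'   `species`, `disp_x`, `disp_y`, `disp_z`, `disp`,
#'   `head_disp_after_tail_align`, `head_internal_rmsd`, `tail_slide`,
#'   `tail_rotation_deg`.
#' @export
motion_report <- function(frameA, frameB) {
  stopifnot(inherits(frameA, "filament_model"),
            inherits(frameB, "filament_model"))
  n <- n_subunits(frameA)
  if (n_subunits(frameB) != n)
    stop("motion_report: frames have different subunit counts", call. = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    a <- frameA$subunits[[i]]$atoms
    b <- frameB$subunits[[i]]$atoms
    if (nrow(a) != nrow(b) || !all(a$atom == b$atom & a$resno == b$resno))
      stop("motion_report: atom topology mismatch at subunit ", i - 1L,
           call. = FALSE)
    A <- as.matrix(a[c("x", "y", "z")]); B <- as.matrix(b[c("x", "y", "z")])
    dc <- colMeans(B) - colMeans(A)
    tail_sel <- subunit_domain_sel(frameA, i - 1L, "tail")
    head_sel <- subunit_domain_sel(frameA, i - 1L, "head")
    # head displacement after tail alignment: fit B onto A by tail atoms,
    # then measure residual head-centroid displacement
    idx <- rep(which(tail_sel), each = 3) * 3 - c(2, 1, 0)
    fitted <- bio3d::fit.xyz(fixed = as.numeric(t(A)),
                             mobile = as.numeric(t(B)),
                             fixed.inds = idx, mobile.inds = idx)
    Bfit <- matrix(fitted, ncol = 3, byrow = TRUE)
    head_disp <- sqrt(sum((colMeans(Bfit[head_sel, , drop = FALSE]) -
                             colMeans(A[head_sel, , drop = FALSE]))^2))
    head_rmsd <- bio3d::rmsd(as.numeric(t(A[head_sel, , drop = FALSE])),
                             as.numeric(t(B[head_sel, , drop = FALSE])),
                             fit = TRUE)
    tA <- A[tail_sel, , drop = FALSE]; tB <- B[tail_sel, , drop = FALSE]
    slide <- mean(tB[, 3]) - mean(tA[, 3])
    # optimal rotation about the reference axis (+z) of the tail atoms
    rot <- atan2(sum(tA[, 1] * tB[, 2] - tA[, 2] * tB[, 1]),
                 sum(tA[, 1] * tB[, 1] + tA[, 2] * tB[, 2])) * 180 / pi
    rows[[i]] <- data.frame(subunit = i - 1L,
                            species = frameA$subunits[[i]]$species,
                            disp_x = dc[1], disp_y = dc[2], disp_z = dc[3],
                            disp = sqrt(sum(dc^2)),
                            head_disp_after_tail_align = head_disp,
                            head_internal_rmsd = head_rmsd,
                            tail_slide = slide, tail_rotation_deg = rot)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("motion_report", "data.frame")
  out
}

#' Write a motion report as TSV
#'
#' @param report a [motion_report()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motion_report <- function(report, path) {
  stopifnot(inherits(report, "motion_report"))
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Head-centroid trajectories across conformations
#'
#' Follows the head-domain centroid of selected subunits through an ordered
#' series of conformations (e.g. a curvature ramp) and reports the path and
#' simple summaries.
#'
#' @param frames list of >= 2 [filament_model()] objects with identical
#'   topology, in frame order.
#' @param subunits 0-based subunit indices to follow (default: all).
#' @return list of class `head_trajectories`; one element per subunit with
#'   `subunit`, `centroids` (frames x 3 matrix), `path_length` and
#'   `net_displacement` (Angstrom).
#' @export
head_trajectories <- function(frames, subunits = NULL) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("head_trajectories: need at least 2 frames", call. = FALSE)
  lapply(frames, function(f) stopifnot(inherits(f, "filament_model")))
  n <- n_subunits(frames[[1]])
  if (is.null(subunits)) subunits <- 0:(n - 1L)
  out <- lapply(subunits, function(i) {
    sel <- subunit_domain_sel(frames[[1]], i, "head")
    ctr <- t(vapply(frames, function(f) {
      colMeans(subunit_xyz(f, i)[sel, , drop = FALSE])
    }, numeric(3)))
    colnames(ctr) <- c("x", "y", "z")
    steps <- sqrt(rowSums((ctr[-1, , drop = FALSE] -
                             ctr[-nrow(ctr), , drop = FALSE])^2))
    list(subunit = i, centroids = ctr, path_length = sum(steps),
         net_displacement = sqrt(sum((ctr[nrow(ctr), ] - ctr[1, ])^2)))
  })
  structure(out, class = "head_trajectories")
}
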