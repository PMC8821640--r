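#' helixlat: helical lattice analysis of heteropolymeric filaments
#'
#' Tools for screw-operator algebra on 1-start helical lattices, reduction of
#' helical symmetry under multi-species register patterns, filament model
#' building, geometric contact analysis and a forward rigid-body bend model.
#' The motivating system is the archaellum, the rotary swimming filament of
#' archaea, whose lattice can be described by a rise (axial translation per
#' subunit, in Angstrom) and a twist (rotation per subunit, in degrees).
#'
#' @section Sign conventions:
#' Positive twist is a right-handed rotation about the +z filament axis when
#' advancing along +z. Subunit index 0 sits at the origin and indices increase
#' with +z. Principal angles live in the half-open interval (-180, 180].
#'
#' @name helixlat-package
#' @keywords internal
"_PACKAGE"

# default comparison tolerances (degrees / Angstrom)
.hlx_tol_deg <- 1e-6
.hlx_tol_ang <- 1e-9

#' Reduce an angle to its principal value
#'
#' Maps an angle in degrees to the congruent value in the half-open interval
#' (-180, 180]. For example a per-period rotation of 648 degrees is reported
#' as -72 degrees (648 = 720 - 72).
#'
#' @param angle_degrees numeric vector of finite angles, in degrees.
#' @return numeric vector of the same length, each value in (-180, 180] and
#'   congruent to the input modulo 360.
#' @examples
#' normalize_twist(648)   # -72
#' normalize_twist(108)   # 108
#' @export
normalize_twist <- function(angle_degrees) {
  if (!is.numeric(angle_degrees) || any(!is.finite(angle_degrees)))
    stop("normalize_twist: angle must be finite numeric", call. = FALSE)
  a <- angle_degrees %% 360
  ifelse(a > 180, a - 360, a)
}

#' Construct a helical symmetry (rise/twist pair)
#'
#' @param rise axial translation per subunit, Angstrom; must be > 0.
#' @param twist rotation per subunit, degrees. Stored both as given
#'   (`twist_raw`, reported modulo 360 in [0, 360)) and as the principal
#'   value in (-180, 180] (`twist`).
#' @return an object of class `helical_symmetry` with fields `rise`,
#'   `twist` (principal) and `twist_raw`.
#' @examples
#' helical_symmetry(5.57, 108)
#' helical_symmetry(33.4, -71.8)
#' @export
helical_symmetry <- function(rise, twist) {
  if (!is.numeric(rise) || length(rise) != 1L || !is.finite(rise) || rise <= 0)
    stop("helical_symmetry: rise must be a single finite value > 0", call. = FALSE)
  if (!is.numeric(twist) || length(twist) != 1L || !is.finite(twist))
    stop("helical_symmetry: twist must be a single finite value", call. = FALSE)
  structure(list(rise = rise,
                 twist = normalize_twist(twist),
                 twist_raw = twist %% 360),
            class = "helical_symmetry")
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("Helical symmetry: rise %s A, twist %s deg (raw %s deg)\n",
              format(signif(x$rise, 6)), format(signif(x$twist, 4)),
              format(signif(x$twist_raw, 4))))
  invisible(x)
}

is_helical_symmetry <- function(x) inherits(x, "helical_symmetry")

#' Screw operator relating subunit n to subunit n + k
#'
#' The generating operator of a 1-start lattice (k = 1) translates by the
#' rise and rotates by the twist; the operator for offset k is its k-fold
#' composition. Negative k gives the inverse displacement.
#'
#' @param sym a [helical_symmetry()].
#' @param k integer subunit offset.
#' @return object of class `screw_operator` with fields `k`, `delta_z`
#'   (Angstrom) and `delta_phi` (degrees, raw/unreduced).
#' @examples
#' screw_operator(helical_symmetry(5.57, 108), 6)
#' @export
screw_operator <- function(sym, k) {
  stopifnot(is_helical_symmetry(sym))
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k != round(k))
    stop("screw_operator: k must be a single integer", call. = FALSE)
  k <- as.integer(k)
  structure(list(k = k, delta_z = k * sym$rise, delta_phi = k * sym$twist),
            class = "screw_operator")
}

#' @export
print.screw_operator <- function(x, ...) {
  cat(sprintf("Screw operator n -> n%+d: dz %s A, dphi %s deg (principal %s deg)\n",
              x$k, format(signif(x$delta_z, 6)), format(signif(x$delta_phi, 4)),
              format(signif(normalize_twist(x$delta_phi), 4))))
  invisible(x)
}

#' Compose two screw operators
#'
#' Operators about a common axis commute; the composite translates by the sum
#' of translations and rotates by the sum of rotations.
#'
#' @param a,b `screw_operator` objects.
#' @return a `screw_operator` for offset `a$k + b$k`.
#' @export
compose_screw <- function(a, b) {
  stopifnot(inherits(a, "screw_operator"), inherits(b, "screw_operator"))
  structure(list(k = a$k + b$k, delta_z = a$delta_z + b$delta_z,
                 delta_phi = a$delta_phi + b$delta_phi),
            class = "screw_operator")
}

#' Apply a screw operator to coordinates
#'
#' Rotates about +z by `delta_phi` degrees (right-handed) and translates by
#' `delta_z` along +z.
#'
#' @param op a `screw_operator` (or any list with `delta_z`, `delta_phi`).
#' @param xyz n x 3 numeric matrix of coordinates, Angstrom.
#' @return transformed n x 3 matrix.
#' @export
apply_screw <- function(op, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3)
  th <- op$delta_phi * pi / 180
  ct <- cos(th); st <- sin(th)
  out <- cbind(ct * xyz[, 1] - st * xyz[, 2],
               st * xyz[, 1] + ct * xyz[, 2],
               xyz[, 3] + op$delta_z)
  dimnames(out) <- dimnames(xyz)
  out
}

#' Reduce helical symmetry to a larger repeating unit
#'
#' If the true asymmetric unit repeats only every `period` subunits (for
#' example because several subunit species alternate), the lattice is
#' described by the `period`-fold composed operator: rise multiplied by the
#' period and twist multiplied then wrapped. The classic two-species,
#' three-strand archaellum case reduces (5.57 A, 108 deg) by period 6 to
#' (33.42 A, -72 deg), while the hypothetical in-register alternation reduces
#' by period 2 to (11.14 A, raw 216 deg).
#'
#' @param sym a [helical_symmetry()].
#' @param period positive integer.
#' @return a [helical_symmetry()] with `rise = period * rise`, raw twist
#'   `period * twist` modulo 360 and the principal twist alongside.
#' @examples
#' reduce_symmetry(helical_symmetry(5.57, 108), 6)  # 33.42 A, -72 deg
#' reduce_symmetry(helical_symmetry(5.57, 108), 2)  # 11.14 A, raw 216 deg
#' @export
reduce_symmetry <- function(sym, period) {
  stopifnot(is_helical_symmetry(sym))
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period != round(period) || period < 1)
    stop("reduce_symmetry: period must be an integer >= 1", call. = FALSE)
  helical_symmetry(period * sym$rise, period * sym$twist)
}

#' Geometry of the k-start strand family
#'
#' Connecting every k-th subunit of a 1-start lattice partitions the filament
#' into k strands (the k-start family). One step along such a strand advances
#' by k times the rise and rotates by the principal value of k times the
#' twist; the sign of that step angle sets the strand handedness.
#'
#' @param sym a [helical_symmetry()].
#' @param k positive integer family order.
#' @param tol_degrees angles within this of 0 are treated as vertical.
#' @return object of class `start_family` with `k`, `step_rise` (A),
#'   `step_phi` (principal degrees), `handedness` ("left", "right" or
#'   "vertical") and `n_strands` (= k).
#' @examples
#' start_family(helical_symmetry(5.57, 108), 3)   # -36 deg: left-handed
#' start_family(helical_symmetry(5.57, 108), 7)   # +36 deg: right-handed
#' start_family(helical_symmetry(5.57, 108), 10)  # 0 deg: vertical columns
#' @export
start_family <- function(sym, k, tol_degrees = .hlx_tol_deg) {
  stopifnot(is_helical_symmetry(sym))
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1)
    stop("start_family: k must be an integer >= 1", call. = FALSE)
  k <- as.integer(k)
  step_phi <- normalize_twist(k * sym$twist)
  handed <- if (abs(step_phi) <= tol_degrees) "vertical"
            else if (step_phi > 0) "right" else "left"
  structure(list(k = k, step_rise = k * sym$rise, step_phi = step_phi,
                 handedness = handed, n_strands = k),
            class = "start_family")
}

#' @export
print.start_family <- function(x, ...) {
  cat(sprintf("%d-start family: %d strands, step %s A / %s deg (%s-handed)\n",
              x$k, x$n_strands, format(signif(x$step_rise, 6)),
              format(signif(x$step_phi, 4)), x$handedness))
  invisible(x)
}

#' Smallest axial-repeat offset
#'
#' Finds the smallest subunit offset k whose accumulated rotation is a
#' multiple of 360 degrees within tolerance, i.e. the k-start family whose
#' strands are vertical columns parallel to the filament axis. For a
#' 108-degree twist this is k = 10 (the axial column sets used to follow
#' tail up-down motion along a bent filament).
#'
#' @param sym a [helical_symmetry()].
#' @param max_k largest offset to try (>= 1).
#' @param tol_degrees angular tolerance.
#' @return the smallest such integer k, or `NA_integer_` if none exists up
#'   to `max_k`.
#' @examples
#' axial_repeat(helical_symmetry(5.57, 108), 20)    # 10
#' axial_repeat(helical_symmetry(33.4, -71.8), 20)  # NA: incommensurate
#' @export
axial_repeat <- function(sym, max_k, tol_degrees = .hlx_tol_deg) {
  stopifnot(is_helical_symmetry(sym))
  if (!is.numeric(max_k) || length(max_k) != 1L || max_k < 1)
    stop("axial_repeat: max_k must be >= 1", call. = FALSE)
  if (!is.numeric(tol_degrees) || tol_degrees < 0)
    stop("axial_repeat: tol_degrees must be >= 0", call. = FALSE)
  for (k in seq_len(as.integer(max_k))) {
    if (abs(normalize_twist(k * sym$twist)) <= tol_degrees) return(k)
  }
  NA_integer_
}

#' Write/read a helical symmetry as plain key-value config
#'
#' The format is two `key = value` lines (`rise_angstrom`, `twist_degrees`),
#' order-insensitive, `#` comments allowed.
#'
#' @param sym a [helical_symmetry()].
#' @param path file path.
#' @return `write_symmetry` returns `path` invisibly; `read_symmetry`
#'   returns a [helical_symmetry()].
#' @export
write_symmetry <- function(sym, path) {
  stopifnot(is_helical_symmetry(sym))
  writeLines(c(sprintf("rise_angstrom = %.10g", sym$rise),
               sprintf("twist_degrees = %.10g", sym$twist)), path)
  invisible(path)
}

#' @rdname write_symmetry
#' @export
read_symmetry <- function(path) {
  kv <- read_keyvals(path)
  need <- c("rise_angstrom", "twist_degrees")
  if (!all(need %in% names(kv)))
    stop("read_symmetry: missing keys: ",
         paste(setdiff(need, names(kv)), collapse = ", "), call. = FALSE)
  helical_symmetry(as.numeric(kv[["rise_angstrom"]]),
                   as.numeric(kv[["twist_degrees"]]))
}

# parse "key = value" lines, ignoring blanks and # comments
read_keyvals <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  hit <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", ln))
  bad <- vapply(hit, length, 1L) != 3L
  if (any(bad))
    stop("malformed config line: ", ln[which(bad)[1]], call. = FALSE)
  stats::setNames(vapply(hit, `[`, "", 3L), vapply(hit, `[`, "", 2L))
}
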