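#' Helical net diagram
#'
#' Unwraps the filament surface lattice into a 2D plot of azimuth (degrees,
#' modulo 360) against axial position (Angstrom), one point per subunit.
#' When a subunit labeling is supplied each point carries its species, which
#' makes the alternation pattern and any out-of-register strand visible, as
#' in the classic net-diagram analysis of two-species archaella.
#'
#' @param sym a [helical_symmetry()].
#' @param n_subunits number of subunits to place (>= 1), indices 0..n-1.
#' @param labeling optional [subunit_labeling()]; adds a `species` column.
#' @return a data.frame of class `net_diagram` with columns `index`,
#'   `azimuth_deg` (in [0, 360)), `z_angstrom` and `species` (NA when no
#'   labeling is given).
#' @examples
#' net_diagram(helical_symmetry(5.57, 108), 12)
#' @export
net_diagram <- function(sym, n_subunits, labeling = NULL) {
  stopifnot(is_helical_symmetry(sym))
  if (!is.numeric(n_subunits) || length(n_subunits) != 1L || n_subunits < 1 ||
      n_subunits != round(n_subunits))
    stop("net_diagram: n_subunits must be an integer >= 1", call. = FALSE)
  i <- seq_len(n_subunits) - 1L
  sp <- if (is.null(labeling)) rep(NA_integer_, length(i))
        else species_at(labeling, i)
  out <- data.frame(index = i,
                    azimuth_deg = (i * sym$twist) %% 360,
                    z_angstrom = i * sym$rise,
                    species = sp)
  class(out) <- c("net_diagram", "data.frame")
  out
}

#' Export a net diagram as a tab-separated table
#'
#' @param net a [net_diagram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_net_diagram <- function(net, path) {
  stopifnot(inherits(net, "net_diagram"))
  utils::write.table(net, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
plot.net_diagram <- function(x, ...) {
  sp <- x$species
  col <- if (all(is.na(sp))) "black" else grDevices::hcl.colors(
    max(sp, na.rm = TRUE) + 1L, "Dark 3")[sp + 1L]
  graphics::plot(x$azimuth_deg, x$z_angstrom, col = col, pch = 19,
                 xlab = "azimuth (deg)", ylab = "z (Angstrom)",
                 xlim = c(0, 360), ...)
  invisible(x)
}
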