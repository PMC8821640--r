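#' Fixture configuration for the toy archaellum-like filament
#'
#' Parameters of the synthetic two-species filament used throughout the test
#' suite and examples. The lattice and register are those of a two-species
#' archaellum: rise 5.57 Angstrom, twist 108 degrees, species alternating
#' along the three 3-start strands with one strand out of register (offsets
#' (0,0,1), labeling period 6). Toy monomers have a 46-residue ideal-helix
#' tail (1.5 Angstrom axial spacing per residue, end-to-end about 69
#' Angstrom), a two-residue Ser-Gly hinge and a globular pseudo-atom head;
#' species 1 carries an extra outward-facing loop.
#'
#' The tail centre-line runs from radius `tail_r0` at the filament core to
#' `tail_r1` at azimuthal sweep `tail_sweep_deg`. These constants are
#' calibration constants, fixed in version control: on this lattice they put
#' the tail-segment contact shell at exactly {+-1, +-3, +-4, +-7} with at
#' least 1.4 Angstrom margin on either side of the 8 Angstrom cutoff.
#'
#' @param rise,twist lattice parameters (Angstrom, degrees).
#' @param strands,species,offsets register pattern (see
#'   [register_pattern()]).
#' @param tail_residues number of tail residues.
#' @param tail_spacing axial spacing per tail residue along the tail axis.
#' @param tail_r0,tail_r1,tail_sweep_deg tail centre-line calibration.
#' @param helix_radius radius of the ideal helix around the centre-line.
#' @param head_center_radius,head_sphere_radius head placement (Angstrom).
#' @param head_residues number of head shell pseudo-residues.
#' @param seed integer seed for the small deterministic coordinate jitter.
#' @return object of class `fixture_config`.
#' @export
fixture_config <- function(rise = 5.57, twist = 108,
                           strands = 3, species = 2, offsets = c(0, 0, 1),
                           tail_residues = 46, tail_spacing = 1.5,
                           tail_r0 = 4.5, tail_r1 = 16, tail_sweep_deg = 80,
                           helix_radius = 2.3,
                           head_center_radius = 38, head_sphere_radius = 11,
                           head_residues = 60, seed = 7) {
  vals <- c(rise, tail_residues, tail_spacing, tail_r0, tail_r1, helix_radius,
            head_center_radius, head_sphere_radius, head_residues)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("fixture_config: size parameters must be positive", call. = FALSE)
  structure(list(rise = rise, twist = twist, strands = strands,
                 species = species, offsets = offsets,
                 tail_residues = tail_residues, tail_spacing = tail_spacing,
                 tail_r0 = tail_r0, tail_r1 = tail_r1,
                 tail_sweep_deg = tail_sweep_deg, helix_radius = helix_radius,
                 head_center_radius = head_center_radius,
                 head_sphere_radius = head_sphere_radius,
                 head_residues = head_residues, seed = as.integer(seed)),
            class = "fixture_config")
}

# evaluate expr with a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# deterministic near-uniform points on a unit sphere (golden-angle spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(th), r * sin(th), z)
}

#' Generate a toy archaellin-like monomer
#'
#' Builds a reduced-representation monomer positioned for subunit index 0 of
#' the fixture lattice: a 46-residue alpha-helical tail wound around a
#' calibrated centre-line rising from the filament core, a Ser60-Gly61
#' hinge, and a globular head modelled as a pseudo-atom shell. The head also
#' carries a small set of typed polar/charged sites (Ser OG, backbone O,
#' Lys NZ, Glu OE1) planted across the 3-start interface so that built
#' filaments show hydrogen-bond and salt-bridge contacts between 3-start
#' neighbours. Species 1 carries an extra outward-facing loop (residues
#' 131-137) and therefore more atoms than species 0. Coordinates are
#' deterministic given the config seed.
#'
#' @param config a [fixture_config()].
#' @param species species id, 0 or 1.
#' @return an annotated [monomer_model()].
#' @export
make_toy_monomer <- function(config = fixture_config(), species = 0L) {
  stopifnot(inherits(config, "fixture_config"))
  species <- as.integer(species)
  if (!species %in% c(0L, 1L))
    stop("make_toy_monomer: species must be 0 or 1", call. = FALSE)
  L <- config$tail_residues * config$tail_spacing  # tail end-to-end target
  psi <- config$tail_sweep_deg * pi / 180
  A <- c(config$tail_r0, 0, 0)
  Bxy <- config$tail_r1 * c(cos(psi), sin(psi))
  planar <- sqrt(sum((Bxy - A[1:2])^2))
  if (planar >= L)
    stop("make_toy_monomer: tail sweep exceeds tail length", call. = FALSE)
  B <- c(Bxy, sqrt(L^2 - planar^2))
  axis <- (B - A) / L
  # orthonormal frame around the centre-line
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- ref - sum(ref * axis) * axis; v <- v / sqrt(sum(v^2))
  w <- c(axis[2] * v[3] - axis[3] * v[2],
         axis[3] * v[1] - axis[1] * v[3],
         axis[1] * v[2] - axis[2] * v[1])
  nt <- config$tail_residues
  t <- (seq_len(nt) - 1) / (nt - 1)
  phase <- (seq_len(nt) - 1) * 100 * pi / 180  # ~3.6 residues/turn
  tail_xyz <- t(vapply(seq_len(nt), function(j) {
    A + t[j] * (B - A) + config$helix_radius *
      (cos(phase[j]) * v + sin(phase[j]) * w)
  }, numeric(3)))
  tail_resid <- rep_len(c("ILE", "LEU", "VAL", "ALA", "PHE", "GLY"), nt)
  tail_resid[1] <- "ILE"; tail_resid[nt] <- "ALA"
  tail <- data.frame(atom = "CA", element = "C", resid = tail_resid,
                     resno = 13L + seq_len(nt),  # residues 14..59
                     x = tail_xyz[, 1], y = tail_xyz[, 2], z = tail_xyz[, 3])
  # head centre, continuing outward from the tail top
  hc_az <- psi + 10 * pi / 180
  Ch <- c(config$head_center_radius * cos(hc_az),
          config$head_center_radius * sin(hc_az),
          B[3] + 8)
  # hinge Ser60-Gly61 between tail top and head
  hdir <- (Ch - B); hdir <- hdir / sqrt(sum(hdir^2))
  hinge <- data.frame(
    atom = c("CA", "OG", "CA"), element = c("C", "O", "C"),
    resid = c("SER", "SER", "GLY"), resno = c(60L, 60L, 61L),
    x = c(B[1] + 3 * hdir[1], B[1] + 3 * hdir[1] + 0.8, B[1] + 6 * hdir[1]),
    y = c(B[2] + 3 * hdir[2], B[2] + 3 * hdir[2] + 0.8, B[2] + 6 * hdir[2]),
    z = c(B[3] + 3 * hdir[3], B[3] + 3 * hdir[3], B[3] + 6 * hdir[3]))
  # head shell: pseudo-CA on a sphere with a small deterministic jitter
  sph <- fibonacci_sphere(config$head_residues)
  jit <- with_seed(config$seed + species, matrix(
    stats::rnorm(3 * config$head_residues, 0, 0.15), ncol = 3))
  hx <- sweep(config$head_sphere_radius * sph + jit, 2, Ch, `+`)
  head <- data.frame(atom = "CA", element = "C",
                     resid = rep_len(c("GLY", "THR", "ASN", "VAL"),
                                     config$head_residues),
                     resno = 61L + seq_len(config$head_residues),
                     x = hx[, 1], y = hx[, 2], z = hx[, 3])
  # polar sites planted across the 3-start (k = +3) head-head interface:
  # donor atoms sit halfway to the k = +3 neighbour's acceptor positions
  sym <- helical_symmetry(config$rise, config$twist)
  op3 <- screw_operator(sym, 3L)
  inv3 <- screw_operator(sym, -3L)
  C3 <- as.numeric(apply_screw(op3, matrix(Ch, 1)))
  e <- (C3 - Ch) / sqrt(sum((C3 - Ch)^2))
  M <- (Ch + C3) / 2
  nperp <- c(-e[2], e[1], 0); nperp <- nperp / sqrt(sum(nperp^2))
  M2 <- M + 3 * nperp
  p_og <- M - 1.45 * e                                  # Ser OG donor
  p_o <- as.numeric(apply_screw(inv3, matrix(M + 1.45 * e, 1)))   # Gly O
  p_nz <- M2 - 1.6 * e                                  # Lys NZ
  p_oe <- as.numeric(apply_screw(inv3, matrix(M2 + 1.6 * e, 1)))  # Glu OE1
  r0 <- 61L + config$head_residues
  planted <- data.frame(
    atom = c("CA", "OG", "CA", "O", "CA", "NZ", "CA", "OE1"),
    element = c("C", "O", "C", "O", "C", "N", "C", "O"),
    resid = c("SER", "SER", "GLY", "GLY", "LYS", "LYS", "GLU", "GLU"),
    resno = rep(r0 + 1:4, each = 2L),
    x = c(p_og[1] - 1, p_og[1], p_o[1] - 1, p_o[1],
          p_nz[1] - 1, p_nz[1], p_oe[1] - 1, p_oe[1]),
    y = c(p_og[2], p_og[2], p_o[2], p_o[2],
          p_nz[2], p_nz[2], p_oe[2], p_oe[2]),
    z = c(p_og[3] + 1, p_og[3], p_o[3] + 1, p_o[3],
          p_nz[3] + 1, p_nz[3], p_oe[3] + 1, p_oe[3]))
  atoms <- rbind(tail, hinge, head, planted)
  if (species == 1L) {
    # outward-facing glycosylation-like loop, K131-A137 style
    out_dir <- Ch / sqrt(sum(Ch^2))
    lt <- seq(-0.5, 0.5, length.out = 7)
    loop_xyz <- t(vapply(seq_len(7), function(j) {
      Ch + (config$head_sphere_radius + 4 + 3 * cos(pi * lt[j])) * out_dir +
        c(0, 0, 6 * lt[j])
    }, numeric(3)))
    loop <- data.frame(atom = "CA", element = "C",
                       resid = c("LYS", "ASN", "ASN", "THR", "THR", "GLY",
                                 "ALA"),
                       resno = as.integer(130 + 1:7),
                       x = loop_xyz[, 1], y = loop_xyz[, 2], z = loop_xyz[, 3])
    atoms <- rbind(atoms, loop)
  }
  atoms <- atoms[order(atoms$resno), ]
  rownames(atoms) <- NULL
  ann <- domain_annotation(c(14, 59), c(60, 61), c(62, max(atoms$resno)))
  monomer_model(atoms, species = species, annotation = ann)
}

#' Build the packaged archaellum-like fixture filament
#'
#' Straight two-species filament on the 5.57 Angstrom / 108 degree lattice
#' with the three-strand, one-out-of-register pattern (labeling period 6,
#' first six labels 0,0,1,1,1,0). The toy tail geometry is calibrated so
#' that [tail_core_contacts()] on an interior subunit returns
#' {-7, -4, -3, -1, 1, 3, 4, 7}.
#'
#' @param preset fixture name; only `"mvillosus"` is defined.
#' @param n number of subunits (>= 6).
#' @param config a [fixture_config()].
#' @return a [filament_model()].
#' @export
make_fixture_filament <- function(preset = "mvillosus", n = 24,
                                  config = fixture_config()) {
  preset <- match.arg(preset, "mvillosus")
  if (!is.numeric(n) || length(n) != 1L || n < 6 || n != round(n))
    stop("make_fixture_filament: n must be an integer >= 6", call. = FALSE)
  monomers <- lapply(seq_len(config$species) - 1L,
                     function(s) make_toy_monomer(config, s))
  lab <- labeling_from_register(
    register_pattern(config$strands, config$species, config$offsets))
  build_filament(monomers, helical_symmetry(config$rise, config$twist),
                 lab, n)
}

#' Generate a (possibly corrupted) species label sequence
#'
#' Draws `n` labels from a register pattern and flips each one independently
#' to a different species with probability `error_rate`. Deterministic given
#' the seed; with `error_rate = 0` the output equals
#' [labeling_from_register()] exactly and round-trips through
#' [infer_register()].
#'
#' @param rp a [register_pattern()].
#' @param n sequence length.
#' @param error_rate per-position corruption probability in [0, 1].
#' @param seed integer seed.
#' @return integer vector of species labels for subunits 0..n-1.
#' @export
make_label_sequence <- function(rp, n, error_rate = 0, seed = 1) {
  stopifnot(inherits(rp, "register_pattern"))
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 1)
    stop("make_label_sequence: error_rate must be in [0, 1]", call. = FALSE)
  lab <- labeling_from_register(rp)
  x <- species_at(lab, 0:(n - 1L))
  if (error_rate > 0 && rp$q > 1) {
    x <- with_seed(seed, {
      flip <- stats::runif(n) < error_rate
      shift <- sample.int(rp$q - 1L, n, replace = TRUE)
      ifelse(flip, (x + shift) %% rp$q, x)
    })
  }
  as.integer(x)
}
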