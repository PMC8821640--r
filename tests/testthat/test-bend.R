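test_that("zero curvature is the identity mapping", {
  b0 <- bend_filament(mv_fil, bend_spec(0))
  for (i in c(1, 15, 30))
    expect_identical(b0$subunits[[i]]$atoms[c("x", "y", "z")],
                     mv_fil$subunits[[i]]$atoms[c("x", "y", "z")])
})

test_that("excessive curvature triggers the self-intersection guard", {
  r <- filament_diameter(mv_fil) / 2
  expect_error(bend_filament(mv_fil, bend_spec(1.01 / r)), "self-intersect")
  expect_no_error(bend_filament(mv_fil, bend_spec(0.5 / r)))
  expect_error(bend_spec(-1), "kappa")
  expect_error(bend_filament(bend_filament(mv_fil, bend_spec(1e-3)),
                             bend_spec(1e-3)), "already bent")
})

test_that("the neutral axis is mapped isometrically onto the arc", {
  # single-atom monomer on the axis: subunit i sits exactly at (0, 0, i*rise)
  axis_fil <- point_filament(c(0, 0, 0), mv_sym, 20)
  kap <- 2e-3
  bent <- bend_filament(axis_fil, bend_spec(kap))
  pos <- t(vapply(bent$subunits, function(s)
    as.numeric(s$atoms[1, c("x", "y", "z")]), numeric(3)))
  R <- 1 / kap
  centre <- c(R, 0, 0)
  # every mapped station lies on the arc circle...
  radii <- sqrt((pos[, 1] - centre[1])^2 + pos[, 3]^2)
  expect_equal(radii, rep(R, 20), tolerance = 1e-9)
  # ...and consecutive stations subtend kappa*rise, i.e. arc length = rise
  for (i in 1:19) {
    v1 <- c(pos[i, 1] - R, pos[i, 3]); v2 <- c(pos[i + 1, 1] - R, pos[i + 1, 3])
    ang <- acos(sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))
    expect_equal(R * ang, mv_sym$rise, tolerance = 1e-9)
  }
  # chords are shorter than the arc (sanity on the geometry)
  chord <- sqrt(sum((pos[2, ] - pos[1, ])^2))
  expect_lt(chord, mv_sym$rise)
  expect_equal(chord, 2 * R * sin(kap * mv_sym$rise / 2), tolerance = 1e-9)
})

test_that("subunits are compressed concave-side and stretched convex-side", {
  kap <- 1e-3
  # columns of single atoms at radius 49, one on each side of the bend plane
  concave <- point_filament(c(49, 0, 0), helical_symmetry(5.57, 0), 10)
  convex <- point_filament(c(-49, 0, 0), helical_symmetry(5.57, 0), 10)
  spacing <- function(fil) {
    b <- bend_filament(fil, bend_spec(kap, azimuth_deg = 0))
    pos <- t(vapply(b$subunits, function(s)
      as.numeric(s$atoms[1, c("x", "y", "z")]), numeric(3)))
    mean(sqrt(rowSums((pos[-1, ] - pos[-10, ])^2)))
  }
  ratio <- spacing(convex) / spacing(concave)
  expect_equal(ratio, (1 + 49 * kap) / (1 - 49 * kap), tolerance = 1e-6)
  expect_gt(ratio, 1)  # convex spacing strictly exceeds concave
})

test_that("domains stay internally rigid across bent frames", {
  for (spec in list(bend_spec(1e-3), bend_spec(3e-3, azimuth_deg = 40),
                    bend_spec(1e-3, hinge_swing_deg = 8))) {
    bent <- bend_filament(mv_fil, spec)
    mr <- motion_report(mv_fil, bent)
    expect_lt(max(mr$head_internal_rmsd), 1e-9)
    # tail rigidity: per-subunit tail RMSD after optimal superposition
    for (i in c(0, 14, 29)) {
      sel <- helixlat:::subunit_domain_sel(mv_fil, i, "tail")
      A <- as.matrix(mv_fil$subunits[[i + 1]]$atoms[sel, c("x", "y", "z")])
      B <- as.matrix(bent$subunits[[i + 1]]$atoms[sel, c("x", "y", "z")])
      expect_lt(bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)), fit = TRUE),
                1e-9)
    }
  }
})

test_that("atom displacement vanishes linearly as curvature goes to zero", {
  max_disp <- function(kap) {
    bent <- bend_filament(mv_fil, bend_spec(kap))
    max(vapply(seq_len(30), function(i) {
      A <- as.matrix(mv_fil$subunits[[i]]$atoms[c("x", "y", "z")])
      B <- as.matrix(bent$subunits[[i]]$atoms[c("x", "y", "z")])
      sqrt(max(rowSums((A - B)^2)))
    }, 0))
  }
  d <- vapply(c(8e-4, 4e-4, 2e-4, 1e-4), max_disp, 0)
  expect_true(all(diff(d) < 0))
  # halving kappa roughly halves the displacement (linear regime)
  expect_equal(d[-1] / d[-4], rep(0.5, 3), tolerance = 0.05)
})

test_that("motion reports are zero for identical frames and typed otherwise", {
  mr0 <- motion_report(mv_fil, mv_fil)
  expect_true(all(abs(mr0$disp) < 1e-12))
  expect_true(all(abs(mr0$head_disp_after_tail_align) < 1e-9))
  expect_true(all(abs(mr0$tail_slide) < 1e-12))
  expect_true(all(abs(mr0$tail_rotation_deg) < 1e-9))
  short <- make_fixture_filament("mvillosus", 12)
  expect_error(motion_report(mv_fil, short), "subunit counts")
  f <- tempfile(fileext = ".tsv")
  write_motion_report(mr0, f)
  expect_equal(nrow(utils::read.delim(f)), 30)
})

test_that("opposite axial columns slide in opposite directions when bent", {
  # subunits k and k+5 sit in axial columns 180 degrees apart (5*108 = 540);
  # subunits k and k+10 share a column (10*108 = 1080 = 0 mod 360)
  ref <- 8
  tails <- helixlat:::subunit_domain_sel(mv_fil, ref, "tail")
  ctr <- colMeans(as.matrix(
    mv_fil$subunits[[ref + 1]]$atoms[tails, c("x", "y", "z")]))
  az <- atan2(ctr[2], ctr[1]) * 180 / pi
  bent <- bend_filament(mv_fil, bend_spec(1.5e-3, azimuth_deg = az))
  mr <- motion_report(mv_fil, bent)
  s <- mr$tail_slide
  expect_true(sign(s[ref + 1]) != sign(s[ref + 5 + 1]))  # opposite columns
  expect_true(sign(s[ref + 1]) == sign(s[ref + 10 + 1])) # same column
  # tails also rotate about the axis on the bent filament
  expect_gt(max(abs(mr$tail_rotation_deg)), 0)
})

test_that("head trajectories grow monotonically along a curvature ramp", {
  kappas <- c(0, 5e-4, 1e-3, 1.5e-3, 2e-3)
  frames <- lapply(kappas, function(k) bend_filament(mv_fil, bend_spec(k)))
  tr <- head_trajectories(frames, c(6, 14))
  for (t in tr) {
    disp <- sqrt(rowSums((t$centroids -
      matrix(t$centroids[1, ], nrow(t$centroids), 3, byrow = TRUE))^2))
    expect_true(all(diff(disp) > 0))
    expect_gte(t$path_length, t$net_displacement)
  }
  # identical frames give zero-length paths
  tr0 <- head_trajectories(list(mv_fil, mv_fil, mv_fil), 5)
  expect_equal(tr0[[1]]$path_length, 0)
  expect_equal(tr0[[1]]$net_displacement, 0)
  # rigid whole-filament translation leaves trajectory shapes congruent
  shifted <- lapply(frames, translate_filament, shift = c(10, -5, 3))
  trs <- head_trajectories(shifted, c(6, 14))
  for (i in 1:2) {
    expect_equal(trs[[i]]$path_length, tr[[i]]$path_length, tolerance = 1e-9)
    expect_equal(trs[[i]]$net_displacement, tr[[i]]$net_displacement,
                 tolerance = 1e-9)
  }
  expect_error(head_trajectories(list(mv_fil), 1), "at least 2")
})

test_that("the hinge swing moves heads relative to tails", {
  swung <- bend_filament(mv_fil, bend_spec(0, hinge_swing_deg = 10))
  mr <- motion_report(mv_fil, swung)
  expect_gt(min(mr$head_disp_after_tail_align), 0.5)
  expect_lt(max(mr$head_internal_rmsd), 1e-9)
  # tails untouched at zero curvature
  expect_true(all(abs(mr$tail_slide) < 1e-12))
})
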