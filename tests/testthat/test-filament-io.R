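test_that("build_filament places subunits by the screw operators", {
  cfg <- fixture_config()
  monomers <- lapply(0:1, function(s) make_toy_monomer(cfg, s))
  one <- build_filament(monomers, mv_sym, mv_lab, 1)
  expect_equal(as.matrix(one$subunits[[1]]$atoms[c("x", "y", "z")]),
               as.matrix(monomers[[1]]$atoms[c("x", "y", "z")]))
  fil <- build_filament(monomers, mv_sym, mv_lab, 12)
  # centroid azimuth advances by k * 108 degrees
  ctr0 <- colMeans(as.matrix(fil$subunits[[1]]$atoms[c("x", "y", "z")]))
  for (k in c(1, 5, 11)) {
    ck <- colMeans(as.matrix(fil$subunits[[k + 1]]$atoms[c("x", "y", "z")]))
    daz <- (atan2(ck[2], ck[1]) - atan2(ctr0[2], ctr0[1])) * 180 / pi
    expect_lt(abs(normalize_twist(daz - k * 108)), 1e-6)
    expect_equal(unname(ck[3] - ctr0[3]), k * 5.57, tolerance = 1e-9)
  }
  # species counts follow the period-6 pattern
  fil60 <- build_filament(monomers, mv_sym, mv_lab, 60)
  sp <- vapply(fil60$subunits, function(s) s$species, 0L)
  expect_equal(unname(table(sp)), c(30L, 30L), ignore_attr = TRUE)
  # missing species monomer
  expect_error(build_filament(monomers[1], mv_sym, mv_lab, 12),
               "no monomer")
})

test_that("inverse screw operators reproduce the reference monomer", {
  for (i in c(0, 7, 23)) {
    sub <- mv_fil$subunits[[i + 1]]
    ref <- mv_fil$monomers[[sub$species + 1]]
    back <- apply_screw(screw_operator(mv_sym, -i),
                        as.matrix(sub$atoms[c("x", "y", "z")]))
    rmsd <- sqrt(mean(rowSums(
      (back - as.matrix(ref$atoms[c("x", "y", "z")]))^2)))
    expect_lt(rmsd, 1e-6)
  }
})

test_that("species counts are constant over any period window", {
  sp <- vapply(mv_fil$subunits, function(s) s$species, 0L)
  p <- mv_lab$period
  counts <- sapply(1:(length(sp) - p + 1), function(start)
    sum(sp[start:(start + p - 1)] == 0))
  expect_true(all(counts == counts[1]))
})

test_that("mmCIF write/read round-trips atoms and chains", {
  small <- make_fixture_filament("mvillosus", 12)
  f <- tempfile(fileext = ".cif")
  write_structure(small, f)
  back <- read_structure(f)
  n_expected <- sum(vapply(small$subunits, function(s) nrow(s$atoms), 0L))
  expect_equal(nrow(back), n_expected)
  expect_equal(length(unique(back$chain)), 12)
  for (i in c(1, 6, 12)) {
    orig <- small$subunits[[i]]$atoms
    got <- back[back$chain == sprintf("S%04d", i), ]
    expect_equal(got$atom, orig$atom)
    expect_equal(got$resno, orig$resno)
    expect_lt(max(abs(got$x - orig$x), abs(got$y - orig$y),
                  abs(got$z - orig$z)), 1e-3)
  }
})

test_that("PDB output is limited to 62 single-character chains", {
  small <- make_fixture_filament("mvillosus", 8)
  f <- tempfile(fileext = ".pdb")
  write_structure(small, f, format = "pdb")
  back <- read_structure(f)
  expect_equal(length(unique(back$chain)), 8)
  orig <- small$subunits[[3]]$atoms
  got <- back[back$chain == "C", ]
  expect_lt(max(abs(got$x - orig$x)), 1e-3)
  big <- make_fixture_filament("mvillosus", 63)
  expect_error(write_structure(big, f, format = "pdb"), "mmCIF")
})

test_that("read_monomer derives the head range from tail and hinge", {
  small <- make_fixture_filament("mvillosus", 6)
  f <- tempfile(fileext = ".cif")
  write_structure(small, f)
  # extract the first chain as a monomer file
  at <- read_structure(f)
  one <- at[at$chain == "S0001", ]
  g <- tempfile(fileext = ".cif")
  one$subunit <- 0L
  write_structure(
    structure(list(sym = mv_sym, labeling = mv_lab,
                   monomers = small$monomers,
                   subunits = list(list(index = 0L, species = 0L, op = NULL,
                                        atoms = one))),
              class = "filament_model"), g)
  mono <- read_monomer(g, species = 0, tail = c(14, 59), hinge = c(60, 61))
  expect_s3_class(mono, "monomer_model")
  expect_equal(mono$annotation$head, c(62L, max(one$resno)))
  expect_error(read_structure(tempfile(fileext = ".xyz")), "unsupported")
})

test_that("monomer validation rejects malformed input", {
  df <- data.frame(atom = "CA", element = "C", resid = "ALA", resno = 5L,
                   x = 0, y = 0, z = NA_real_)
  expect_error(monomer_model(df), "finite")
  df2 <- data.frame(atom = c("CA", "CA"), element = "C", resid = "ALA",
                    resno = c(5L, 4L), x = 0, y = 0, z = 0)
  expect_error(monomer_model(df2), "non-decreasing")
  expect_error(domain_annotation(c(14, 59), c(61, 62), c(63, 100)),
               "without gaps")
  expect_error(domain_annotation(c(14, 59), c(50, 51), c(62, 100)),
               "ordered")
})

test_that("sequon scanning finds N-X-S/T motifs including overlaps", {
  expect_equal(find_sequons("ANNTTA"), c(2L, 3L))
  expect_equal(find_sequons("ANPTA", exclude_proline = TRUE), integer(0))
  expect_equal(find_sequons("ANPTA"), 2L)
  expect_equal(find_sequons("ACDEF"), integer(0))
  expect_equal(find_sequons("NST"), 1L)
  expect_equal(find_sequons("nnss"), c(1L, 2L))  # case-insensitive
  expect_error(find_sequons("ANXTA"), "invalid")
  # FASTA route agrees with the string route
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">loop", "KNNTTGA", ">plain", "ACDEF"), f)
  hits <- find_sequons_fasta(f)
  expect_equal(hits$loop, c(2L, 3L))
  expect_equal(hits$plain, integer(0))
})

test_that("filament diameter is twice the maximal atom radius", {
  onaxis <- point_filament(c(0, 0, 0), mv_sym, 1)
  expect_equal(filament_diameter(onaxis), 0)
  wide <- point_filament(c(49, 0, 0), mv_sym, 1)
  expect_equal(filament_diameter(wide), 98)
  # invariant under the screw operators
  wide20 <- point_filament(c(49, 0, 0), mv_sym, 20)
  expect_equal(filament_diameter(wide20), 98, tolerance = 1e-9)
})
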