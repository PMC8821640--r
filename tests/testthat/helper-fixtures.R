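# shared fixtures, built once per test run

mv_sym <- helical_symmetry(5.57, 108)
mv_pattern <- register_pattern(3, 2, c(0, 0, 1))
mv_lab <- labeling_from_register(mv_pattern)
mv_fil <- make_fixture_filament("mvillosus", 30)

# a filament whose monomer is a single atom at the given position
point_filament <- function(xyz, sym, n, resno = 14L) {
  m <- monomer_model(data.frame(atom = "CA", element = "C", resid = "ALA",
                                resno = resno,
                                x = xyz[1], y = xyz[2], z = xyz[3]))
  build_filament(list(m), sym, labeling_from_register(register_pattern(1, 1, 0)),
                 n)
}

# rigidly translate every subunit of a filament model
translate_filament <- function(model, shift) {
  for (i in seq_along(model$subunits)) {
    a <- model$subunits[[i]]$atoms
    a$x <- a$x + shift[1]; a$y <- a$y + shift[2]; a$z <- a$z + shift[3]
    model$subunits[[i]]$atoms <- a
  }
  model
}

# brute-force minimal period of a label vector (independent oracle)
brute_period <- function(labels, max_p) {
  n <- length(labels)
  for (p in seq_len(max_p)) {
    ok <- TRUE
    for (i in seq_len(n - p)) {
      if (labels[i + p] != labels[i]) { ok <- FALSE; break }
    }
    if (ok) return(p)
  }
  NA_integer_
}

# random register pattern under a fixed-seed RNG stream
random_pattern <- function(max_s = 5, max_q = 3) {
  s <- sample.int(max_s, 1)
  q <- sample.int(max_q, 1)
  register_pattern(s, q, sample.int(q, s, replace = TRUE) - 1L)
}
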