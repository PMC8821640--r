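#' Species register pattern on an s-strand family
#'
#' Describes how q subunit species are phased across the s strands of an
#' s-start family when species alternate along each strand. Each strand j
#' carries a phase offset in [0, q); a strand whose offset differs from the
#' majority is "out of register". The two-species archaellum pattern is
#' s = 3, q = 2 with offsets (0, 0, 1): every third 3-start strand shifted
#' by one subunit.
#'
#' @param s number of strands (positive integer).
#' @param q number of species (positive integer).
#' @param offsets integer vector of length `s`, each in [0, q).
#' @return object of class `register_pattern` with fields `s`, `q`,
#'   `offsets`.
#' @examples
#' register_pattern(3, 2, c(0, 0, 1))
#' @export
register_pattern <- function(s, q, offsets) {
  if (!is.numeric(s) || length(s) != 1L || s < 1 || s != round(s))
    stop("register_pattern: s must be an integer >= 1", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || q < 1 || q != round(q))
    stop("register_pattern: q must be an integer >= 1", call. = FALSE)
  offsets <- as.integer(offsets)
  if (length(offsets) != s)
    stop("register_pattern: need one offset per strand", call. = FALSE)
  if (any(offsets < 0 | offsets >= q))
    stop("register_pattern: offsets must lie in [0, q)", call. = FALSE)
  structure(list(s = as.integer(s), q = as.integer(q), offsets = offsets),
            class = "register_pattern")
}

#' @export
print.register_pattern <- function(x, ...) {
  cat(sprintf("Register pattern: %d strand(s), %d species, offsets (%s)\n",
              x$s, x$q, paste(x$offsets, collapse = ",")))
  invisible(x)
}

#' Subunit labeling induced by a register pattern
#'
#' Realizes the species assignment species(i) = (floor(i/s) + offsets[i mod
#' s]) mod q for subunit index i >= 0: along each strand of the s-start
#' family the species cycle with period q, and the strand phases come from
#' the register offsets. The fundamental period (smallest p with
#' species(i + p) = species(i) for all i) is computed and cached.
#'
#' @param rp a [register_pattern()].
#' @return object of class `subunit_labeling` with fields `s`, `q`,
#'   `offsets` and `period`.
#' @examples
#' lab <- labeling_from_register(register_pattern(3, 2, c(0, 0, 1)))
#' species_at(lab, 0:5)  # 0 0 1 1 1 0
#' lab$period            # 6
#' @export
labeling_from_register <- function(rp) {
  stopifnot(inherits(rp, "register_pattern"))
  lab <- structure(list(s = rp$s, q = rp$q, offsets = rp$offsets,
                        period = NA_integer_),
                   class = "subunit_labeling")
  lab$period <- minimal_label_period(lab, max_period = rp$s * rp$q)
  lab
}

#' @export
print.subunit_labeling <- function(x, ...) {
  cat(sprintf("Subunit labeling: %d strand(s), %d species, offsets (%s), period %d\n",
              x$s, x$q, paste(x$offsets, collapse = ","), x$period))
  cat("first labels:", paste(species_at(x, 0:(min(2L * x$period, 24L) - 1L)),
                             collapse = " "), "\n")
  invisible(x)
}

#' Species label of subunits
#'
#' @param lab a [subunit_labeling()].
#' @param i vector of subunit indices (>= 0).
#' @return integer species labels in [0, q).
#' @export
species_at <- function(lab, i) {
  stopifnot(inherits(lab, "subunit_labeling"))
  if (any(i < 0 | i != round(i)))
    stop("species_at: indices must be non-negative integers", call. = FALSE)
  i <- as.integer(i)
  (i %/% lab$s + lab$offsets[(i %% lab$s) + 1L]) %% lab$q
}

#' Minimal period of a species labeling
#'
#' Smallest p >= 1 such that species(i + p) = species(i) for all i. For a
#' labeling induced by a register pattern the formula is exactly periodic
#' with period dividing s*q, so verification over a window of 2*s*q labels
#' is exhaustive; for a plain label vector the window is the vector itself.
#' The archaellum register (3 strands, 2 species, offsets (0,0,1)) has
#' minimal period 6; perfect in-register alternation has period 2.
#'
#' @param lab a [subunit_labeling()] or an integer/character vector of
#'   observed labels (indices 0, 1, ... in vector order).
#' @param max_period largest period to consider.
#' @param ... unused.
#' @return the minimal period, as integer.
#' @examples
#' minimal_label_period(labeling_from_register(register_pattern(3, 2, c(0, 0, 1))))
#' minimal_label_period(rep_len(c(0L, 1L), 48))  # 2
#' @export
minimal_label_period <- function(lab, max_period = NULL, ...) {
  UseMethod("minimal_label_period")
}

#' @export
minimal_label_period.subunit_labeling <- function(lab, max_period = NULL, ...) {
  if (is.null(max_period)) max_period <- lab$s * lab$q
  if (max_period < lab$s * lab$q)
    stop("minimal_label_period: max_period must be >= s*q", call. = FALSE)
  window <- 2L * lab$s * lab$q + as.integer(max_period)
  x <- species_at(lab, 0:(window - 1L))
  p <- period_of_vector(x, max_period)
  if (is.na(p))
    stop("minimal_label_period: no period <= max_period found", call. = FALSE)
  p
}

#' @export
minimal_label_period.default <- function(lab, max_period = NULL, ...) {
  x <- lab
  if (length(x) < 2L)
    stop("minimal_label_period: need at least 2 labels", call. = FALSE)
  if (is.null(max_period)) max_period <- length(x) - 1L
  p <- period_of_vector(x, max_period)
  if (is.na(p))
    stop("minimal_label_period: no period <= max_period found within window",
         call. = FALSE)
  p
}

# smallest p in 1..max_period with x[i+p] == x[i] over the whole vector
period_of_vector <- function(x, max_period) {
  n <- length(x)
  for (p in seq_len(min(max_period, n - 1L))) {
    if (all(x[seq_len(n - p) + p] == x[seq_len(n - p)])) return(p)
  }
  NA_integer_
}

#' Helical symmetry reduced by a labeling's period
#'
#' Convenience composition: the lattice symmetry that maps every subunit onto
#' one of the same species is the 1-start symmetry reduced by the labeling's
#' minimal period. For (5.57 A, 108 deg) and the archaellum register this is
#' (33.42 A, -72 deg); for in-register alternation it is (11.14 A, raw
#' 216 deg).
#'
#' @param sym a [helical_symmetry()].
#' @param lab a [subunit_labeling()].
#' @return a [helical_symmetry()].
#' @export
reduced_symmetry_for_labeling <- function(sym, lab) {
  stopifnot(inherits(lab, "subunit_labeling"))
  reduce_symmetry(sym, minimal_label_period(lab))
}

#' Strands out of register
#'
#' Identifies the strand(s) whose phase offset deviates from the modal
#' (strict-majority) offset. Strand indices are 0-based to match subunit
#' indexing.
#'
#' @param rp a [register_pattern()] with q >= 2.
#' @return integer vector of deviating strand indices (possibly empty).
#' @examples
#' out_of_register_strands(register_pattern(3, 2, c(0, 0, 1)))  # 2
#' @export
out_of_register_strands <- function(rp) {
  stopifnot(inherits(rp, "register_pattern"))
  if (rp$q < 2)
    stop("out_of_register_strands: needs q >= 2", call. = FALSE)
  tab <- table(rp$offsets)
  top <- max(tab)
  if (sum(tab == top) != 1L)
    stop("out_of_register_strands: no strict modal offset (ambiguous register)",
         call. = FALSE)
  modal <- as.integer(names(tab)[which.max(tab)])
  which(rp$offsets != modal) - 1L
}

#' Ordered species pairs along a neighbour direction
#'
#' Enumerates the distinct ordered pairs (species(i), species(i + k)) over a
#' full labeling period: the contact types a subunit makes with its k-offset
#' neighbour. In the archaellum register, k = 3 yields only heterotypic
#' pairs while k = 7 yields all four ordered pairs.
#'
#' @param lab a [subunit_labeling()].
#' @param k non-zero integer neighbour offset.
#' @return two-column integer matrix of distinct ordered pairs, one row per
#'   pair, ordered lexicographically.
#' @examples
#' lab <- labeling_from_register(register_pattern(3, 2, c(0, 0, 1)))
#' species_pairs_along(lab, 3)  # (0,1) and (1,0) only
#' species_pairs_along(lab, 7)  # all four ordered pairs
#' @export
species_pairs_along <- function(lab, k) {
  stopifnot(inherits(lab, "subunit_labeling"))
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k == 0)
    stop("species_pairs_along: k must be a non-zero integer", call. = FALSE)
  k <- as.integer(k)
  p <- lab$period
  i <- 0:(p - 1L)
  # shift indices by enough periods to keep them non-negative for k < 0
  base <- max(0L, as.integer(ceiling(-k / p)) * p)
  a <- species_at(lab, i + base)
  b <- species_at(lab, i + base + k)
  m <- unique(cbind(from = a, to = b))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Index gaps along a single-species pseudo-strand
#'
#' Traces all subunits of one species in index order and returns the cyclic
#' sequence of index gaps over one labeling period, canonicalized as the
#' lexicographically minimal rotation. A broken ("stepped") pseudo-strand
#' shows a non-constant gap motif: the archaellum register gives (1, 1, 4)
#' for either species, i.e. runs of three consecutive subunits separated by
#' a step of four.
#'
#' @param lab a [subunit_labeling()].
#' @param species species label to trace.
#' @return integer vector of cyclic gaps (sums to the period times
#'   species multiplicity share).
#' @examples
#' lab <- labeling_from_register(register_pattern(3, 2, c(0, 0, 1)))
#' pseudo_strand_steps(lab, 0)  # 1 1 4
#' @export
pseudo_strand_steps <- function(lab, species) {
  stopifnot(inherits(lab, "subunit_labeling"))
  p <- lab$period
  idx <- which(species_at(lab, 0:(p - 1L)) == species) - 1L
  if (length(idx) == 0L)
    stop("pseudo_strand_steps: species ", species, " does not occur",
         call. = FALSE)
  gaps <- if (length(idx) == 1L) p else diff(c(idx, idx[1L] + p))
  canonical_rotation(as.integer(gaps))
}

# lexicographically minimal rotation of an integer vector
canonical_rotation <- function(x) {
  n <- length(x)
  if (n <= 1L) return(x)
  rots <- vapply(seq_len(n),
                 function(r) paste(x[((seq_len(n) + r - 2L) %% n) + 1L],
                                   collapse = ","),
                 "")
  best <- order(rots)[1L]
  x[((seq_len(n) + best - 2L) %% n) + 1L]
}

#' Infer a register pattern from observed labels
#'
#' Inverse of [labeling_from_register()]: given a sequence of species labels
#' for subunits 0, 1, ..., recovers the per-strand offsets. The result is
#' canonicalized by renaming species in order of first appearance (so
#' observed[1] becomes species 0, which forces strand 0's offset to 0); the
#' true pattern is only identifiable up to this global relabeling/phase.
#'
#' @param observed vector of species labels (any atomic type).
#' @param s number of strands.
#' @param q number of species.
#' @return a [register_pattern()]; attribute `species_map` records the
#'   original label of each canonical species.
#' @examples
#' lab <- labeling_from_register(register_pattern(3, 2, c(0, 0, 1)))
#' infer_register(species_at(lab, 0:23), 3, 2)
#' @export
infer_register <- function(observed, s, q) {
  if (!is.numeric(s) || s < 1 || s != round(s) ||
      !is.numeric(q) || q < 1 || q != round(q))
    stop("infer_register: s and q must be positive integers", call. = FALSE)
  s <- as.integer(s); q <- as.integer(q)
  n <- length(observed)
  if (n < 2L * s * q)
    stop("infer_register: need at least 2*s*q = ", 2L * s * q, " labels",
         call. = FALSE)
  lev <- unique(observed)
  if (length(lev) > q)
    stop("infer_register: observed ", length(lev), " distinct labels but q = ",
         q, call. = FALSE)
  if (length(lev) < q)
    warning("infer_register: only ", length(lev), " of ", q,
            " species observed (degenerate labeling)", call. = FALSE)
  # species labels are symbolic: the integer value of each species (its
  # position in the alternation cycle) must be inferred along with the
  # offsets. Fix value 0 on the first-observed species (this pins the global
  # phase and forces offset[0] = 0) and try every assignment of the
  # remaining values; keep the one that reproduces the sequence.
  i <- 0:(n - 1L)
  first <- match(observed, lev) - 1L  # 0-based first-appearance code
  perms <- value_assignments(length(lev), q)
  best_prefix <- -1L
  best_fail <- 0L
  for (vmap in perms) {
    v <- vmap[first + 1L]  # integer species value per subunit
    offsets <- v[seq_len(s)] %% q  # row 0 of each strand: off_j = v(obs_j)
    predicted <- (i %/% s + offsets[(i %% s) + 1L]) %% q
    bad <- which(predicted != v)
    if (length(bad) == 0L) {
      rp <- register_pattern(s, q, offsets)
      smap <- rep(NA, q)
      smap[vmap + 1L] <- lev[seq_along(vmap)]
      attr(rp, "species_map") <- smap
      return(rp)
    }
    if (bad[1L] > best_prefix) {
      best_prefix <- bad[1L]
      best_fail <- bad[1L] - 1L
    }
  }
  stop("infer_register: inconsistent labeling at subunit index ", best_fail,
       call. = FALSE)
}

# all assignments of integer values in [0, q) to n_lev observed species,
# with the first-observed species fixed at value 0
value_assignments <- function(n_lev, q) {
  slots <- setdiff(seq_len(q) - 1L, 0L)
  if (n_lev == 1L) return(list(0L))
  perm_rec <- function(chosen, remaining, depth) {
    if (depth == 0L) return(list(chosen))
    out <- list()
    for (r in seq_along(remaining))
      out <- c(out, perm_rec(c(chosen, remaining[r]), remaining[-r],
                             depth - 1L))
    out
  }
  perm_rec(0L, slots, n_lev - 1L)
}

#' Write/read register patterns and label sequences
#'
#' Register patterns are stored as plain key-value config (`strands`,
#' `species`, `offsets` as comma-separated integers); label sequences as
#' one-column text (one label per line, optional `species` header).
#'
#' @param rp a [register_pattern()].
#' @param path file path.
#' @return the reader returns the parsed object; writers return `path`
#'   invisibly.
#' @export
write_register <- function(rp, path) {
  stopifnot(inherits(rp, "register_pattern"))
  writeLines(c(sprintf("strands = %d", rp$s),
               sprintf("species = %d", rp$q),
               sprintf("offsets = %s", paste(rp$offsets, collapse = ","))),
             path)
  invisible(path)
}

#' @rdname write_register
#' @export
read_register <- function(path) {
  kv <- read_keyvals(path)
  need <- c("strands", "species", "offsets")
  if (!all(need %in% names(kv)))
    stop("read_register: missing keys: ",
         paste(setdiff(need, names(kv)), collapse = ", "), call. = FALSE)
  register_pattern(as.integer(kv[["strands"]]), as.integer(kv[["species"]]),
                   as.integer(strsplit(kv[["offsets"]], ",")[[1]]))
}

#' @param labels vector of species labels.
#' @rdname write_register
#' @export
write_labels <- function(labels, path) {
  writeLines(c("species", as.character(labels)), path)
  invisible(path)
}

#' @rdname write_register
#' @export
read_labels <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  if (length(ln) && identical(tolower(ln[1]), "species")) ln <- ln[-1]
  if (all(grepl("^-?[0-9]+$", ln))) as.integer(ln) else ln
}
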