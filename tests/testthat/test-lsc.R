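# LSC extraction, per-clade profiles, character-state assignment.

mk_calls <- function(columns, classes) {
  tibble::tibble(column = columns, clade_a = "A", clade_b = "B",
                 class = factor(classes,
                                levels = c("type0", "typeI", "typeII",
                                           "none")),
                 posterior = 0.5, slow_clade = NA_character_,
                 fast_clade = NA_character_)
}

mk_graph <- function(columns, xyz, threshold = 4) {
  sm <- tibble::tibble(column = columns, chain = "A",
                       resno = seq_along(columns), insert = "",
                       aa_aln = "A", aa_struct = "A",
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  class(sm) <- c("structure_map", class(sm))
  build_contact_graph(sm, columns, threshold = threshold)
}

test_that("LSCs are typed connected components with a type I/II member", {
  # columns 10, 11 in contact; 40 isolated; 50-51 in contact but type0 only
  g <- mk_graph(c(10L, 11L, 40L, 50L, 51L),
                cbind(c(0, 3, 100, 200, 203), 0, 0))
  calls <- mk_calls(c(10L, 11L, 40L, 50L, 51L),
                    c("typeI", "type0", "typeII", "type0", "type0"))
  lscs <- find_lscs(calls, g)
  expect_equal(unique(lscs$lsc), 1L)
  expect_setequal(lscs$column, c(10L, 11L))
  # singleton type II and the all-type0 component are excluded
  expect_false(40L %in% lscs$column)
  expect_false(any(c(50L, 51L) %in% lscs$column))
})

test_that("components match a brute-force floodfill on random graphs", {
  set.seed(14)
  for (rep in 1:50) {
    n <- sample(6:14, 1)
    cols <- sort(sample(1:60, n))
    xyz <- matrix(runif(3 * n, 0, 25), ncol = 3)
    g <- mk_graph(cols, xyz, threshold = 10)
    classes <- sample(c("typeI", "typeII", "type0"), n, replace = TRUE)
    calls <- mk_calls(cols, classes)
    lscs <- find_lscs(calls, g)

    e <- contact_edges(g)
    comps <- if (nrow(e)) {
      floodfill_components(cols, as.matrix(e))
    } else {
      as.list(cols)
    }
    keep <- Filter(function(cc) {
      length(cc) >= 2 &&
        any(classes[match(cc, cols)] %in% c("typeI", "typeII"))
    }, comps)
    got <- split(lscs$column, lscs$lsc)
    expect_equal(length(got), length(keep), info = paste("rep", rep))
    if (length(keep)) {
      keep <- keep[order(vapply(keep, min, numeric(1)))]
      for (i in seq_along(keep)) {
        expect_setequal(got[[i]], keep[[i]])
      }
    }
  }
})

test_that("profiles tally consensus, frequency and gap fraction", {
  aln <- aln_of(a1 = "KA", a2 = "KA", a3 = "KA", a4 = "KC",
                b1 = "--", b2 = "--", b3 = "--", b4 = "--")
  part <- tibble::tibble(sequence_id = c(paste0("a", 1:4), paste0("b", 1:4)),
                         clade = rep(c("A", "B"), each = 4))
  lscs <- tibble::tibble(lsc = 1L, column = 1:2,
                         class = c("typeI", "type0"),
                         resno = 1:2, chain = "A", aa_struct = c("K", "A"))
  pf <- lsc_state_profiles(lscs, aln, part)
  a1 <- pf[pf$clade == "A" & pf$column == 1, ]
  expect_equal(a1$consensus, "K")
  expect_equal(a1$frequency, 1)
  a2 <- pf[pf$clade == "A" & pf$column == 2, ]
  expect_equal(a2$consensus, "A")
  expect_equal(a2$frequency, 0.75)
  b1 <- pf[pf$clade == "B" & pf$column == 1, ]
  expect_true(is.na(b1$consensus))
  expect_equal(b1$gap_fraction, 1)
})

test_that("state assignment groups clades by radical class and conservation", {
  # K vs R conserved: same positive group -> one state;
  # C conserved vs variable -> two states; all-gap clade -> missing
  profiles <- dplyr::bind_rows(
    tibble::tibble(lsc = 1L, clade = "w", column = 1:2,
                   consensus = c("K", "C"), frequency = c(1, 1),
                   gap_fraction = 0),
    tibble::tibble(lsc = 1L, clade = "x", column = 1:2,
                   consensus = c("R", "C"), frequency = c(0.9, 0.95),
                   gap_fraction = 0),
    tibble::tibble(lsc = 1L, clade = "y", column = 1:2,
                   consensus = c("K", "S"), frequency = c(1, 0.4),
                   gap_fraction = 0.1),
    tibble::tibble(lsc = 1L, clade = "z", column = 1:2,
                   consensus = c(NA, NA), frequency = c(0, 0),
                   gap_fraction = c(1, 1))
  )
  st <- assign_states(profiles, 1L)
  s <- stats::setNames(st$state, st$clade)
  expect_equal(s[["w"]], s[["x"]])     # K ~ R, both conserved
  expect_false(s[["w"]] == s[["y"]])   # zinc-finger-like: conserved vs variable
  expect_true(is.na(s[["z"]]))

  # manual override wins verbatim
  st2 <- assign_states(profiles, 1L,
                       override = c(w = 1, x = 2, y = 2, z = 1))
  expect_equal(st2$state, c(1L, 2L, 2L, 1L))
})

test_that("character matrix assembles one column per LSC and writes TSV", {
  profiles <- dplyr::bind_rows(
    tibble::tibble(lsc = 1L, clade = c("u", "v"), column = 1L,
                   consensus = c("K", "D"), frequency = 1, gap_fraction = 0),
    tibble::tibble(lsc = 2L, clade = c("u", "v"), column = 2L,
                   consensus = c("A", "A"), frequency = 1, gap_fraction = 0)
  )
  cm <- character_matrix(profiles)
  expect_equal(names(cm), c("clade", "lsc1", "lsc2"))
  expect_equal(cm$lsc1, c(1L, 2L))   # K vs D: different radical groups
  expect_equal(cm$lsc2, c(1L, 1L))

  f <- withr::local_tempfile(fileext = ".tsv")
  cm$lsc2[2] <- NA
  write_character_matrix(cm, f)
  txt <- read.delim(f, colClasses = "character")
  expect_equal(txt$lsc2, c("1", "?"))
})
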