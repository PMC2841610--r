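test_that("lipid exposure labelling uses a strict threshold over TM residues", {
  topo <- topology(5, 6)
  fr <- stats::setNames(c(0.51, 0.50, 0.9, 0.1), c(4, 5, 6, 7))
  # residue 5 at exactly 0.50 is NOT exposed; 6 at 0.9 is
  lab <- label_lipid_exposed(fr, topo)
  expect_equal(unname(lab), c(FALSE, TRUE))
  expect_equal(names(lab), c("5", "6"))

  fr2 <- stats::setNames(c(0.51), 5)
  expect_error(label_lipid_exposed(fr2, topo), "missing lipid fraction.*6")

  topo2 <- topology(c(5, 8), c(6, 9))
  fr3 <- stats::setNames(c(0.9, 0.1, 0.51, 0.49), c(5, 6, 8, 9))
  expect_equal(unname(label_lipid_exposed(fr3, topo2)),
               c(TRUE, FALSE, TRUE, FALSE))
})

test_that("definition 1 applies the C-beta cutoff with C-alpha for glycine", {
  topo <- topology(c(1, 3), c(1, 3))  # residues 1 and 3 are helices; 2 is loop
  seqs <- "AGA"
  mk <- function(d_cb) coords_df(
    residue = c(1L, 1L, 3L, 3L),
    atom = c("CA", "CB", "CA", "CB"),
    element = "C",
    x = c(0, 0, 0, d_cb), y = 0, z = 0)
  # CB-CB at 7.9 -> contact; at 8.1 -> none; at exactly 8.0 -> contact
  expect_equal(nrow(residue_contacts(mk(7.9), topo, contact_definition(1), seqs)), 1L)
  expect_equal(nrow(residue_contacts(mk(8.1), topo, contact_definition(1), seqs)), 0L)
  expect_equal(nrow(residue_contacts(mk(8.0), topo, contact_definition(1), seqs)), 1L)

  # glycine at residue 1: its CA (not CB) is the representative atom
  gly <- coords_df(residue = c(1L, 3L, 3L),
                   atom = c("CA", "CA", "CB"), element = "C",
                   x = c(0, 10, 7.5), y = 0, z = 0)
  got <- residue_contacts(gly, topo, contact_definition(1), "GAA")
  expect_equal(nrow(got), 1L)  # CA(gly)-CB distance 7.5 <= 8
})

test_that("missing C-beta on a non-glycine residue falls back to C-alpha", {
  topo <- topology(c(1, 3), c(1, 3))
  cc <- coords_df(residue = c(1L, 3L, 3L), atom = c("CA", "CA", "CB"),
                  element = "C", x = c(0, 10, 7), y = 0, z = 0)
  expect_warning(got <- residue_contacts(cc, topo, contact_definition(1), "AAA"),
                 "falling back to CA")
  expect_equal(nrow(got), 1L)
})

test_that("definitions 2 and 3 are strict and exclude hydrogens", {
  topo <- topology(c(1, 3), c(1, 3))
  # def 2: C+C vdW = 3.4, margin 0.6 -> threshold 4.0 (strict)
  mk <- function(d) coords_df(residue = c(1L, 3L), atom = c("CB", "CB"),
                              element = "C", x = c(0, d), y = 0, z = 0)
  expect_equal(nrow(residue_contacts(mk(3.99), topo, contact_definition(2), "AAA")), 1L)
  expect_equal(nrow(residue_contacts(mk(4.00), topo, contact_definition(2), "AAA")), 0L)
  # def 3: heavy atoms < 5.5 strict
  expect_equal(nrow(residue_contacts(mk(5.49), topo, contact_definition(3), "AAA")), 1L)
  expect_equal(nrow(residue_contacts(mk(5.50), topo, contact_definition(3), "AAA")), 0L)
  # hydrogens never create contacts under defs 2-3
  hh <- coords_df(residue = c(1L, 1L, 3L, 3L),
                  atom = c("CB", "HB", "CB", "HB"),
                  element = c("C", "H", "C", "H"),
                  x = c(0, 2.5, 6, 3.5), y = 0, z = 0)
  expect_equal(nrow(residue_contacts(hh, topo, contact_definition(3), "AAA")), 0L)
})

test_that("residue contacts equal the brute-force oracle on random bundles", {
  for (seed in 1:6) {
    n <- 2L + (seed %% 3L)
    b <- make_bundle(bundle_spec(n, helix_len = 10L, seed = seed))
    for (kind in 1:3) {
      def <- contact_definition(kind)
      fast <- residue_contacts(b$coords, b$topo, def, b$protein)
      slow <- brute_force_contacts(b$coords, b$topo, def, b$protein)
      expect_equal(unclass(fast), unclass(slow),
                   info = sprintf("seed %d definition %d", seed, kind))
    }
  }
})

test_that("contacts are invariant under rigid rotation and translation", {
  b <- make_bundle(bundle_spec(3, helix_len = 8L, seed = 11))
  def <- contact_definition(2)
  before <- residue_contacts(b$coords, b$topo, def, b$protein)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(b$coords[, c("x", "y", "z")]) %*% R
  moved <- b$coords
  moved$x <- xyz[, 1] + 13.7; moved$y <- xyz[, 2] - 4.2; moved$z <- xyz[, 3] + 99
  after <- residue_contacts(moved, b$topo, def, b$protein)
  expect_equal(unclass(before), unclass(after))
})

test_that("heavy-atom contacts under 5.5 A always satisfy definition 2", {
  # with all vdW radii >= 1.4 and margin 0.6, d < 5.5 implies d < r1+r2+0.6
  # only when r1+r2 >= 4.9; check on C/N/O/S combinations from real bundles
  b <- make_bundle(bundle_spec(3, helix_len = 8L, seed = 21))
  def3 <- residue_contacts(b$coords, b$topo, contact_definition(3), b$protein)
  def2 <- residue_contacts(b$coords, b$topo,
                           contact_definition(2, vdw_radii = c(C = 2.5, N = 2.5,
                                                               O = 2.5, S = 2.5)),
                           b$protein)
  key3 <- paste(def3$i, def3$j); key2 <- paste(def2$i, def2$j)
  expect_true(all(key3 %in% key2))
})

test_that("helix interactions require one contacting residue pair", {
  topo <- topology(c(1, 40, 80), c(20, 60, 100))
  cs <- contact_set(10, 50, topo)
  g <- observed_helix_interactions(cs, topo)
  expect_equal(g$edges, matrix(c(1L, 2L), 1))

  g0 <- observed_helix_interactions(empty_contact_set(topo), topo)
  expect_equal(g0$n, 3L)
  expect_equal(nrow(g0$edges), 0L)

  # many contacts between one helix pair still give a single edge
  cs2 <- contact_set(rep(41:60, each = 2), rep(81:100, 2)[1:40], topo)
  g2 <- observed_helix_interactions(cs2, topo)
  expect_equal(g2$edges, matrix(c(2L, 3L), 1))
})
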