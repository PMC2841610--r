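test_that("profile windows have length w*20 and zero-pad past the termini", {
  set.seed(42)
  prof <- matrix(rnorm(10 * 20), 10, 20)
  w <- profile_window(prof, 5, 7)
  expect_length(w, 140)
  expect_equal(w[61:80], prof[5, ])  # centre block

  w1 <- profile_window(prof, 1, 7)
  expect_equal(w1[1:60], rep(0, 60))        # 3 left blocks empty
  expect_equal(w1[61:80], prof[1, ])
  wL <- profile_window(prof, 10, 7)
  expect_equal(wL[81:140], rep(0, 60))      # 3 right blocks empty
  expect_error(profile_window(prof, 11, 7), "outside")
})

test_that("Z-score normalization is fitted on training data only", {
  tr <- cbind(c(1, 2, 3), c(5, 5, 5))
  te <- cbind(c(2, 4), c(7, 5))
  out <- fit_apply_zscore(tr, test = te)
  # population sd: [1,2,3] -> +-1.2247
  expect_equal(out$train[, 1], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(out$train[, 2], c(0, 0, 0))          # constant column
  expect_equal(out$test[1, 1], 0)                   # equals training mean
  expect_equal(out$test[2, 1], 2 * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(out$test[, 2], c(0, 0))              # constant col stays 0
  expect_error(fit_apply_zscore(tr[0, , drop = FALSE]), "empty")

  # property: every non-constant normalized training column has mean ~0, sd ~1
  set.seed(7)
  m <- matrix(rnorm(200), 20, 10)
  z <- fit_apply_zscore(m)$train
  expect_true(all(abs(colMeans(z)) < 1e-9))
  popsd <- sqrt(colMeans(sweep(z, 2, colMeans(z))^2))
  expect_true(all(abs(popsd - 1) < 1e-6))
})

test_that("separation encoding is one-hot with inclusive-left boundaries", {
  expect_equal(separation_encoding(30), c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(separation_encoding(50), c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(separation_encoding(51), c(0, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(separation_encoding(75), c(0, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(separation_encoding(200), c(0, 0, 0, 0, 0, 0, 1, 0))
  expect_equal(separation_encoding(201), c(0, 0, 0, 0, 0, 0, 0, 1))
  expect_error(separation_encoding(0), ">= 1")
  # always exactly one bit set
  for (d in c(1, 49, 76, 125, 126, 199, 1000)) {
    expect_equal(sum(separation_encoding(d)), 1)
  }
})

test_that("relative positions divide by helix length and flip on odd parity", {
  topo <- topology(c(1, 30, 60), c(20, 49, 79))
  h1 <- topo[1, ]; h2 <- topo[2, ]; h3 <- topo[3, ]
  # first residue of a 20-residue helix -> 1/20
  z <- relative_position_pair(1, h1, 30, h2)
  expect_equal(z[1], 0.05)
  # helices 1,2 adjacent -> flip applied to second residue: 1 - 0/20 = 1
  expect_equal(z[2], 1)
  z2 <- relative_position_pair(1, h1, 49, h2)
  expect_equal(z2[2], 1 - 19 / 20)
  # helices 1,3: even separation -> no flip
  z3 <- relative_position_pair(1, h1, 60, h3)
  expect_equal(z3[2], 1 / 20)
  # z always in (0, 1]
  for (p in 30:49) {
    zz <- relative_position_pair(5, h1, p, h2)
    expect_true(all(zz > 0 & zz <= 1))
  }
  expect_error(relative_position_pair(25, h1, 30, h2), "outside")
})

test_that("lipid feature matrices have one 140-long row per TM residue", {
  b <- make_bundle(bundle_spec(2, helix_len = 15L, seed = 5))
  prof <- make_profiles(b, signal_strength = 4, seed = 5)$profile
  feats <- build_lipid_features(b$protein, prof, b$topo)
  expect_equal(dim(feats), c(30L, 140L))
  first_tm <- tm_residues(b$topo)[1]
  expect_equal(unname(feats[1, ]), profile_window(prof, first_tm, 7))
  expect_error(build_lipid_features(b$protein, prof[-1, ], b$topo), "length")
})

test_that("pair features assemble windows, lipid scores, separation and z", {
  b <- make_bundle(bundle_spec(2, helix_len = 5L, seed = 6))
  prof <- make_profiles(b, signal_strength = 4, seed = 6)$profile
  tm <- tm_residues(b$topo)
  scores <- stats::setNames(rnorm(length(tm)), tm)
  pf <- build_pair_features(b$protein, prof, scores, b$topo)
  # 2 helices x 5 residues -> 25 pairs; 280 profile + 2 lipid + 8 sep + 2 z
  expect_equal(dim(pf$features), c(25L, 292L))
  expect_equal(nrow(pf$pairs), 25L)
  expect_true(all(pf$pairs$i < pf$pairs$j))
  expect_true(all(pf$pairs$helix_i != pf$pairs$helix_j))
  # spot-check one row against the component functions
  k <- 7L
  i <- pf$pairs$i[k]; j <- pf$pairs$j[k]
  manual <- c(profile_window(prof, i, 7), profile_window(prof, j, 7),
              scores[[as.character(i)]], scores[[as.character(j)]],
              separation_encoding(abs(i - j)),
              relative_position_pair(i, b$topo[pf$pairs$helix_i[k], ],
                                     j, b$topo[pf$pairs$helix_j[k], ]))
  expect_equal(unname(pf$features[k, ]), unname(manual))
  expect_error(build_pair_features(b$protein, prof, scores[-1], b$topo),
               "missing lipid score")
})
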