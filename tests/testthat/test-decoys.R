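test_that("predicted interactions follow the any-positive-pair rule", {
  topo <- topology(c(1, 30, 60, 90), c(20, 49, 79, 109))
  pairs <- data.frame(i = c(5, 10, 65), j = c(35, 95, 95),
                      helix_i = c(1, 1, 3), helix_j = c(2, 4, 4))
  g <- predicted_interactions(pairs, c(-1, -2, -3), topo)
  expect_equal(nrow(g$edges), 0L)
  g2 <- predicted_interactions(pairs, c(-1, -2, 0.5), topo)
  expect_equal(g2$edges, matrix(c(3L, 4L), 1))
  # consistency with observed_helix_interactions under +-1 scoring
  b <- make_bundle(bundle_spec(3, seed = 8))
  tmp <- tm_residues(b$topo); hx <- helix_of(b$topo, tmp)
  allpairs <- expand.grid(a = seq_along(tmp), b = seq_along(tmp))
  allpairs <- allpairs[hx[allpairs$a] != hx[allpairs$b] & allpairs$a < allpairs$b, ]
  pp <- data.frame(i = tmp[allpairs$a], j = tmp[allpairs$b],
                   helix_i = hx[allpairs$a], helix_j = hx[allpairs$b])
  sc <- ifelse(paste(pp$i, pp$j) %in% paste(b$contacts$i, b$contacts$j), 1, -1)
  expect_equal(predicted_interactions(pp, sc, b$topo)$edges,
               observed_helix_interactions(b$contacts, b$topo)$edges)
})

test_that("arrangement scores count matching helix pairs", {
  g5 <- interaction_graph(5, rbind(c(1, 2), c(2, 3), c(4, 5)))
  expect_equal(arrangement_score(g5, g5), choose(5, 2))

  g4 <- interaction_graph(4, rbind(c(1, 2), c(3, 4)))
  expect_equal(arrangement_score(complement_graph(g4), g4), 0L)

  # n=3, predicted {1-2}, candidate {1-2, 2-3}: pairs 1-2 and 1-3 match
  pred <- interaction_graph(3, rbind(c(1, 2)))
  cand <- interaction_graph(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(arrangement_score(cand, pred), 2L)

  expect_error(arrangement_score(g4, g5), "mismatch")
})

test_that("score of a graph plus score of its complement sums to C(n,2)", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    pairs <- t(utils::combn(n, 2))
    g <- interaction_graph(n, pairs[runif(nrow(pairs)) < 0.5, , drop = FALSE])
    h <- interaction_graph(n, pairs[runif(nrow(pairs)) < 0.5, , drop = FALSE])
    expect_equal(arrangement_score(g, h) +
                   arrangement_score(complement_graph(g), h),
                 choose(n, 2))
  }
})

test_that("ranking puts the native first when decoys each mismatch a pair", {
  native <- interaction_graph(5, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  decoys <- make_decoys(native, 10, seed = 2)
  cands <- c(list(arrangement_candidate("native", native, "native")), decoys)
  rk <- rank_candidates(cands, native)
  expect_true(rk$native_first)
  expect_equal(rk$ranking$id[1], "native")
  expect_equal(rk$ranking$score[1], choose(5, 2))
  expect_true(all(diff(rk$ranking$score) <= 0))
  # ranking is a permutation of candidates
  expect_setequal(rk$ranking$id, vapply(cands, function(x) x$id, ""))

  # a decoy identical to the native graph ties -> still counts as first
  tie <- arrangement_candidate("twin", native, "decoy")
  rk2 <- rank_candidates(list(arrangement_candidate("native", native, "native"),
                              tie), native)
  expect_true(rk2$native_first)

  expect_error(rank_candidates(decoys, native), "native")
})

test_that("decoy generation produces distinct non-native graphs", {
  native <- interaction_graph(7, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                                       c(5, 6), c(6, 7), c(1, 7)))
  decoys <- make_decoys(native, 24, seed = 5)
  expect_length(decoys, 24)
  keys <- vapply(decoys, function(d)
    paste(apply(d$graph$edges, 1, paste, collapse = "-"), collapse = ","), "")
  expect_equal(anyDuplicated(keys), 0L)
  nk <- paste(apply(native$edges, 1, paste, collapse = "-"), collapse = ",")
  expect_false(nk %in% keys)
  # every decoy mismatches >= 1 pair, so the native strictly outranks it
  scores <- vapply(decoys, function(d)
    arrangement_score(d$graph, native), numeric(1))
  expect_true(all(scores < choose(7, 2)))

  # pigeonhole: n=2 has exactly one possible decoy
  tiny <- interaction_graph(2, rbind(c(1, 2)))
  expect_error(make_decoys(tiny, 2, seed = 1), "distinct")
  expect_length(make_decoys(tiny, 1, seed = 1), 1)
})
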