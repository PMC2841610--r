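test_that("circular initialization places vertices on a regular polygon", {
  p4 <- circular_init(4, 1)
  expect_equal(unname(p4),
               rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)),
               tolerance = 1e-12)
  p1 <- circular_init(1, 2.5)
  expect_equal(unname(p1), cbind(2.5, 0))
  expect_error(circular_init(0), "at least one")
  # all adjacent distances equal
  p7 <- circular_init(7, 3)
  d <- sqrt(rowSums((p7 - p7[c(2:7, 1), ])^2))
  expect_true(max(d) - min(d) < 1e-9)
})

test_that("two connected vertices relax to separation L0", {
  g <- interaction_graph(2, rbind(c(1, 2)))
  fit <- kamada_kawai(g)
  expect_true(fit$converged)
  d <- sqrt(sum((fit$positions[1, ] - fit$positions[2, ])^2))
  expect_equal(d, layout_params()$L0, tolerance = 1e-6)
})

test_that("a triangle relaxes to an equilateral within 1 percent", {
  g <- interaction_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  fit <- kamada_kawai(g)
  p <- fit$positions
  sides <- c(sqrt(sum((p[1, ] - p[2, ])^2)),
             sqrt(sum((p[2, ] - p[3, ])^2)),
             sqrt(sum((p[1, ] - p[3, ])^2)))
  expect_true(all(abs(sides - layout_params()$L0) / layout_params()$L0 < 0.01))
})

test_that("spring energy never increases from the circular start", {
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(4:9, 1)
    # random connected graph: spanning path + random extra edges
    edges <- cbind(1:(n - 1), 2:n)
    extra <- t(utils::combn(n, 2))
    extra <- extra[runif(nrow(extra)) < 0.3, , drop = FALSE]
    g <- interaction_graph(n, rbind(edges, extra))
    fit <- kamada_kawai(g)
    expect_lte(fit$energy, fit$initial_energy)
  }
})

test_that("disconnected graphs are rejected with the unreachable helices", {
  g <- interaction_graph(4, rbind(c(1, 2)))
  expect_error(kamada_kawai(g), "disconnected")
  expect_error(kamada_kawai(g), "3, 4")
})

test_that("arrangement enumeration finds interchangeable helices", {
  # star: leaves 2,3,4 all share neighbour set {1} -> 3! arrangements
  star <- interaction_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  perms <- equivalent_arrangements(star)
  expect_length(perms, 6)
  expect_equal(perms[[1]], 1:4)  # identity first
  # every permutation is a graph automorphism
  for (q in perms) {
    mapped <- cbind(q[star$edges[, 1]], q[star$edges[, 2]])
    expect_equal(interaction_graph(4, mapped)$edges, star$edges)
  }

  # two helices sharing identical interactions -> exactly 2 arrangements
  g <- interaction_graph(5, rbind(c(1, 3), c(2, 3), c(1, 4), c(2, 4),
                                  c(3, 4), c(4, 5)))
  expect_length(equivalent_arrangements(g), 2)

  # a 7-ring has no interchangeable helices
  ring <- interaction_graph(7, cbind(1:7, c(2:7, 1)))
  expect_length(equivalent_arrangements(ring), 1)
})

test_that("crossover counting matches the parametric-intersection oracle", {
  # convex ring order: sequential loops never cross
  ring <- circular_init(6, 5)
  expect_equal(count_same_side_crossovers(ring)$total, 0L)

  # constructed crossing: loops 1 (helices 1-2) and 3 (helices 3-4) same side
  pos <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  got <- count_same_side_crossovers(pos)
  expect_equal(got$total, 1L)
  expect_equal(got$side1, 1L)

  expect_error(count_same_side_crossovers(rbind(c(0, 0), c(0, 0))),
               "coincident")

  set.seed(31)
  for (rep in 1:60) {
    n <- sample(3:10, 1)
    pos <- matrix(runif(2 * n, -5, 5), n, 2)
    expect_equal(count_same_side_crossovers(pos), oracle_crossovers(pos))
  }
})

test_that("crossover counts are invariant to rotation, translation, scale", {
  set.seed(37)
  pos <- matrix(runif(16, -4, 4), 8, 2)
  base <- count_same_side_crossovers(pos)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- sweep(pos %*% R * 3.7, 2, c(11, -6), "+")
  expect_equal(count_same_side_crossovers(moved), base)
})

test_that("arrangement selection ranks by crossovers then contact distance", {
  # two interchangeable helices: one arrangement has fewer crossovers
  b <- make_bundle(bundle_spec(7, order = c(3, 1, 2, 4, 5, 6, 7), seed = 13))
  ring <- b$graph
  arr <- select_arrangement(ring, b$topo, contacts = NULL, seed = 1)
  expect_length(arr, 1)
  expect_true(same_cyclic_order(layout_cyclic_order(arr[[1]]$positions),
                                b$spec$order))

  # single-arrangement graph gives a list of length 1
  path4 <- interaction_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  topo4 <- topology(c(1, 21, 41, 61), c(16, 36, 56, 76))
  expect_length(select_arrangement(path4, topo4, contacts = NULL), 1)
})

test_that("equal-crossover ties are broken by lower total contact distance", {
  # star graph with two interchangeable leaves and contacts that favour
  # one leaf assignment: both arrangements have 0 crossovers
  topo <- topology(c(1, 21, 41), c(16, 36, 56))
  g <- interaction_graph(3, rbind(c(1, 2), c(1, 3)))
  cs <- contact_set(c(5, 6, 7), c(25, 26, 27), topo)  # h1-h2 contacts only
  arr <- select_arrangement(g, topo, contacts = cs,
                            ga = ga_config(pop_size = 40, generations = 60),
                            seed = 3)
  expect_length(arr, 2)
  expect_equal(arr[[1]]$crossovers$total, arr[[2]]$crossovers$total)
  expect_lte(arr[[1]]$contact_distance, arr[[2]]$contact_distance)
})
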