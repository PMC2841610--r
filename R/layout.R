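# 2-D helical packing arrangement: circular initialization, Kamada-Kawai
# spring-energy minimization, enumeration of interchangeable-helix
# arrangements, same-side loop-crossover counting, and ranked selection.

#' Layout parameters
#'
#' @param L0 Ideal edge length in layout units (rest length of a
#'   unit-graph-distance spring).
#' @param K Global spring constant.
#' @param tol Convergence tolerance on the maximum vertex gradient norm.
#' @param max_sweeps Maximum number of vertex-update sweeps.
#' @param init_radius Radius of the regular polygon used for initialization.
#' @param scale_min_dist After layout, coordinates are rescaled so the
#'   minimum inter-vertex distance equals this many Angstrom (typical
#'   helix-axis packing distance).
#' @return An object of class `layout_params`.
#' @export
layout_params <- function(L0 = 1, K = 1, tol = 1e-6, max_sweeps = 1000L,
                          init_radius = 1, scale_min_dist = 10) {
  stopifnot(L0 > 0, K > 0, tol > 0, max_sweeps >= 1, init_radius > 0,
            scale_min_dist > 0)
  structure(list(L0 = L0, K = K, tol = tol, max_sweeps = as.integer(max_sweeps),
                 init_radius = init_radius, scale_min_dist = scale_min_dist),
            class = "layout_params")
}

#' Regular-polygon initial layout
#'
#' Vertex `k` sits at angle `2*pi*(k-1)/n` on a circle of the given radius,
#' so vertex 1 is at angle 0.
#'
#' @param n Number of vertices (`>= 1`).
#' @param radius Circle radius.
#' @return `n x 2` coordinate matrix.
#' @export
circular_init <- function(n, radius = 1) {
  n <- as.integer(n)
  if (n < 1L) stop("need at least one vertex")
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = radius * cos(ang), y = radius * sin(ang))
}

# BFS all-pairs shortest path lengths of an interaction graph
graph_distances <- function(graph) {
  n <- graph$n
  adj <- neighbours_of(graph)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# spring energy of layout p given rest lengths l and strengths k (upper tri)
kk_energy <- function(p, l, k) {
  n <- nrow(p)
  e <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- sqrt(sum((p[i, ] - p[j, ])^2))
      e <- e + k[i, j] * (dij - l[i, j])^2
    }
  }
  e
}

# gradient of the energy with respect to vertex m
kk_gradient <- function(p, l, k, m) {
  g <- c(0, 0)
  for (j in seq_len(nrow(p))) {
    if (j == m) next
    delta <- p[m, ] - p[j, ]
    dij <- sqrt(sum(delta^2))
    if (dij < 1e-12) dij <- 1e-12
    g <- g + 2 * k[m, j] * (dij - l[m, j]) * delta / dij
  }
  g
}

#' Kamada-Kawai spring-energy layout
#'
#' Minimizes `E = sum_{i<j} k_ij (|p_i - p_j| - L0 * d_ij)^2` where `d_ij`
#' is the graph-theoretic shortest-path length and the spring strength
#' `k_ij = K / d_ij^2` is inversely proportional to the squared graph
#' distance. Vertices are updated one at a time (the vertex with the largest
#' gradient first) by a damped Newton step with backtracking, so the energy
#' never increases; iteration stops when the maximum gradient norm drops
#' below `tol` or after `max_sweeps` updates per vertex on average.
#'
#' @param graph A connected [interaction_graph()].
#' @param init `n x 2` initial coordinates (default [circular_init()]).
#' @param params A [layout_params()].
#' @return List with `positions` (`n x 2`), `energy`, `initial_energy`,
#'   `iterations`, `converged`.
#' @export
kamada_kawai <- function(graph, init = NULL, params = layout_params()) {
  n <- graph$n
  if (is.null(init)) init <- circular_init(n, params$init_radius)
  stopifnot(nrow(init) == n)
  if (n == 1L) {
    return(list(positions = init, energy = 0, initial_energy = 0,
                iterations = 0L, converged = TRUE))
  }
  d <- graph_distances(graph)
  if (any(is.infinite(d))) {
    comp <- which(is.infinite(d[1, ]))
    stop("cannot lay out a disconnected interaction graph (helices ",
         paste(comp, collapse = ", "), " unreachable from helix 1)")
  }
  l <- params$L0 * d
  k <- params$K / pmax(d, 1e-12)^2
  diag(k) <- 0
  p <- unname(as.matrix(init))
  e0 <- kk_energy(p, l, k)
  e <- e0
  max_iter <- params$max_sweeps * n
  iter <- 0L
  converged <- FALSE
  repeat {
    gnorms <- vapply(seq_len(n), function(m) sqrt(sum(kk_gradient(p, l, k, m)^2)),
                     numeric(1))
    m <- which.max(gnorms)
    if (gnorms[m] < params$tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    # 2x2 Newton step on vertex m with backtracking line search
    g <- kk_gradient(p, l, k, m)
    H <- matrix(0, 2, 2)
    for (j in seq_len(n)) {
      if (j == m) next
      delta <- p[m, ] - p[j, ]
      dij <- sqrt(sum(delta^2)); if (dij < 1e-12) dij <- 1e-12
      u <- delta / dij
      # Hessian of k (d - l)^2: 2k [ I - (l/d)(I - u u^T) ]
      H <- H + 2 * k[m, j] * (diag(2) - (l[m, j] / dij) * (diag(2) - tcrossprod(u)))
    }
    step <- tryCatch(solve(H, g), error = function(e) g)
    if (!all(is.finite(step)) || sum(step * g) <= 0) step <- g
    t_step <- 1
    old_row <- p[m, ]
    repeat {
      p[m, ] <- old_row - t_step * step
      e_new <- kk_energy(p, l, k)
      if (e_new <= e || t_step < 1e-10) break
      t_step <- t_step / 2
    }
    if (e_new > e) p[m, ] <- old_row else e <- e_new
    iter <- iter + 1L
  }
  stopifnot(e <= e0 + 1e-12)  # energy-descent invariant
  list(positions = p, energy = e, initial_energy = e0, iterations = iter,
       converged = converged)
}

#' Enumerate arrangements of interchangeable helices
#'
#' Two helices are interchangeable when they share the same interactions:
#' their neighbour sets, with the other member of the pair removed from
#' each, are identical. Interchangeability classes are closed transitively;
#' the returned permutations are all combinations of within-class
#' reorderings (always including the identity), capped at `max_perms`
#' (beyond the cap a seeded random sample is drawn, with a warning).
#'
#' @param graph An [interaction_graph()].
#' @param max_perms Enumeration cap (default 10000).
#' @param seed Seed for sampling past the cap.
#' @return List of integer permutations (`perm[h]` = layout slot of helix `h`).
#' @export
equivalent_arrangements <- function(graph, max_perms = 10000L, seed = 1L) {
  n <- graph$n
  adj <- neighbours_of(graph)
  # union-find over the "shares interactions" relation
  parent <- seq_len(n)
  find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b <= a) next
    if (setequal(setdiff(adj[[a]], b), setdiff(adj[[b]], a))) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  classes <- split(seq_len(n), vapply(seq_len(n), find, 1L))
  classes <- classes[vapply(classes, length, 1L) > 1L]
  if (length(classes) == 0L) return(list(seq_len(n)))

  total <- prod(vapply(classes, function(cl) factorial(length(cl)), 1))
  perms_of <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  if (total <= max_perms) {
    result <- list(seq_len(n))
    for (cl in classes) {
      cl_perms <- perms_of(cl)
      expanded <- list()
      for (base in result) {
        for (cp in cl_perms) {
          q <- base
          q[cl] <- cp
          expanded[[length(expanded) + 1L]] <- q
        }
      }
      result <- expanded
    }
    result <- unique(result)
    # identity first, then lexicographic
    ord <- order(vapply(result, function(q) paste(sprintf("%03d", q), collapse = ""), ""))
    result <- result[ord]
    idp <- which(vapply(result, function(q) all(q == seq_len(n)), logical(1)))
    c(result[idp], result[-idp])
  } else {
    warning("more than ", max_perms, " equivalent arrangements; sampling")
    result <- list(seq_len(n))
    seen <- new.env()
    assign(paste(seq_len(n), collapse = ","), TRUE, envir = seen)
    with_seed(seed, {
      while (length(result) < max_perms) {
        q <- seq_len(n)
        for (cl in classes) q[cl] <- sample(cl)
        key <- paste(q, collapse = ",")
        if (!exists(key, envir = seen)) {
          assign(key, TRUE, envir = seen)
          result[[length(result) + 1L]] <- q
        }
      }
    })
    result
  }
}

# orientation sign of the triplet (a, b, c): sign of cross(b - a, c - a)
orient_sign <- function(a, b, c) {
  v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  sign(v)
}

# proper crossing of open segments (p1, p2) and (p3, p4)
segments_cross <- function(p1, p2, p3, p4) {
  o1 <- orient_sign(p1, p2, p3); o2 <- orient_sign(p1, p2, p4)
  o3 <- orient_sign(p3, p4, p1); o4 <- orient_sign(p3, p4, p2)
  (o1 * o2 < 0) && (o3 * o4 < 0)
}

#' Count same-side loop crossovers of a layout
#'
#' Loop `i` is the segment joining the layout positions of helices `i` and
#' `i + 1` (adjacent in sequence). Because consecutive loops exit on
#' alternating membrane sides, loop `i` is assigned to side `i mod 2`;
#' crossings are counted only between loops on the same side, using a
#' cross-product orientation test for proper intersection (shared endpoints
#' and collinear touching do not count).
#'
#' @param positions `n x 2` matrix of helix positions, in helix order.
#'   Helix `h` is row `h`.
#' @return List with `side0`, `side1` (crossover counts for even- and
#'   odd-indexed loops) and `total`.
#' @export
count_same_side_crossovers <- function(positions) {
  n <- nrow(positions)
  if (n < 2L) return(list(side0 = 0L, side1 = 0L, total = 0L))
  loops <- lapply(seq_len(n - 1L), function(i)
    list(a = positions[i, ], b = positions[i + 1L, ], side = i %% 2L))
  for (lp in loops) {
    if (all(lp$a == lp$b)) stop("coincident helix positions give a zero-length loop")
  }
  counts <- c(`0` = 0L, `1` = 0L)
  if (length(loops) >= 2L) {
    for (i in seq_len(length(loops) - 1L)) {
      for (j in (i + 1L):length(loops)) {
        if (loops[[i]]$side != loops[[j]]$side) next
        if (segments_cross(loops[[i]]$a, loops[[i]]$b,
                           loops[[j]]$a, loops[[j]]$b)) {
          key <- as.character(loops[[i]]$side)
          counts[key] <- counts[key] + 1L
        }
      }
    }
  }
  list(side0 = unname(counts["0"]), side1 = unname(counts["1"]),
       total = unname(counts["0"] + counts["1"]))
}

#' Construct and rank helical packing arrangements
#'
#' Lays out the interaction graph once with [kamada_kawai()] (from the
#' regular-polygon start), rescales so the minimum inter-helix distance is
#' `scale_min_dist` Angstrom, then for every interchangeable-helix
#' permutation from [equivalent_arrangements()]: assigns helices to layout
#' slots, counts same-side loop crossovers, optimizes per-helix rotations
#' with the genetic algorithm (when contacts are supplied) and computes the
#' summed contact distance. Arrangements are ranked by crossovers
#' (ascending), then total contact distance (ascending), then id.
#'
#' @param graph A connected [interaction_graph()].
#' @param topo A [topology()] (needed to place residues on helical wheels).
#' @param contacts Optional [contact_set()] (or data frame `i`, `j`) of
#'   predicted/observed contact pairs; `NULL` skips rotation optimization.
#' @param params A [layout_params()].
#' @param ga A [ga_config()] for rotation optimization.
#' @param seed Integer seed (threaded to the GA and permutation sampling).
#' @return List of `arrangement` objects, ranked; each has `id`,
#'   `permutation`, `positions` (helix order), `crossovers`, `rotations`,
#'   `contact_distance`, `graph`, `layout`.
#' @export
select_arrangement <- function(graph, topo, contacts = NULL,
                               params = layout_params(), ga = ga_config(),
                               seed = 1L) {
  fit <- kamada_kawai(graph, circular_init(graph$n, params$init_radius), params)
  pos <- fit$positions
  if (graph$n >= 2L) {
    dmin <- min(stats::dist(pos))
    if (dmin <= 0) stop("degenerate layout: coincident vertices")
    pos <- pos * (params$scale_min_dist / dmin)
  }
  perms <- equivalent_arrangements(graph, seed = seed)
  arrangements <- vector("list", length(perms))
  for (k in seq_along(perms)) {
    perm <- perms[[k]]
    hpos <- pos[perm, , drop = FALSE]  # helix h at slot perm[h]
    cross <- count_same_side_crossovers(hpos)
    rot <- rep(0L, graph$n)
    cdist <- 0
    if (!is.null(contacts) && nrow(contacts) > 0L) {
      opt <- ga_optimize(hpos, topo, contacts, config = ga,
                         seed = seed + k)
      rot <- opt$rotations
      cdist <- opt$objective
    }
    arrangements[[k]] <- structure(
      list(id = k, permutation = perm, positions = hpos,
           crossovers = cross, rotations = rot, contact_distance = cdist,
           graph = graph, layout = fit),
      class = "arrangement")
  }
  ord <- order(vapply(arrangements, function(a) a$crossovers$total, 0L),
               vapply(arrangements, `[[`, 0, "contact_distance"),
               vapply(arrangements, `[[`, 0L, "id"))
  arrangements[ord]
}

#' @export
print.arrangement <- function(x, ...) {
  cat("<arrangement>", nrow(x$positions), "helices; crossovers",
      x$crossovers$total, "; contact distance",
      sprintf("%.2f", x$contact_distance), "A\n")
  invisible(x)
}
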