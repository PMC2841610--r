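# Helical-wheel projection of residues onto laid-out helices and a genetic
# algorithm optimizing one integer rotation angle (degrees) per helix so the
# summed 2-D distance over contact pairs is minimal.

HELIX_TWIST_DEG <- 100   # canonical alpha-helix: 3.6 residues/turn
WHEEL_RADIUS <- 2.3      # approximate C-beta radial distance, Angstrom

#' Residue position on a helical wheel
#'
#' Residue `k` of a helix sits at azimuth
#' `theta = rotation + 100 * (k - start)` degrees (counter-clockwise) on a
#' circle of radius `r` around the helix centre.
#'
#' @param center Length-2 numeric, helix centre (Angstrom).
#' @param k Residue position (within the helix span).
#' @param start First residue of the helix span.
#' @param end Last residue of the helix span (for bounds checking).
#' @param rotation Rotation angle in degrees.
#' @param r Wheel radius (Angstrom).
#' @param twist Helical twist in degrees per residue.
#' @return Length-2 numeric `(x, y)`.
#' @export
residue_xy <- function(center, k, start, end, rotation = 0,
                       r = WHEEL_RADIUS, twist = HELIX_TWIST_DEG) {
  if (k < start || k > end) {
    stop("residue ", k, " outside helix span ", start, "-", end)
  }
  theta <- (rotation + twist * (k - start)) * pi / 180
  c(center[1] + r * cos(theta), center[2] + r * sin(theta))
}

# Precompute, per contact pair, the helix indices and residue offsets so the
# objective can be evaluated for many rotation vectors at once.
.contact_pair_geometry <- function(positions, topo, contacts) {
  hx_i <- helix_of(topo, contacts$i)
  hx_j <- helix_of(topo, contacts$j)
  if (anyNA(hx_i) || anyNA(hx_j)) stop("contact residue outside TM helix spans")
  if (any(hx_i > nrow(positions)) || any(hx_j > nrow(positions))) {
    stop("contact references a helix missing from the layout")
  }
  list(
    ha = hx_i, hb = hx_j,
    off_a = HELIX_TWIST_DEG * (contacts$i - topo$start[hx_i]),
    off_b = HELIX_TWIST_DEG * (contacts$j - topo$start[hx_j]),
    cax = positions[hx_i, 1], cay = positions[hx_i, 2],
    cbx = positions[hx_j, 1], cby = positions[hx_j, 2])
}

# objective for a population: rows of `rot_mat` are rotation vectors (deg)
.contact_distance_pop <- function(geom, rot_mat, r = WHEEL_RADIUS) {
  deg <- pi / 180
  ta <- sweep(rot_mat[, geom$ha, drop = FALSE], 2, geom$off_a, "+") * deg
  tb <- sweep(rot_mat[, geom$hb, drop = FALSE], 2, geom$off_b, "+") * deg
  dx <- sweep(r * cos(ta), 2, geom$cax, "+") - sweep(r * cos(tb), 2, geom$cbx, "+")
  dy <- sweep(r * sin(ta), 2, geom$cay, "+") - sweep(r * sin(tb), 2, geom$cby, "+")
  rowSums(sqrt(dx^2 + dy^2))
}

#' Summed 2-D contact distance at given rotations
#'
#' @param positions `n x 2` helix centre matrix (helix `h` = row `h`),
#'   Angstrom.
#' @param topo A [topology()].
#' @param contacts A [contact_set()] (or data frame with columns `i`, `j`).
#' @param rotations Numeric vector of per-helix rotation angles (degrees).
#' @param r Wheel radius (Angstrom).
#' @return Total Euclidean 2-D distance over all contact pairs (Angstrom).
#' @export
contact_distance_sum <- function(positions, topo, contacts, rotations,
                                 r = WHEEL_RADIUS) {
  if (nrow(contacts) == 0L) return(0)
  stopifnot(length(rotations) == nrow(positions))
  geom <- .contact_pair_geometry(positions, topo, contacts)
  .contact_distance_pop(geom, matrix(rotations, nrow = 1), r = r)
}

#' Genetic-algorithm configuration
#'
#' @param pop_size Population size (`>= 2`).
#' @param generations Number of generations.
#' @param tournament Tournament size for selection.
#' @param crossover_rate Probability of uniform per-gene crossover.
#' @param mutation_rate Per-gene probability of redrawing an angle uniformly
#'   in 0..359.
#' @param elitism Number of best individuals copied unchanged.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100L, generations = 200L, tournament = 3L,
                      crossover_rate = 0.9, mutation_rate = 0.05,
                      elitism = 1L) {
  stopifnot(pop_size >= 2, generations >= 1, tournament >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1, elitism >= 0)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism)),
            class = "ga_config")
}

#' Optimize helix rotations with a genetic algorithm
#'
#' Each individual is one integer angle (0..359 degrees, one-degree
#' resolution) per helix; fitness is the summed 2-D contact distance.
#' Tournament selection, uniform per-gene crossover, uniform-redraw
#' mutation and elitism; with elitism the best objective is non-increasing
#' across generations and the result is never worse than the best initial
#' individual. Deterministic given the seed.
#'
#' @param positions `n x 2` helix centre matrix (Angstrom).
#' @param topo A [topology()].
#' @param contacts A non-empty [contact_set()] (or data frame `i`, `j`).
#' @param config A [ga_config()].
#' @param seed Integer seed.
#' @param r Wheel radius (Angstrom).
#' @return List with `rotations` (integer vector, degrees), `objective`
#'   (Angstrom) and `history` (best objective per generation).
#' @export
ga_optimize <- function(positions, topo, contacts, config = ga_config(),
                        seed = 1L, r = WHEEL_RADIUS) {
  if (is.null(contacts) || nrow(contacts) == 0L) {
    stop("no contact pairs: nothing to optimize")
  }
  n <- nrow(positions)
  geom <- .contact_pair_geometry(positions, topo, contacts)
  with_seed(seed, {
    pop <- matrix(sample(0:359, config$pop_size * n, replace = TRUE),
                  nrow = config$pop_size)
    fitness <- .contact_distance_pop(geom, pop, r = r)
    history <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      ord <- order(fitness)
      new_pop <- matrix(0L, nrow = config$pop_size, ncol = n)
      n_elite <- min(config$elitism, config$pop_size)
      if (n_elite > 0L) new_pop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], ]
      for (s in seq(n_elite + 1L, length.out = config$pop_size - n_elite)) {
        pick <- function() {
          cand <- sample.int(config$pop_size, config$tournament, replace = TRUE)
          cand[which.min(fitness[cand])]
        }
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        child <- if (runif(1) < config$crossover_rate) {
          take1 <- runif(n) < 0.5
          ifelse(take1, p1, p2)
        } else p1
        mut <- runif(n) < config$mutation_rate
        if (any(mut)) child[mut] <- sample(0:359, sum(mut), replace = TRUE)
        new_pop[s, ] <- child
      }
      pop <- new_pop
      fitness <- .contact_distance_pop(geom, pop, r = r)
      history[gen] <- min(fitness)
    }
    best <- which.min(fitness)
    list(rotations = as.integer(pop[best, ] %% 360L),
         objective = fitness[best],
         history = history)
  })
}
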