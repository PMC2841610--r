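# Shared helpers: tiny hand-built structures and independent oracles used
# across test files. Oracles here are deliberately written as plain loops /
# closed forms, independent of the package's vectorized implementations.

# a minimal structure_coords data frame from a table of atoms
coords_df <- function(residue, atom, element, x, y, z) {
  structure(data.frame(residue = residue, resid = "ALA", atom = atom,
                       element = element, x = x, y = y, z = z,
                       hydrogen = element %in% c("H", "D")),
            class = c("structure_coords", "data.frame"))
}

# independent O(n^2) segment-intersection oracle for loop crossovers:
# parametric solve for the intersection point rather than orientation signs
oracle_crossovers <- function(positions) {
  n <- nrow(positions)
  if (n < 2) return(list(side0 = 0L, side1 = 0L, total = 0L))
  seg <- lapply(seq_len(n - 1), function(i)
    list(p = positions[i, ], r = positions[i + 1, ] - positions[i, ],
         side = i %% 2))
  counts <- c(0L, 0L)  # side0, side1
  for (i in seq_along(seg)) for (j in seq_along(seg)) {
    if (j <= i || seg[[i]]$side != seg[[j]]$side) next
    p <- seg[[i]]$p; r <- seg[[i]]$r
    q <- seg[[j]]$p; s <- seg[[j]]$r
    denom <- r[1] * s[2] - r[2] * s[1]
    if (abs(denom) < 1e-300) next  # parallel: no proper crossing
    t <- ((q[1] - p[1]) * s[2] - (q[2] - p[2]) * s[1]) / denom
    u <- ((q[1] - p[1]) * r[2] - (q[2] - p[2]) * r[1]) / denom
    if (t > 0 && t < 1 && u > 0 && u < 1) {
      counts[seg[[i]]$side + 1L] <- counts[seg[[i]]$side + 1L] + 1L
    }
  }
  list(side0 = counts[1], side1 = counts[2], total = sum(counts))
}

# exhaustive 2-helix rotation optimum over the full 360x360 integer grid
exhaustive_two_helix_optimum <- function(positions, topo, contacts,
                                         step = 1L) {
  angles <- seq(0L, 359L, by = step)
  best <- Inf
  for (a in angles) {
    d <- vapply(angles, function(b)
      contact_distance_sum(positions, topo, contacts, c(a, b)), numeric(1))
    m <- min(d)
    if (m < best) best <- m
  }
  best
}

# cyclic order of layout positions around their centroid
layout_cyclic_order <- function(positions) {
  ang <- atan2(positions[, 2] - mean(positions[, 2]),
               positions[, 1] - mean(positions[, 1]))
  order(ang)
}

# are two cyclic orders equal up to rotation and reflection?
same_cyclic_order <- function(a, b) {
  n <- length(a)
  if (length(b) != n) return(FALSE)
  for (shift in seq_len(n)) {
    rot <- c(b[shift:n], b[seq_len(shift - 1)])
    if (all(a == rot) || all(a == rev(rot))) return(TRUE)
  }
  FALSE
}

# small lipid-exposure dataset built from 2-helix bundles
lipid_dataset <- function(seeds, signal_strength, helix_len = 16L) {
  lapply(seeds, function(s) {
    b <- make_bundle(bundle_spec(2, helix_len = helix_len, seed = s))
    p <- make_profiles(b, signal_strength = signal_strength, seed = s + 500)
    f <- build_lipid_features(b$protein, p$profile, b$topo)
    list(id = paste0("p", s), features = f, labels = unname(p$exposed))
  })
}
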