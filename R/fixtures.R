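# Synthetic fixture generator: idealized TM helix bundles with known
# geometry and contacts, sequence profiles with planted lipid-exposure
# signal, lipid-fraction tables and decoy interaction sets. Everything is
# deterministic given (spec, seed).

TM_RESIDUE_POOL <- c("L", "I", "V", "F", "A", "M", "T", "W")
LOOP_PATTERN <- c("S", "P", "N", "S")
HYDROPHOBIC_COLS <- c("A", "F", "I", "L", "M", "V")
POLAR_COLS <- c("D", "E", "K", "N", "Q", "R", "S", "T")
INTERFACE_COLS <- c("C", "G", "H", "P", "W", "Y")

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

#' Bundle specification for the synthetic generator
#'
#' Describes an idealized TM helix bundle: helices stand perpendicular to
#' the membrane plane, their axes on a ring (or at explicit centres), with
#' antiparallel alternation (odd helices up, even down).
#'
#' @param n Number of helices.
#' @param helix_len Residues per helix (default 16).
#' @param spacing Inter-axis distance between ring-adjacent helices
#'   (Angstrom, default 9.5).
#' @param order Circular order: `order[t]` is the helix occupying ring slot
#'   `t`. Default `1:n`.
#' @param centers Optional explicit `n x 2` axis positions (Angstrom,
#'   row = helix); overrides `spacing`/`order`.
#' @param rotations Per-helix azimuth offsets in degrees; default drawn
#'   uniformly from 0..359 using `seed`.
#' @param loop_len Residues between consecutive helices (default 4).
#' @param seed Integer seed.
#' @return An object of class `bundle_spec`.
#' @export
bundle_spec <- function(n, helix_len = 16L, spacing = 9.5, order = seq_len(n),
                        centers = NULL, rotations = NULL, loop_len = 4L,
                        seed = 1L) {
  n <- as.integer(n)
  stopifnot(n >= 1L, helix_len >= 4L, loop_len >= 4L,
            length(order) == n, all(sort(order) == seq_len(n)))
  if (is.null(centers)) {
    if (n == 1L) {
      centers <- matrix(0, 1, 2)
    } else if (n == 2L) {
      centers <- rbind(c(0, 0), c(spacing, 0))[order(order), , drop = FALSE]
    } else {
      R <- spacing / (2 * sin(pi / n))
      ang <- 2 * pi * (seq_len(n) - 1L) / n
      slots <- cbind(R * cos(ang), R * sin(ang))
      centers <- matrix(0, n, 2)
      centers[order, ] <- slots  # helix order[t] occupies slot t
    }
  } else {
    centers <- as.matrix(centers)
    stopifnot(nrow(centers) == n, ncol(centers) == 2)
  }
  if (is.null(rotations)) {
    rotations <- with_seed(seed, sample(0:359, n, replace = TRUE))
  }
  structure(list(n = n, helix_len = as.integer(helix_len), spacing = spacing,
                 order = as.integer(order), centers = centers,
                 rotations = as.numeric(rotations),
                 loop_len = as.integer(loop_len), seed = as.integer(seed)),
            class = "bundle_spec")
}

# idealized helix atoms for one residue: backbone pseudo-atoms + CB + one
# extended side-chain pseudo-atom 2.5 A from CB (45 degrees outward/up)
.residue_atoms <- function(cx, cy, theta_deg, z, dir) {
  th <- theta_deg * pi / 180
  radial <- c(cos(th), sin(th))
  list(
    N  = c(cx + 1.5 * cos(th - 0.45), cy + 1.5 * sin(th - 0.45), z - 0.6, "N"),
    CA = c(cx + 2.3 * radial[1], cy + 2.3 * radial[2], z, "C"),
    C  = c(cx + 1.7 * cos(th + 0.45), cy + 1.7 * sin(th + 0.45), z + 0.55, "C"),
    O  = c(cx + 2.0 * cos(th + 0.62), cy + 2.0 * sin(th + 0.62), z + 1.2, "O"),
    CB = c(cx + 3.3 * radial[1], cy + 3.3 * radial[2], z + 0.5 * dir, "C"),
    CG = c(cx + (3.3 + 2.5 * cos(pi / 4)) * radial[1],
           cy + (3.3 + 2.5 * cos(pi / 4)) * radial[2],
           z + 0.5 * dir + 2.5 * sin(pi / 4), "C"))
}

#' Generate an idealized TM helix bundle
#'
#' Builds ideal alpha-helices (rise 1.5 Angstrom/residue, twist 100
#' degrees/residue, backbone + C-beta + one extended side-chain
#' pseudo-atom) at the spec's axis positions, alternating up/down, joined
#' by loops; the ground-truth contact set is computed with a brute-force
#' per-residue-pair distance scan and the interaction graph follows from
#' it.
#'
#' @param spec A [bundle_spec()].
#' @param definition A [contact_definition()] used for the ground-truth
#'   contact set.
#' @return List with `protein` ([protein_record()]), `topo` ([topology()]),
#'   `coords` (`structure_coords`), `contacts` ([contact_set()]), `graph`
#'   ([interaction_graph()]), and `spec`.
#' @export
make_bundle <- function(spec, definition = contact_definition()) {
  n <- spec$n; len <- spec$helix_len
  if (n >= 2L && min(stats::dist(spec$centers)) < 2 * WHEEL_RADIUS) {
    stop("helix axes closer than one wheel diameter: overlapping helices")
  }
  seq_chars <- character(0)
  starts <- integer(n); ends <- integer(n)
  rows <- list()
  pos <- 0L
  tm_seq <- with_seed(spec$seed + 7L,
                      sample(TM_RESIDUE_POOL, n * len, replace = TRUE))
  for (h in seq_len(n)) {
    if (h > 1L) {
      seq_chars <- c(seq_chars, rep(LOOP_PATTERN, length.out = spec$loop_len))
      pos <- pos + spec$loop_len
    }
    starts[h] <- pos + 1L; ends[h] <- pos + len
    dir <- if (h %% 2L == 1L) 1 else -1
    cx <- spec$centers[h, 1]; cy <- spec$centers[h, 2]
    for (kk in seq_len(len)) {
      resno <- pos + kk
      z <- dir * 1.5 * (kk - 1) - dir * 1.5 * (len - 1) / 2
      theta <- spec$rotations[h] + dir * HELIX_TWIST_DEG * (kk - 1)
      atoms <- .residue_atoms(cx, cy, theta, z, dir)
      aa <- tm_seq[(h - 1L) * len + kk]
      for (an in names(atoms)) {
        a <- atoms[[an]]
        rows[[length(rows) + 1L]] <- data.frame(
          residue = resno, resid = AA3[[aa]], atom = an, element = a[4],
          x = as.numeric(a[1]), y = as.numeric(a[2]), z = as.numeric(a[3]),
          hydrogen = FALSE)
      }
      seq_chars <- c(seq_chars, aa)
    }
    pos <- pos + len
  }
  protein <- protein_record(sprintf("bundle_n%d_s%d", n, spec$seed),
                            paste(seq_chars, collapse = ""))
  topo <- topology(starts, ends, L = protein$length)
  coords <- structure(do.call(rbind, rows),
                      class = c("structure_coords", "data.frame"))
  contacts <- brute_force_contacts(coords, topo, definition, protein$sequence)
  graph <- observed_helix_interactions(contacts, topo)
  list(protein = protein, topo = topo, coords = coords, contacts = contacts,
       graph = graph, spec = spec)
}

#' Brute-force reference contact scan
#'
#' Independent per-residue-pair double loop over atom coordinates; used to
#' label ground-truth contacts in generated bundles and as the reference
#' oracle [residue_contacts()] is validated against.
#'
#' @inheritParams residue_contacts
#' @return A [contact_set()].
#' @export
brute_force_contacts <- function(coords, topo, definition, sequence) {
  if (inherits(sequence, "protein_record")) sequence <- sequence$sequence
  chars <- strsplit(sequence, "")[[1]]
  tm <- tm_residues(topo)
  tm <- tm[tm %in% coords$residue]
  hx <- helix_of(topo, tm)
  atoms_by_res <- split(coords[!coords$hydrogen, ], coords$residue[!coords$hydrogen])
  ci <- integer(); cj <- integer()
  for (a in seq_along(tm)) {
    for (b in seq_along(tm)) {
      if (b <= a || hx[a] == hx[b]) next
      ra <- atoms_by_res[[as.character(tm[a])]]
      rb <- atoms_by_res[[as.character(tm[b])]]
      if (is.null(ra) || is.null(rb)) next
      hit <- FALSE
      if (definition$kind == 1L) {
        wa <- if (chars[tm[a]] == "G") "CA" else "CB"
        wb <- if (chars[tm[b]] == "G") "CA" else "CB"
        pa <- ra[ra$atom == wa, ]; pb <- rb[rb$atom == wb, ]
        if (nrow(pa) == 0L) pa <- ra[ra$atom == "CA", ]
        if (nrow(pb) == 0L) pb <- rb[rb$atom == "CA", ]
        if (nrow(pa) > 0L && nrow(pb) > 0L) {
          dd <- sqrt((pa$x[1] - pb$x[1])^2 + (pa$y[1] - pb$y[1])^2 +
                     (pa$z[1] - pb$z[1])^2)
          hit <- dd <= definition$cbeta_cutoff
        }
      } else {
        for (u in seq_len(nrow(ra))) {
          dd <- sqrt((ra$x[u] - rb$x)^2 + (ra$y[u] - rb$y)^2 + (ra$z[u] - rb$z)^2)
          if (definition$kind == 2L) {
            thr <- definition$vdw_radii[ra$element[u]] +
                   definition$vdw_radii[rb$element] + definition$vdw_margin
            if (any(dd < thr)) { hit <- TRUE; break }
          } else {
            if (any(dd < definition$heavy_cutoff)) { hit <- TRUE; break }
          }
        }
      }
      if (hit) { ci <- c(ci, tm[a]); cj <- c(cj, tm[b]) }
    }
  }
  if (length(ci) == 0L) return(empty_contact_set(topo))
  contact_set(ci, cj, topo)
}

# outward cosine of each TM residue's side-chain azimuth: +1 points straight
# away from the bundle centroid, -1 straight at it
.residue_outwardness <- function(bundle) {
  spec <- bundle$spec; topo <- bundle$topo
  centroid <- colMeans(spec$centers)
  tm <- tm_residues(topo)
  hx <- helix_of(topo, tm)
  outward <- numeric(length(tm))
  for (k in seq_along(tm)) {
    h <- hx[k]
    dir <- if (h %% 2L == 1L) 1 else -1
    off <- tm[k] - topo$start[h]
    theta <- (spec$rotations[h] + dir * HELIX_TWIST_DEG * off) * pi / 180
    radial <- c(cos(theta), sin(theta))
    toward <- centroid - spec$centers[h, ]
    nt <- sqrt(sum(toward^2))
    # single helix (centroid == centre): everything faces lipid
    outward[k] <- if (nt < 1e-9) 1 else -sum(radial * toward) / nt
  }
  stats::setNames(outward, tm)
}

# is a TM residue's side chain pointing away from the bundle centroid?
.residue_exposed <- function(bundle) {
  out <- .residue_outwardness(bundle)
  stats::setNames(out > 0, names(out))
}

#' Plant a lipid-exposure signal into a profile and fraction table
#'
#' Residues whose side chains point more than 90 degrees away from the
#' bundle centroid are lipid exposed. The planted profile has two
#' components, mimicking the sequence signals evolution leaves on TM
#' helices: a binary hydrophobicity/conservation contrast (hydrophobic
#' columns enriched and polar columns depleted on lipid-facing residues,
#' and vice versa for the core) and a graded interface-propensity component
#' (small/aromatic packing-motif columns enriched in proportion to how
#' directly a side chain faces the bundle core). The lipid-contact fraction
#' is graded with the same geometry (`0.5 + 0.45 * outwardness`), so the
#' exposure label (`fraction > 0.5`) coincides with the side chain pointing
#' away from the core. Gaussian noise with standard deviation
#' `1/signal_strength` is added to every profile cell
#' (`signal_strength = 0` gives pure noise, i.e. profiles carry no signal;
#' `signal_strength = Inf` is noiseless).
#'
#' @param bundle Output of [make_bundle()].
#' @param signal_strength Non-negative signal-to-noise control (default 4).
#' @param seed Integer seed.
#' @return List with `profile` (`L x 20` matrix), `fractions` (named
#'   vector over TM residues) and `exposed` (named logical ground truth).
#' @export
make_profiles <- function(bundle, signal_strength = 4, seed = 1L) {
  stopifnot(signal_strength >= 0)
  L <- bundle$protein$length
  outward <- .residue_outwardness(bundle)
  exposed <- stats::setNames(outward > 0, names(outward))
  tm <- as.integer(names(outward))
  pattern <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  if (signal_strength > 0) {
    for (k in seq_along(tm)) {
      s <- if (exposed[k]) 1 else -1
      pattern[tm[k], HYDROPHOBIC_COLS] <- s
      pattern[tm[k], POLAR_COLS] <- -s
      pattern[tm[k], INTERFACE_COLS] <- -outward[k]
    }
  }
  noise_sd <- if (is.infinite(signal_strength)) 0
              else if (signal_strength == 0) 1 else 1 / signal_strength
  noise <- with_seed(seed, matrix(stats::rnorm(L * 20, sd = noise_sd), L, 20))
  profile <- pattern + noise
  colnames(profile) <- AA_ALPHABET
  fractions <- stats::setNames(0.5 + 0.45 * outward, tm)
  list(profile = profile, fractions = fractions, exposed = exposed)
}

#' Generate decoy interaction sets
#'
#' Each decoy differs from the native graph in at least one helix pair: a
#' flip count is drawn from `1..choose(n, 2)` and that many pairs have
#' their edge presence toggled. Decoys are distinct from each other and
#' from the native graph.
#'
#' @param native The native [interaction_graph()].
#' @param n_decoys Number of decoys requested.
#' @param seed Integer seed.
#' @return List of [arrangement_candidate()]s tagged `"decoy"`.
#' @export
make_decoys <- function(native, n_decoys, seed = 1L) {
  stopifnot(n_decoys >= 1L)
  n <- native$n
  if (n < 2L) stop("decoys need at least 2 helices")
  npairs <- choose(n, 2)
  if (n_decoys > 2^npairs - 1) {
    stop("cannot make ", n_decoys, " distinct decoys: only ",
         2^npairs - 1, " non-native graphs exist on ", n, " helices")
  }
  pairs <- t(utils::combn(n, 2))
  native_key <- paste(apply(native$edges, 1, paste, collapse = "-"),
                      collapse = ",")
  with_seed(seed, {
    decoys <- list()
    seen <- character(0)
    tries <- 0L
    while (length(decoys) < n_decoys) {
      tries <- tries + 1L
      if (tries > 1000L * n_decoys) stop("decoy sampling failed to find enough distinct graphs")
      nflip <- sample.int(npairs, 1)
      flip <- sample.int(npairs, nflip)
      edges <- native$edges
      for (f in flip) {
        a <- pairs[f, 1]; b <- pairs[f, 2]
        if (has_edge(interaction_graph(n, edges), a, b)) {
          keep <- !(edges[, 1] == a & edges[, 2] == b)
          edges <- edges[keep, , drop = FALSE]
        } else {
          edges <- rbind(edges, c(a, b))
        }
      }
      g <- interaction_graph(n, edges)
      key <- paste(apply(g$edges, 1, paste, collapse = "-"), collapse = ",")
      if (key == native_key || key %in% seen) next
      seen <- c(seen, key)
      decoys[[length(decoys) + 1L]] <-
        arrangement_candidate(sprintf("decoy_%03d", length(decoys) + 1L), g,
                              provenance = "decoy")
    }
    decoys
  })
}
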