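# Ground-truth labelling from coordinates and lipid-fraction tables:
# lipid-exposed residues, inter-helix residue contacts under three geometric
# definitions, and the helix-helix interaction graph they induce.

#' Contact definition
#'
#' Geometric rule declaring two residues on different TM helices to be in
#' contact:
#' * definition 1 — C-beta/C-beta distance (C-alpha for glycine) at most
#'   `cbeta_cutoff` (8 Angstrom);
#' * definition 2 — any non-hydrogen atom pair closer than the sum of the
#'   two van der Waals radii plus `vdw_margin` (0.6 Angstrom);
#' * definition 3 — any backbone or side-chain heavy-atom pair closer than
#'   `heavy_cutoff` (5.5 Angstrom).
#'
#' Definition 1 uses a non-strict cutoff ("maximal distance of 8 A");
#' definitions 2 and 3 are strict ("less than").
#'
#' @param kind Integer in `1:3`.
#' @param cbeta_cutoff,vdw_margin,heavy_cutoff Cutoffs in Angstrom.
#' @param vdw_radii Named vector of element van der Waals radii (Angstrom);
#'   Bondi-style defaults covering C, N, O, S, P.
#' @return An object of class `contact_definition`.
#' @export
contact_definition <- function(kind = 1L,
                               cbeta_cutoff = 8.0,
                               vdw_margin = 0.6,
                               heavy_cutoff = 5.5,
                               vdw_radii = c(C = 1.70, N = 1.55, O = 1.52,
                                             S = 1.80, P = 1.80)) {
  kind <- as.integer(kind)
  stopifnot(kind %in% 1:3, cbeta_cutoff > 0, vdw_margin >= 0, heavy_cutoff > 0,
            all(c("C", "N", "O", "S") %in% names(vdw_radii)))
  structure(list(kind = kind, cbeta_cutoff = cbeta_cutoff,
                 vdw_margin = vdw_margin, heavy_cutoff = heavy_cutoff,
                 vdw_radii = vdw_radii),
            class = "contact_definition")
}

#' Label lipid-exposed TM residues
#'
#' A TM residue is lipid exposed when its fraction of simulation time in
#' lipid contact exceeds the threshold (strictly greater than 0.5 by
#' default). Residues outside TM helices are excluded.
#'
#' @param fractions Named numeric vector as from [read_lipid_fractions()].
#' @param topo A [topology()].
#' @param threshold Exposure threshold, default 0.5 (strict `>`).
#' @return Named logical vector over TM residues.
#' @export
label_lipid_exposed <- function(fractions, topo, threshold = 0.5) {
  tm <- tm_residues(topo)
  missing <- setdiff(as.character(tm), names(fractions))
  if (length(missing) > 0L) {
    stop("missing lipid fraction for TM residue(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  f <- fractions[as.character(tm)]
  stats::setNames(f > threshold, tm)
}

# Cbeta (Calpha for glycine) coordinate per TM residue; falls back to Calpha
# with a warning when a non-glycine residue lacks a Cbeta.
.rep_atom_coords <- function(coords, residues, sequence) {
  out <- matrix(NA_real_, nrow = length(residues), ncol = 3)
  chars <- strsplit(sequence, "")[[1]]
  warned <- FALSE
  for (k in seq_along(residues)) {
    r <- residues[k]
    rows <- coords[coords$residue == r, , drop = FALSE]
    want <- if (chars[r] == "G") "CA" else "CB"
    hit <- rows[rows$atom == want, , drop = FALSE]
    if (nrow(hit) == 0L && want == "CB") {
      hit <- rows[rows$atom == "CA", , drop = FALSE]
      if (nrow(hit) > 0L && !warned) {
        warning("missing CB for non-glycine residue ", r,
                "; falling back to CA")
        warned <- TRUE
      }
    }
    if (nrow(hit) == 0L) next
    out[k, ] <- c(hit$x[1], hit$y[1], hit$z[1])
  }
  out
}

#' Inter-helix residue contacts from coordinates
#'
#' Applies a [contact_definition()] to every residue pair lying on different
#' TM helices. Loop and re-entrant residues (anything outside the TM spans)
#' never enter the contact set.
#'
#' @param coords A `structure_coords` data frame (see [read_structure()]).
#' @param topo A [topology()].
#' @param definition A [contact_definition()].
#' @param sequence Protein sequence (string) aligned to `coords` residue
#'   numbering; needed to find glycines for definition 1.
#' @return A [contact_set()].
#' @export
residue_contacts <- function(coords, topo, definition = contact_definition(),
                             sequence) {
  if (inherits(sequence, "protein_record")) sequence <- sequence$sequence
  tm <- tm_residues(topo)
  tm <- tm[tm %in% unique(coords$residue)]
  if (length(tm) == 0L) stop("no TM residues with coordinates")
  hx <- helix_of(topo, tm)

  pairs_i <- integer(); pairs_j <- integer()
  if (definition$kind == 1L) {
    rep_xyz <- .rep_atom_coords(coords, tm, sequence)
    ok <- stats::complete.cases(rep_xyz)
    d <- as.matrix(stats::dist(rep_xyz[ok, , drop = FALSE]))
    tm_ok <- tm[ok]; hx_ok <- hx[ok]
    idx <- which(upper.tri(d) & d <= definition$cbeta_cutoff, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      keep <- hx_ok[idx[, 1]] != hx_ok[idx[, 2]]
      pairs_i <- tm_ok[idx[keep, 1]]
      pairs_j <- tm_ok[idx[keep, 2]]
    }
  } else {
    at <- coords[coords$residue %in% tm & !coords$hydrogen, , drop = FALSE]
    if (definition$kind == 2L) {
      rad <- definition$vdw_radii[at$element]
      if (anyNA(rad)) stop("no van der Waals radius for element(s): ",
                           paste(unique(at$element[is.na(rad)]), collapse = ", "))
    }
    xyz <- as.matrix(at[, c("x", "y", "z")])
    res <- at$residue
    ahx <- helix_of(topo, res)
    d <- as.matrix(stats::dist(xyz))
    hit <- if (definition$kind == 2L) {
      thr <- outer(rad, rad, "+") + definition$vdw_margin
      d < thr
    } else {
      d < definition$heavy_cutoff
    }
    hit[ahx[row(hit)] == ahx[col(hit)]] <- FALSE
    idx <- which(hit & upper.tri(hit), arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      pairs_i <- res[idx[, 1]]
      pairs_j <- res[idx[, 2]]
    }
  }
  if (length(pairs_i) == 0L) return(empty_contact_set(topo))
  contact_set(pairs_i, pairs_j, topo)
}

#' Helix-helix interactions observed in a contact set
#'
#' Two helices interact when at least one residue from each is in contact.
#'
#' @param contacts A [contact_set()].
#' @param topo A [topology()].
#' @return An [interaction_graph()] on the topology's helices.
#' @export
observed_helix_interactions <- function(contacts, topo) {
  n <- n_helices(topo)
  if (nrow(contacts) == 0L) return(interaction_graph(n))
  edges <- unique(cbind(pmin(contacts$helix_i, contacts$helix_j),
                        pmax(contacts$helix_i, contacts$helix_j)))
  interaction_graph(n, edges)
}
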