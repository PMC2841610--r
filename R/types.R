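# Core domain types: lightweight S3 containers with validation at construction.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_NONCANONICAL <- c("X", "B", "Z", "U")

#' Protein record
#'
#' A protein sequence with an identifier. Non-canonical letters (X, B, Z, U)
#' are accepted and later mapped to zero profile columns; any other character
#' is rejected.
#'
#' @param id Single string, record identifier.
#' @param sequence Single string over the 20-letter amino-acid alphabet
#'   (plus X/B/Z/U), case-insensitive.
#' @return An object of class `protein_record` with fields `id`, `sequence`
#'   and `length`.
#' @export
protein_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(sequence) < 1L) stop("empty sequence for record '", id, "'")
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% c(AA_ALPHABET, AA_NONCANONICAL))
  if (length(bad) > 0L) {
    stop("illegal residue character '", chars[bad[1]], "' at position ",
         bad[1], " in record '", id, "'")
  }
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$id, "-", x$length, "residues\n")
  invisible(x)
}

#' Transmembrane topology
#'
#' Ordered set of TM helix spans (1-based, inclusive). Spans are sorted by
#' start and must not overlap; when `L` is given every span must lie within
#' `[1, L]`.
#'
#' @param starts,ends Integer vectors of equal length, 1-based inclusive
#'   helix boundaries.
#' @param L Optional sequence length for bounds checking.
#' @return An object of class `topology`: a data frame with columns
#'   `helix`, `start`, `end` plus attribute `n`.
#' @export
topology <- function(starts, ends, L = NULL) {
  starts <- as.integer(starts); ends <- as.integer(ends)
  stopifnot(length(starts) == length(ends), length(starts) >= 1L)
  if (any(starts > ends)) {
    i <- which(starts > ends)[1]
    stop("invalid helix span ", starts[i], "-", ends[i], ": start > end")
  }
  if (any(starts < 1L)) stop("helix span starts before residue 1")
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)])) {
    stop("overlapping helix spans")
  }
  if (!is.null(L) && any(ends > L)) {
    stop("helix span extends beyond sequence length ", L)
  }
  out <- data.frame(helix = seq_along(starts), start = starts, end = ends)
  structure(out, n = nrow(out), class = c("topology", "data.frame"))
}

#' Number of TM helices in a topology
#' @param topo A [topology()] object.
#' @return Integer helix count.
#' @export
n_helices <- function(topo) attr(topo, "n")

#' Map residue positions to helix indices
#'
#' @param topo A [topology()] object.
#' @param positions Integer vector of 1-based residue positions.
#' @return Integer vector: helix index per position, `NA` for residues
#'   outside every TM span.
#' @export
helix_of <- function(topo, positions) {
  out <- rep(NA_integer_, length(positions))
  for (h in seq_len(nrow(topo))) {
    inside <- positions >= topo$start[h] & positions <= topo$end[h]
    out[inside] <- topo$helix[h]
  }
  out
}

#' All TM residue positions of a topology
#' @param topo A [topology()] object.
#' @return Sorted integer vector of residue positions inside TM helices.
#' @export
tm_residues <- function(topo) {
  unlist(lapply(seq_len(nrow(topo)),
                function(h) topo$start[h]:topo$end[h]), use.names = FALSE)
}

#' Interaction graph over TM helices
#'
#' Undirected, simple graph on helix indices `1..n`; edges are stored as a
#' two-column matrix with `a < b`, deduplicated and sorted.
#'
#' @param n Number of helices (vertices).
#' @param edges Two-column matrix (or empty) of helix-index pairs.
#' @return An object of class `interaction_graph`.
#' @export
interaction_graph <- function(n, edges = matrix(integer(), ncol = 2)) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L | edges > n)) stop("edge endpoint outside 1..n")
    if (any(edges[, 1] == edges[, 2])) stop("self-loop edges not allowed")
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(n = n, edges = edges), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("<interaction_graph>", x$n, "helices,", nrow(x$edges), "interactions\n")
  if (nrow(x$edges) > 0L)
    cat(" ", paste(x$edges[, 1], x$edges[, 2], sep = "-", collapse = " "), "\n")
  invisible(x)
}

#' Test edge membership in an interaction graph
#' @param graph An [interaction_graph()].
#' @param a,b Helix indices.
#' @return Logical.
#' @export
has_edge <- function(graph, a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  any(graph$edges[, 1] == lo & graph$edges[, 2] == hi)
}

#' Adjacency list of an interaction graph
#' @param graph An [interaction_graph()].
#' @return List of integer neighbour vectors, one per vertex.
#' @export
neighbours_of <- function(graph) {
  adj <- vector("list", graph$n)
  for (v in seq_len(graph$n)) adj[[v]] <- integer()
  if (nrow(graph$edges) > 0L) {
    for (k in seq_len(nrow(graph$edges))) {
      a <- graph$edges[k, 1]; b <- graph$edges[k, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  lapply(adj, sort)
}

#' Contact set
#'
#' Inter-helix residue contacts: pairs `(i, j)` with `i < j`, annotated with
#' the helix index of each residue. Both residues must lie inside TM spans
#' and on different helices.
#'
#' @param i,j Integer residue positions.
#' @param topo A [topology()] used to annotate and validate helix membership.
#' @return An object of class `contact_set`: a data frame with columns
#'   `i`, `j`, `helix_i`, `helix_j`.
#' @export
contact_set <- function(i, j, topo) {
  i <- as.integer(i); j <- as.integer(j)
  stopifnot(length(i) == length(j))
  lo <- pmin(i, j); hi <- pmax(i, j)
  hi_h <- helix_of(topo, hi); lo_h <- helix_of(topo, lo)
  if (anyNA(lo_h) || anyNA(hi_h)) stop("contact residue outside TM helix spans")
  if (any(lo_h == hi_h)) stop("intra-helix pair in contact set")
  out <- data.frame(i = lo, j = hi, helix_i = lo_h, helix_j = hi_h)
  out <- unique(out)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("contact_set", "data.frame"))
}

#' Empty contact set helper
#' @param topo A [topology()].
#' @return A `contact_set` with zero rows.
#' @export
empty_contact_set <- function(topo) {
  structure(data.frame(i = integer(), j = integer(),
                       helix_i = integer(), helix_j = integer()),
            class = c("contact_set", "data.frame"))
}
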