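# Predicted helix-helix interactions from pair scores, and scoring/ranking of
# candidate packing arrangements (native / native model / decoys) against the
# predicted interaction graph.

#' Predicted helix-helix interactions from residue-pair scores
#'
#' Applies the interaction rule to predictions: helices `a` and `b` interact
#' when any residue pair between them has a decision score above the
#' threshold (raw score 0 by default).
#'
#' @param pairs Data frame with columns `helix_i`, `helix_j` (as returned in
#'   `build_pair_features()$pairs`).
#' @param scores Numeric vector of decision scores, one per pair row.
#' @param topo A [topology()].
#' @param threshold Decision threshold, default 0.
#' @return An [interaction_graph()].
#' @export
predicted_interactions <- function(pairs, scores, topo, threshold = 0) {
  stopifnot(nrow(pairs) == length(scores))
  n <- n_helices(topo)
  hit <- scores > threshold
  if (!any(hit)) return(interaction_graph(n))
  edges <- unique(cbind(pmin(pairs$helix_i[hit], pairs$helix_j[hit]),
                        pmax(pairs$helix_i[hit], pairs$helix_j[hit])))
  interaction_graph(n, edges)
}

#' Candidate packing arrangement
#'
#' @param id Candidate identifier.
#' @param graph Its [interaction_graph()] (observed helix-interaction set).
#' @param provenance One of `"native"`, `"native_model"`, `"decoy"`,
#'   `"synthetic"`.
#' @return An object of class `arrangement_candidate`.
#' @export
arrangement_candidate <- function(id, graph,
                                  provenance = c("decoy", "native",
                                                 "native_model", "synthetic")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(graph, "interaction_graph"))
  structure(list(id = id, graph = graph, provenance = provenance),
            class = "arrangement_candidate")
}

#' Matching-count score of a candidate against predictions
#'
#' Over all `choose(n, 2)` helix pairs, the score is incremented when
#' edge presence/absence agrees between the candidate and the predicted
#' interaction graph — interacting and non-interacting pairs score equally.
#'
#' @param candidate,predicted [interaction_graph()]s on the same `n`.
#' @return Integer in `[0, choose(n, 2)]`.
#' @export
arrangement_score <- function(candidate, predicted) {
  if (candidate$n != predicted$n) {
    stop("vertex-count mismatch: ", candidate$n, " vs ", predicted$n)
  }
  n <- candidate$n
  if (n < 2L) return(0L)
  pairs <- utils::combn(n, 2)
  sum(vapply(seq_len(ncol(pairs)), function(k) {
    has_edge(candidate, pairs[1, k], pairs[2, k]) ==
      has_edge(predicted, pairs[1, k], pairs[2, k])
  }, logical(1)))
}

#' Rank candidate arrangements against predicted interactions
#'
#' Candidates are sorted by score (descending), ties by id, and the native
#' (or native-model) candidate is deemed ranked first when no decoy scores
#' strictly higher — ties count as success.
#'
#' @param candidates List of [arrangement_candidate()]s; at least one must
#'   be tagged `native` or `native_model`.
#' @param predicted The predicted [interaction_graph()].
#' @return An object of class `decoy_ranking`: list with `ranking`
#'   (data frame `id`, `provenance`, `score`) and `native_first`.
#' @export
rank_candidates <- function(candidates, predicted) {
  stopifnot(length(candidates) >= 1L)
  scores <- vapply(candidates, function(cand)
    arrangement_score(cand$graph, predicted), numeric(1))
  tab <- data.frame(
    id = vapply(candidates, function(cand) as.character(cand$id), ""),
    provenance = vapply(candidates, `[[`, "", "provenance"),
    score = scores)
  tab <- tab[order(-tab$score, tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  native <- tab$provenance %in% c("native", "native_model")
  if (!any(native)) stop("no candidate tagged native or native_model")
  best_native <- max(tab$score[native])
  best_decoy <- if (any(!native)) max(tab$score[!native]) else -Inf
  structure(list(ranking = tab, native_first = best_native >= best_decoy),
            class = "decoy_ranking")
}

#' @export
print.decoy_ranking <- function(x, ...) {
  cat("<decoy_ranking>", nrow(x$ranking), "candidates; native first:",
      x$native_first, "\n")
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' Complement of an interaction graph
#' @param graph An [interaction_graph()].
#' @return The complement graph (same vertices, complementary edge set).
#' @export
complement_graph <- function(graph) {
  n <- graph$n
  if (n < 2L) return(interaction_graph(n))
  pairs <- t(utils::combn(n, 2))
  keep <- !vapply(seq_len(nrow(pairs)), function(k)
    has_edge(graph, pairs[k, 1], pairs[k, 2]), logical(1))
  interaction_graph(n, pairs[keep, , drop = FALSE])
}
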