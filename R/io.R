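# Readers and writers for the external formats the pipeline consumes:
# FASTA, PSI-BLAST ASCII PSSM, plain-text/JSON topology, PDB coordinates,
# lipid-fraction tables, and JSON/SVG result output.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return List of [protein_record()] objects, one per header.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(lines[1], ">")) {
    stop("FASTA parse error at line 1: expected '>' header")
  }
  headers <- which(startsWith(lines, ">"))
  ids <- sub("^>\\s*", "", lines[headers])
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id '", ids[duplicated(ids)][1], "'")
  }
  bounds <- c(headers, length(lines) + 1L)
  records <- vector("list", length(headers))
  for (k in seq_along(headers)) {
    body <- lines[seq(bounds[k] + 1L, length.out = bounds[k + 1L] - bounds[k] - 1L)]
    if (length(body) == 0L) stop("record '", ids[k], "' has no sequence lines")
    records[[k]] <- protein_record(ids[k], paste(body, collapse = ""))
  }
  records
}

#' Write protein records as FASTA
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w"); on.exit(close(con))
  for (rec in records) {
    writeLines(paste0(">", rec$id), con)
    seq <- rec$sequence
    starts <- seq(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))), con)
  }
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the standard ASCII output of `psiblast -out_ascii_pssm`: header
#' lines are skipped, each residue row contributes the first 20 integer
#' score columns (the log-odds block), and the lambda/K footer is ignored.
#'
#' @param path Path to the ASCII PSSM file.
#' @param expected_length Optional sequence length; a mismatch in row count
#'   is an error.
#' @return `L x 20` numeric matrix, columns in alphabetical amino-acid order,
#'   with attribute `residues` (the residue letters of the query column).
#' @export
read_pssm <- function(path, expected_length = NULL) {
  lines <- readLines(path, warn = FALSE)
  # residue rows look like: "<idx> <aa> <20+ numbers ...>"
  row_re <- "^\\s*[0-9]+\\s+[A-Za-z]\\s+-?[0-9]"
  rows <- grep(row_re, lines)
  if (length(rows) == 0L) stop("no PSSM residue rows found in ", path)
  scores <- matrix(NA_real_, nrow = length(rows), ncol = 20)
  residues <- character(length(rows))
  for (k in seq_along(rows)) {
    tokens <- strsplit(trimws(lines[rows[k]]), "\\s+")[[1]]
    residues[k] <- tokens[2]
    vals <- suppressWarnings(as.numeric(tokens[-(1:2)]))
    if (anyNA(vals[seq_len(min(20, length(vals)))])) {
      stop("PSSM parse error: non-numeric cell in row ", k,
           " (line ", rows[k], ")")
    }
    if (length(vals) < 20L) {
      stop("PSSM parse error: row ", k, " (line ", rows[k], ") has ",
           length(vals), " score columns, expected >= 20")
    }
    scores[k, ] <- vals[1:20]
  }
  idx <- as.integer(sub("^\\s*([0-9]+).*$", "\\1", lines[rows]))
  if (any(diff(idx) != 1L)) stop("PSSM residue rows are not consecutive")
  if (!is.null(expected_length) && nrow(scores) != expected_length) {
    stop("PSSM has ", nrow(scores), " rows but sequence length is ",
         expected_length)
  }
  colnames(scores) <- AA_ALPHABET
  attr(scores, "residues") <- residues
  scores
}

#' Write a profile matrix in ASCII PSSM layout
#'
#' Round-trip companion of [read_pssm()]; used mainly for fixtures.
#'
#' @param profile `L x 20` numeric matrix.
#' @param sequence Residue letters for the query column (string or vector).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pssm <- function(profile, sequence, path) {
  if (is.character(sequence) && length(sequence) == 1L)
    sequence <- strsplit(sequence, "")[[1]]
  stopifnot(nrow(profile) == length(sequence), ncol(profile) == 20L)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("", con)
  writeLines("Last position-specific scoring matrix computed", con)
  writeLines(paste(" ", paste(sprintf("%3s", AA_ALPHABET), collapse = " ")), con)
  for (k in seq_len(nrow(profile))) {
    writeLines(paste0(sprintf("%5d %s ", k, sequence[k]),
                      paste(sprintf("%6g", profile[k, ]), collapse = " ")), con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1337     0.3176"), con)
  invisible(path)
}

#' Read a TM topology file
#'
#' Accepts either the plain-text format, one helix per line
#' (`"<helix_index> <start>-<end>"`), or a JSON file with a `helices` array
#' of `{index, start, end}` objects.
#'
#' @param path Path to topology file.
#' @param L Optional sequence length for bounds validation.
#' @return A [topology()] object (spans sorted by start).
#' @export
read_topology <- function(path, L = NULL) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) > 0L && grepl("^\\s*[\\[{]", first)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    h <- if (!is.null(obj$helices)) obj$helices else obj
    return(topology(h$start, h$end, L = L))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty topology file: ", path)
  m <- regmatches(lines, regexec("^([0-9]+)\\s+([0-9]+)\\s*-\\s*([0-9]+)$", lines))
  bad <- which(vapply(m, length, 1L) != 4L)
  if (length(bad) > 0L) {
    stop("topology parse error at line ", bad[1], ": '", lines[bad[1]], "'")
  }
  starts <- vapply(m, function(x) as.integer(x[3]), 1L)
  ends <- vapply(m, function(x) as.integer(x[4]), 1L)
  topology(starts, ends, L = L)
}

#' Write a topology file (plain-text dialect)
#' @param topo A [topology()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_topology <- function(topo, path) {
  writeLines(sprintf("%d %d-%d", topo$helix, topo$start, topo$end), path)
  invisible(path)
}

#' Read per-residue lipid-contact fractions
#'
#' Tab/space-separated table, one `"<residue_index> <fraction>"` pair per
#' line; fractions are the fraction of simulation time the residue was in
#' contact with lipid and must lie in `[0, 1]`.
#'
#' @param path Path to the table.
#' @return Named numeric vector (names are residue indices).
#' @export
read_lipid_fractions <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("residue", "fraction"))
  if (any(tab$fraction < 0 | tab$fraction > 1)) {
    stop("lipid fractions outside [0, 1] at residue ",
         tab$residue[which(tab$fraction < 0 | tab$fraction > 1)][1])
  }
  if (anyDuplicated(tab$residue)) stop("duplicate residue index in fraction table")
  stats::setNames(tab$fraction, tab$residue)
}

#' Write a lipid-fraction table
#' @param fractions Named numeric vector (names are residue indices).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lipid_fractions <- function(fractions, path) {
  writeLines(sprintf("%s\t%.6g", names(fractions), fractions), path)
  invisible(path)
}

#' Read protein coordinates from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] restricted to one chain.
#' Alternate locations are resolved to the highest-occupancy copy and
#' hydrogens are flagged so "heavy atom" selections are trivial. With
#' `renumber = TRUE` residues are renumbered sequentially from 1 in order
#' of appearance (for author numbering that does not align with the
#' sequence); the default keeps the file's residue numbers.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier (single letter). Default `"A"`.
#' @param renumber Renumber residues sequentially from 1 (default `FALSE`).
#' @return A `structure_coords` data frame with columns
#'   `residue`, `resid`, `atom`, `element`, `x`, `y`, `z`, `hydrogen`.
#' @export
read_structure <- function(path, chain = "A", renumber = FALSE) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not found in ", path)
  # resolve altlocs: keep the highest-occupancy copy of each residue/atom,
  # preserving file order
  grp <- paste(at$resno, at$insert, at$elety)
  occ <- ifelse(is.na(at$o), 1, at$o)
  best <- tapply(seq_len(nrow(at)), grp, function(ii) ii[which.max(occ[ii])])
  at <- at[sort(unname(unlist(best))), , drop = FALSE]
  reskey <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  resfac <- factor(reskey, levels = unique(reskey))
  residue <- if (renumber) as.integer(resfac) else at$resno
  elem <- at$elesy
  missing_elem <- is.na(elem) | !nzchar(elem)
  elem[missing_elem] <- substr(gsub("[0-9]", "", at$elety[missing_elem]), 1, 1)
  out <- data.frame(residue = residue,
                    resid = at$resid,
                    atom = at$elety,
                    element = toupper(elem),
                    x = at$x, y = at$y, z = at$z,
                    hydrogen = toupper(elem) %in% c("H", "D"))
  if (any(!is.finite(as.matrix(out[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path)
  }
  structure(out, class = c("structure_coords", "data.frame"))
}

#' Write structure coordinates as a minimal PDB file
#' @param coords A `structure_coords` data frame (see [read_structure()]).
#' @param path Output path.
#' @param chain Chain id to stamp on every ATOM record.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(coords, path, chain = "A") {
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_len(nrow(coords))) {
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      k, coords$atom[k], coords$resid[k], chain, coords$residue[k],
      coords$x[k], coords$y[k], coords$z[k], 1.00, 0.00, coords$element[k]), con)
  }
  writeLines("END", con)
  invisible(path)
}

RESULTS_FORMAT_VERSION <- "1.0"

#' Write prediction or arrangement results
#'
#' JSON output is deterministic and round-trippable via [read_results()];
#' arrangements can additionally be rendered as SVG (helix circles, contact
#' annotations, interaction edges).
#'
#' @param x A result object: a contact-prediction data frame
#'   (columns `i`, `j`, `score`, `label`), a [interaction_graph()], a decoy
#'   ranking, or an arrangement as returned by [select_arrangement()].
#' @param path Output path.
#' @param format `"json"` (default) or `"svg"` (arrangements only).
#' @return Invisibly, `path`.
#' @export
write_results <- function(x, path, format = c("json", "svg")) {
  format <- match.arg(format)
  if (format == "svg") {
    if (!inherits(x, "arrangement")) stop("SVG output is for arrangements only")
    writeLines(arrangement_svg(x), path)
    return(invisible(path))
  }
  payload <- list(format_version = RESULTS_FORMAT_VERSION)
  if (inherits(x, "interaction_graph")) {
    payload$type <- "interaction_graph"
    payload$n <- x$n
    payload$edges <- if (nrow(x$edges)) unname(apply(x$edges, 1, as.list)) else list()
  } else if (inherits(x, "arrangement")) {
    payload$type <- "arrangement"
    payload$permutation <- x$permutation
    payload$positions <- unname(apply(x$positions, 1, as.list))
    payload$crossovers <- as.list(x$crossovers)
    payload$rotations <- x$rotations
    payload$contact_distance <- x$contact_distance
  } else if (inherits(x, "decoy_ranking")) {
    payload$type <- "decoy_ranking"
    payload$native_first <- x$native_first
    payload$ranking <- x$ranking
  } else if (is.data.frame(x)) {
    payload$type <- "contact_predictions"
    payload$rows <- x
  } else stop("unsupported result object of class ", class(x)[1])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read results written by [write_results()]
#' @param path Path to a JSON results file.
#' @return The reconstructed result object.
#' @export
read_results <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version)) stop("missing format_version in ", path)
  switch(obj$type,
    contact_predictions = obj$rows,
    interaction_graph = {
      edges <- if (length(obj$edges)) do.call(rbind, lapply(obj$edges, unlist))
               else matrix(integer(), ncol = 2)
      interaction_graph(obj$n, edges)
    },
    decoy_ranking = structure(list(ranking = obj$ranking,
                                   native_first = obj$native_first),
                              class = "decoy_ranking"),
    arrangement = obj,
    stop("unknown result type '", obj$type, "'"))
}

# SVG rendering of a packing arrangement: one circle per helix at its layout
# position, interaction edges, residue ticks on the helical wheel.
arrangement_svg <- function(arr, wheel_radius = 2.3) {
  pos <- arr$positions
  pad <- 3 * wheel_radius + 4
  xr <- range(pos[, 1]); yr <- range(pos[, 2])
  w <- diff(xr) + 2 * pad; h <- diff(yr) + 2 * pad
  px <- function(x) 20 * (x - xr[1] + pad)
  py <- function(y) 20 * (yr[2] - y + pad)
  out <- c(sprintf(
    "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%.0f\" height=\"%.0f\">",
    20 * w, 20 * h))
  if (!is.null(arr$graph) && nrow(arr$graph$edges)) {
    for (k in seq_len(nrow(arr$graph$edges))) {
      a <- arr$graph$edges[k, 1]; b <- arr$graph$edges[k, 2]
      out <- c(out, sprintf(
        "<line x1=\"%.1f\" y1=\"%.1f\" x2=\"%.1f\" y2=\"%.1f\" stroke=\"#888\" stroke-width=\"2\"/>",
        px(pos[a, 1]), py(pos[a, 2]), px(pos[b, 1]), py(pos[b, 2])))
    }
  }
  for (v in seq_len(nrow(pos))) {
    out <- c(out, sprintf(
      "<circle cx=\"%.1f\" cy=\"%.1f\" r=\"%.1f\" fill=\"#cde\" stroke=\"#235\"/>",
      px(pos[v, 1]), py(pos[v, 2]), 20 * wheel_radius),
      sprintf("<text x=\"%.1f\" y=\"%.1f\" text-anchor=\"middle\" font-size=\"14\">H%d</text>",
              px(pos[v, 1]), py(pos[v, 2]) + 5, v))
  }
  c(out, "</svg>")
}
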