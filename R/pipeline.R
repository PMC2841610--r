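# End-to-end workflows tying the modules together: training with
# leave-one-protein-out CV, packing-arrangement construction for a single
# protein, and decoy scoring. These back the command-line interface at
# inst/cli/helixpack.R.

#' Load a training dataset directory
#'
#' Expects, per protein id: `<id>.fasta`, `<id>.pssm`, `<id>.topo`, and a
#' label source — `<id>.lipid` (fraction table) and/or `<id>.pdb`
#' (coordinates). An optional `homology.tsv` (columns id1, id2, evalue)
#' defines the exclusion table.
#'
#' @param dir Dataset directory.
#' @return List with `proteins` (per-id list of inputs) and `homology`.
#' @export
load_dataset <- function(dir) {
  fastas <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  if (length(fastas) == 0L) stop("no .fasta files in ", dir)
  proteins <- list()
  for (f in fastas) {
    id <- sub("\\.fasta$", "", basename(f))
    rec <- read_fasta(f)[[1]]
    pssm_path <- file.path(dir, paste0(id, ".pssm"))
    topo_path <- file.path(dir, paste0(id, ".topo"))
    if (!file.exists(pssm_path)) stop("missing PSSM for protein '", id, "'")
    if (!file.exists(topo_path)) stop("missing topology for protein '", id, "'")
    entry <- list(id = id, protein = rec,
                  profile = read_pssm(pssm_path, expected_length = rec$length),
                  topo = read_topology(topo_path, L = rec$length))
    lipid_path <- file.path(dir, paste0(id, ".lipid"))
    pdb_path <- file.path(dir, paste0(id, ".pdb"))
    if (file.exists(lipid_path)) entry$fractions <- read_lipid_fractions(lipid_path)
    if (file.exists(pdb_path)) entry$coords <- read_structure(pdb_path)
    proteins[[id]] <- entry
  }
  hom_path <- file.path(dir, "homology.tsv")
  homology <- if (file.exists(hom_path)) {
    homology_table(names(proteins),
                   utils::read.table(hom_path, header = TRUE))
  } else NULL
  list(proteins = proteins, homology = homology)
}

#' Train and cross-validate the lipid-exposure classifier
#'
#' @param dataset Output of [load_dataset()] (every protein needs
#'   `fractions`).
#' @param params An [svm_params()] (reference lipid optima by default).
#' @param config A [feature_config()].
#' @param seed Integer seed.
#' @return List with `cv` (from [loo_cv()]), `model` (trained on the full
#'   set) and per-protein `scores` (out-of-fold raw SVM scores, used as
#'   contact features).
#' @export
train_lipid_classifier <- function(dataset, params = svm_params(),
                                   config = feature_config(), seed = 1L) {
  prot <- dataset$proteins
  ds <- lapply(prot, function(p) {
    if (is.null(p$fractions)) stop("missing lipid fractions for '", p$id, "'")
    feats <- build_lipid_features(p$protein, p$profile, p$topo, config)
    labels <- label_lipid_exposed(p$fractions, p$topo)
    list(id = p$id, features = feats, labels = unname(labels))
  })
  cv <- loo_cv(ds, params, homology = dataset$homology, seed = seed)
  # out-of-fold scores per protein, for downstream pair features
  ids <- names(prot)
  scores <- list()
  for (k in seq_along(ds)) {
    excl <- fold_exclusions(dataset$homology, ids[k], ids)
    tr <- which(!ids %in% excl)
    tr_x <- do.call(rbind, lapply(ds[tr], `[[`, "features"))
    tr_y <- unlist(lapply(ds[tr], `[[`, "labels"))
    norm <- fit_apply_zscore(tr_x, test = ds[[k]]$features)
    model <- train_svm(norm$train, tr_y, params)
    scores[[ids[k]]] <- stats::setNames(predict_scores(model, norm$test),
                                        rownames(ds[[k]]$features))
  }
  all_x <- do.call(rbind, lapply(ds, `[[`, "features"))
  all_y <- unlist(lapply(ds, `[[`, "labels"))
  norm <- fit_apply_zscore(all_x)
  full <- train_svm(norm$train, all_y, params, norm_stats = norm$stats,
                    config = config)
  list(cv = cv, model = full, scores = scores)
}

#' Train and cross-validate the residue-contact classifier
#'
#' @param dataset Output of [load_dataset()] (every protein needs `coords`).
#' @param lipid_scores Per-protein named score vectors (e.g. the `scores`
#'   element of [train_lipid_classifier()]).
#' @param definition A [contact_definition()].
#' @param params An [svm_params()] ([contact_svm_params()] by default).
#' @param config A [feature_config()].
#' @param seed Integer seed (threads the balancing subsample).
#' @return List with `cv`, `model` and the per-protein pair tables.
#' @export
train_contact_classifier <- function(dataset, lipid_scores,
                                     definition = contact_definition(),
                                     params = contact_svm_params(),
                                     config = feature_config(), seed = 1L) {
  prot <- dataset$proteins
  ds <- lapply(prot, function(p) {
    if (is.null(p$coords)) stop("missing coordinates for '", p$id, "'")
    pf <- build_pair_features(p$protein, p$profile, lipid_scores[[p$id]],
                              p$topo, config)
    truth <- residue_contacts(p$coords, p$topo, definition, p$protein)
    key <- paste(pf$pairs$i, pf$pairs$j)
    labels <- key %in% paste(truth$i, truth$j)
    list(id = p$id, features = pf$features, labels = labels, pairs = pf$pairs)
  })
  cv <- loo_cv(ds, params, homology = dataset$homology, balance = TRUE,
               seed = seed)
  all_x <- do.call(rbind, lapply(ds, `[[`, "features"))
  all_y <- unlist(lapply(ds, `[[`, "labels"))
  bal <- balance_training(all_x, all_y, seed = seed)
  pars <- params; pars$cost_factor <- bal$cost_factor
  norm <- fit_apply_zscore(bal$features)
  full <- train_svm(norm$train, bal$labels, pars, norm_stats = norm$stats,
                    config = config)
  list(cv = cv, model = full, dataset = ds)
}

#' Predict lipid-exposure scores for one protein
#'
#' @param model A `trained_svm` from [train_lipid_classifier()] (carries its
#'   normalization statistics and feature configuration).
#' @param protein A [protein_record()].
#' @param profile `L x 20` profile matrix.
#' @param topo A [topology()].
#' @return Named numeric vector of raw decision scores over TM residues;
#'   `score > 0` predicts lipid exposed.
#' @export
predict_lipid_exposure <- function(model, protein, profile, topo) {
  config <- if (is.null(model$config)) feature_config() else model$config
  feats <- build_lipid_features(protein, profile, topo, config)
  if (is.null(model$norm_stats)) stop("model carries no normalization statistics")
  stats::setNames(predict_scores(model, apply_zscore(feats, model$norm_stats)),
                  rownames(feats))
}

#' Predict residue contacts and helix interactions for one protein
#'
#' Runs the two-classifier cascade: lipid scores feed the pair features,
#' the contact SVM scores every inter-helix pair, and the interaction
#' graph collects helix pairs with at least one positive score.
#'
#' @param lipid_model,contact_model `trained_svm` models with stored
#'   normalization statistics.
#' @param protein A [protein_record()].
#' @param profile `L x 20` profile matrix.
#' @param topo A [topology()].
#' @return List with `pairs` (data frame `i`, `j`, `helix_i`, `helix_j`,
#'   `score`, `label`), `interactions` (an [interaction_graph()]) and
#'   `contacts` (predicted [contact_set()]).
#' @export
predict_contacts <- function(lipid_model, contact_model, protein, profile,
                             topo) {
  lipid_scores <- predict_lipid_exposure(lipid_model, protein, profile, topo)
  config <- if (is.null(contact_model$config)) feature_config()
            else contact_model$config
  pf <- build_pair_features(protein, profile, lipid_scores, topo, config)
  sc <- predict_scores(contact_model,
                       apply_zscore(pf$features, contact_model$norm_stats))
  pairs <- cbind(pf$pairs, score = sc, label = sc > 0)
  graph <- predicted_interactions(pf$pairs, sc, topo)
  contacts <- if (any(sc > 0)) {
    contact_set(pf$pairs$i[sc > 0], pf$pairs$j[sc > 0], topo)
  } else empty_contact_set(topo)
  list(pairs = pairs, interactions = graph, contacts = contacts)
}

#' Construct the packing arrangement for one protein
#'
#' Runs the pipeline tail: (predicted or supplied) helix-helix interactions
#' -> Kamada-Kawai layout -> crossover-ranked arrangements -> GA-optimized
#' rotations.
#'
#' @param topo A [topology()].
#' @param interactions An [interaction_graph()]: predicted from sequence,
#'   observed from a structure, or supplied from experimental sources.
#' @param contacts Optional [contact_set()] of (predicted) residue contacts
#'   driving rotation optimization.
#' @param params A [layout_params()].
#' @param ga A [ga_config()].
#' @param seed Integer seed.
#' @return Ranked list of arrangements (see [select_arrangement()]).
#' @export
run_pack <- function(topo, interactions, contacts = NULL,
                     params = layout_params(), ga = ga_config(), seed = 1L) {
  stopifnot(inherits(interactions, "interaction_graph"))
  if (interactions$n != n_helices(topo)) {
    stop("interaction graph has ", interactions$n, " helices, topology has ",
         n_helices(topo))
  }
  select_arrangement(interactions, topo, contacts, params = params, ga = ga,
                     seed = seed)
}

#' Score candidate arrangements against predictions
#'
#' @param candidates List of [arrangement_candidate()]s (one tagged native
#'   or native_model).
#' @param predicted The predicted [interaction_graph()].
#' @return A `decoy_ranking` (see [rank_candidates()]).
#' @export
run_score_decoys <- function(candidates, predicted) {
  rank_candidates(candidates, predicted)
}

#' Write a synthetic fixture dataset to disk
#'
#' Generates `n_proteins` idealized bundles with planted profiles and
#' writes them in the directory layout [load_dataset()] reads
#' (FASTA + PSSM + topology + lipid fractions + PDB coordinates +
#' homology table).
#'
#' @param dir Output directory (created if needed).
#' @param n_proteins Number of proteins.
#' @param n_helices Helices per protein (recycled).
#' @param signal_strength Planted-signal strength (see [make_profiles()]).
#' @param seed Integer seed.
#' @return Invisibly, the vector of protein ids.
#' @export
make_fixture_dataset <- function(dir, n_proteins = 10L, n_helices = 2L,
                                 signal_strength = 4, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_helices <- rep_len(n_helices, n_proteins)
  ids <- character(n_proteins)
  for (k in seq_len(n_proteins)) {
    spec <- bundle_spec(n_helices[k], seed = seed + k)
    bundle <- make_bundle(spec)
    prof <- make_profiles(bundle, signal_strength = signal_strength,
                          seed = seed + 1000L + k)
    id <- sprintf("prot%03d", k)
    ids[k] <- id
    bundle$protein$id <- id
    write_fasta(list(bundle$protein), file.path(dir, paste0(id, ".fasta")))
    write_pssm(prof$profile, bundle$protein$sequence,
               file.path(dir, paste0(id, ".pssm")))
    write_topology(bundle$topo, file.path(dir, paste0(id, ".topo")))
    write_lipid_fractions(prof$fractions, file.path(dir, paste0(id, ".lipid")))
    write_structure(bundle$coords, file.path(dir, paste0(id, ".pdb")))
  }
  invisible(ids)
}
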