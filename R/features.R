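# SVM feature engineering: windowed profile features, Z-score normalization
# fitted on training data only, sequence-separation encoding and relative
# helix positions for the residue-pair classifier.

#' Feature configuration
#'
#' @param window Odd sliding-window width (residues), default 7.
#' @param separation_bins Ascending sequence-separation boundaries; an
#'   overflow bin for separations beyond the last boundary is implicit.
#' @param profile_width Number of profile columns per residue (20).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(window = 7L,
                           separation_bins = c(50L, 75L, 100L, 125L, 150L,
                                               175L, 200L),
                           profile_width = 20L) {
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L,
            all(diff(separation_bins) > 0), profile_width >= 1L)
  structure(list(window = window,
                 separation_bins = as.integer(separation_bins),
                 profile_width = as.integer(profile_width)),
            class = "feature_config")
}

#' Sliding profile window centred on a residue
#'
#' Concatenates the profile rows `center - w/2 ... center + w/2`; positions
#' beyond either terminus contribute exact-zero blocks.
#'
#' @param profile `L x 20` profile matrix.
#' @param center 1-based residue index.
#' @param window Odd window width.
#' @return Numeric vector of length `window * ncol(profile)`.
#' @export
profile_window <- function(profile, center, window = 7L) {
  L <- nrow(profile); p <- ncol(profile)
  if (center < 1L || center > L) stop("window center ", center, " outside 1..", L)
  half <- window %/% 2L
  out <- numeric(window * p)
  for (o in seq_len(window)) {
    pos <- center - half + o - 1L
    if (pos >= 1L && pos <= L) out[((o - 1L) * p + 1L):(o * p)] <- profile[pos, ]
  }
  out
}

#' Fit a Z-score normalization on training data and apply it
#'
#' Per-column mean and (population) standard deviation are estimated on the
#' training matrix only; every supplied matrix is transformed with those
#' statistics. Constant columns map to zero.
#'
#' @param train Training feature matrix (rows = examples).
#' @param ... Further matrices to transform with the training statistics.
#' @return List with `train`, one transformed matrix per extra argument
#'   (named as supplied, or `other1`, `other2`, ...), and `stats`
#'   (list with `mean`, `sd`).
#' @export
fit_apply_zscore <- function(train, ...) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("empty training matrix")
  mu <- colMeans(train)
  sdv <- sqrt(colMeans(sweep(train, 2, mu)^2))
  apply_one <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) != length(mu)) stop("column count mismatch with fitted stats")
    z <- sweep(m, 2, mu)
    z <- sweep(z, 2, ifelse(sdv > 0, sdv, 1), "/")
    z[, sdv == 0] <- 0
    z
  }
  others <- list(...)
  out <- list(train = apply_one(train))
  if (length(others) > 0L) {
    nm <- names(others)
    if (is.null(nm)) nm <- rep("", length(others))
    nm[nm == ""] <- paste0("other", seq_len(sum(nm == "")))
    out[nm] <- lapply(others, apply_one)
  }
  out$stats <- list(mean = mu, sd = sdv)
  out
}

#' Apply previously fitted Z-score statistics
#' @param m Feature matrix.
#' @param stats List with `mean` and `sd` (from [fit_apply_zscore()]).
#' @return Transformed matrix.
#' @export
apply_zscore <- function(m, stats) {
  m <- as.matrix(m)
  if (ncol(m) != length(stats$mean)) stop("column count mismatch with fitted stats")
  z <- sweep(m, 2, stats$mean)
  z <- sweep(z, 2, ifelse(stats$sd > 0, stats$sd, 1), "/")
  z[, stats$sd == 0] <- 0
  z
}

#' One-hot sequence-separation encoding
#'
#' Bins the residue separation `d = |i - j|` into the boundaries
#' 50, 75, 100, 125, 150, 175, 200 plus an overflow bin for `d > 200`,
#' inclusive on the left: `d <= 50` sets bit 1, `50 < d <= 75` bit 2, and so
#' on. Exactly one bit is set.
#'
#' @param d Residue separation, `d >= 1`.
#' @param bins Ascending boundaries (default per [feature_config()]).
#' @return Binary vector of length `length(bins) + 1`.
#' @export
separation_encoding <- function(d, bins = feature_config()$separation_bins) {
  if (d < 1) stop("separation must be >= 1")
  out <- numeric(length(bins) + 1L)
  k <- which(d <= bins)
  out[if (length(k) > 0L) k[1] else length(out)] <- 1
  out
}

#' Relative positions of a residue pair within their TM helices
#'
#' Each residue's relative position ("relative Z coordinate") is its 1-based
#' position within the helix divided by the helix length, so the first
#' residue of a 20-residue helix scores 1/20. When the flip condition holds
#' (the helix index difference is odd, i.e. the helices run antiparallel),
#' the second residue's value is complemented as `1 - (pos - start)/length`
#' so residues at the same membrane depth get comparable values and both
#' outputs stay in `(0, 1]`.
#'
#' @param pos_i,pos_j Residue positions (1-based, within their spans).
#' @param helix_i,helix_j Rows of a [topology()] (`start`, `end`, `helix`).
#' @return Numeric vector `c(z_i, z_j)`.
#' @export
relative_position_pair <- function(pos_i, helix_i, pos_j, helix_j) {
  z_for <- function(pos, h) {
    len <- h$end - h$start + 1L
    if (pos < h$start || pos > h$end) {
      stop("residue ", pos, " outside helix span ", h$start, "-", h$end)
    }
    (pos - h$start + 1) / len
  }
  z_i <- z_for(pos_i, helix_i)
  z_j <- z_for(pos_j, helix_j)
  if ((abs(helix_j$helix - helix_i$helix) %% 2L) == 1L) {
    len_j <- helix_j$end - helix_j$start + 1L
    z_j <- 1 - (pos_j - helix_j$start) / len_j
  }
  c(z_i, z_j)
}

#' Lipid-exposure feature matrix
#'
#' One row per TM residue: the length-140 (at defaults) profile window
#' centred on the residue.
#'
#' @param protein A [protein_record()].
#' @param profile `L x 20` profile matrix.
#' @param topo A [topology()].
#' @param config A [feature_config()].
#' @return Matrix `(number of TM residues) x (window * 20)` with rownames
#'   the residue indices.
#' @export
build_lipid_features <- function(protein, profile, topo,
                                 config = feature_config()) {
  if (nrow(profile) != protein$length) {
    stop("profile has ", nrow(profile), " rows but sequence length is ",
         protein$length)
  }
  tm <- tm_residues(topo)
  if (length(tm) == 0L) stop("topology contains no TM helices")
  if (max(tm) > protein$length) stop("helix span exceeds sequence length")
  feats <- t(vapply(tm, function(r) profile_window(profile, r, config$window),
                    numeric(config$window * ncol(profile))))
  rownames(feats) <- tm
  feats
}

#' Residue-pair feature matrix for contact prediction
#'
#' Enumerates every residue pair on different TM helices (`i < j`) and
#' assembles, per pair: the two profile windows (280 values at defaults),
#' the raw lipid-exposure SVM score of each residue, the one-hot
#' sequence-separation encoding (8 bins) and the two relative helix
#' positions — 292 features at defaults.
#'
#' @param protein A [protein_record()].
#' @param profile `L x 20` profile matrix.
#' @param lipid_scores Named numeric vector of raw lipid SVM scores covering
#'   all TM residues (names are residue indices).
#' @param topo A [topology()].
#' @param config A [feature_config()].
#' @return List with `features` (matrix) and `pairs` (data frame `i`, `j`,
#'   `helix_i`, `helix_j`).
#' @export
build_pair_features <- function(protein, profile, lipid_scores, topo,
                                config = feature_config()) {
  if (nrow(profile) != protein$length) {
    stop("profile has ", nrow(profile), " rows but sequence length is ",
         protein$length)
  }
  tm <- tm_residues(topo)
  hx <- helix_of(topo, tm)
  missing <- setdiff(as.character(tm), names(lipid_scores))
  if (length(missing) > 0L) {
    stop("missing lipid score for residue(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  idx <- which(outer(hx, hx, "!=") & upper.tri(matrix(0, length(tm), length(tm))),
               arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no inter-helix residue pairs in topology")
  wins <- t(vapply(tm, function(r) profile_window(profile, r, config$window),
                   numeric(config$window * ncol(profile))))
  nbin <- length(config$separation_bins) + 1L
  nfeat <- 2L * ncol(wins) + 2L + nbin + 2L
  feats <- matrix(0, nrow = nrow(idx), ncol = nfeat)
  pairs <- data.frame(i = tm[idx[, 1]], j = tm[idx[, 2]],
                      helix_i = hx[idx[, 1]], helix_j = hx[idx[, 2]])
  for (k in seq_len(nrow(idx))) {
    a <- idx[k, 1]; b <- idx[k, 2]
    z <- relative_position_pair(tm[a], topo[hx[a], ], tm[b], topo[hx[b], ])
    feats[k, ] <- c(wins[a, ], wins[b, ],
                    lipid_scores[[as.character(tm[a])]],
                    lipid_scores[[as.character(tm[b])]],
                    separation_encoding(abs(tm[a] - tm[b]),
                                        config$separation_bins),
                    z)
  }
  list(features = feats, pairs = pairs)
}
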