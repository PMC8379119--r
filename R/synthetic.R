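#' Default synthetic study configuration
#'
#' Bundles everything the synthetic pipeline needs: a guide tree along which
#' true spectra drift, a strictly positive root spectrum, a drift rate, a
#' predictor noise channel, per-organism protein counts and the size of the
#' disjoint reference sample used to estimate the predictor's confusion
#' matrix.
#'
#' The default guide tree has six organisms arranged as three cherries
#' `((orgA,orgB),(orgC,orgD)),(orgE,orgF)` whose merge heights are separated
#' by roughly a factor of five (cherry heights 0.0425/0.05/0.0575, inner
#' join 0.25, root 1.25, all pairwise path lengths distinct). The separation
#' is what makes the tree identifiable from 7-class composition vectors: the
#' drift leaves only ~7 informative coordinates per organism, so realized
#' distances fluctuate by tens of percent, and successive merge heights must
#' differ by several fold for UPGMA to recover the topology reliably. A
#' deeper, more finely resolved tree (e.g. ten organisms shaped like the
#' model-eukaryote phylogeny, see [eukaryote_guide_tree()]) is *not*
#' reliably recoverable at these sample sizes — a real limitation of
#' comparing organisms through 7-dimensional spectra, documented in the
#' methods vignette.
#'
#' @param seed Master integer seed; all stages derive independent streams
#'   from it.
#' @param n_proteins Proteins sampled per organism (default 20000).
#' @param n_reference Size of the disjoint reference sample used to estimate
#'   the confusion matrix (default 5000).
#' @param guide_tree Rooted ultrametric `phylo` tree with branch lengths.
#' @param root_spectrum Strictly positive `location_spectrum` at the root.
#' @param drift_rate Standard deviation of the per-coordinate log-ratio
#'   increment per unit branch length (default 0.6).
#' @param channel Row-stochastic predictor channel matrix (`channel_matrix()`);
#'   default drawn with diagonal reliability 0.7–0.9.
#' @param scheme A `location_scheme` (default [seven_class_scheme()]).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_proteins = 20000,
                              n_reference = 5000,
                              guide_tree = default_guide_tree(),
                              root_spectrum = default_root_spectrum(),
                              drift_rate = 0.6,
                              channel = NULL,
                              scheme = seven_class_scheme()) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(inherits(guide_tree, "phylo"),
            inherits(root_spectrum, "location_spectrum"),
            inherits(scheme, "location_scheme"))
  if (!is.finite(drift_rate) || drift_rate < 0)
    stop("drift_rate must be finite and >= 0", call. = FALSE)
  if (n_proteins < 1 || n_reference < 1)
    stop("n_proteins and n_reference must be >= 1", call. = FALSE)
  if (is.null(channel))
    channel <- random_channel(length(scheme$classes),
                              seed = derive_seed(seed, "channel"))
  validate_channel(channel, length(scheme$classes))
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 n_reference = as.integer(n_reference),
                 guide_tree = guide_tree, root_spectrum = root_spectrum,
                 drift_rate = drift_rate, channel = channel, scheme = scheme),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_guide_tree <- function() {
  ape::read.tree(text = paste0(
    "(((orgA:0.0425,orgB:0.0425):0.2075,(orgC:0.05,orgD:0.05):0.2):1.0,",
    "(orgE:0.0575,orgF:0.0575):1.1925);"))
}

#' @rdname simulation_config
#' @details `eukaryote_guide_tree()` returns a ten-leaf tree shaped like the
#'   accepted phylogeny of ten model eukaryotes (three primates, two rodents,
#'   two insects, a nematode, two yeasts); useful for demonstrations, but see
#'   the identifiability caveat above.
#' @export
eukaryote_guide_tree <- function() {
  ape::read.tree(text = paste0(
    "(((((H.sapiens:0.02,P.troglodytes:0.02):0.04,G.gorilla:0.06):0.12,",
    "(M.musculus:0.025,R.norvegicus:0.025):0.155):0.36,",
    "((D.melanogaster:0.055,A.gambiae:0.055):0.115,C.elegans:0.17):0.37):1.06,",
    "(S.cerevisiae:0.21,S.pombe:0.21):1.39);"))
}

#' @rdname simulation_config
#' @details `default_root_spectrum()` is a moderately even seven-class
#'   eukaryote-like composition (12% secreted, 24% nuclear, 22% cytoplasmic,
#'   14% plasma membrane, 10% mitochondrial, 10% ER, 8% Golgi).
#' @export
default_root_spectrum <- function(scheme = seven_class_scheme()) {
  location_spectrum(c(.12, .24, .22, .14, .10, .10, .08), scheme,
                    organism_id = "root")
}

#' Random predictor channel
#'
#' Row-stochastic matrix `q(o, p)`: the probability that the predictor
#' outputs class `p` when the true class is `o`. Each diagonal entry is
#' drawn uniformly from `diag_range` and the remaining mass is spread evenly
#' over the off-diagonal classes.
#'
#' @param n_classes Number of classes.
#' @param diag_range Range of the per-class correct-prediction probability.
#' @param seed Integer seed.
#' @return An `n_classes` x `n_classes` row-stochastic matrix.
#' @export
random_channel <- function(n_classes, diag_range = c(0.7, 0.9), seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  with_seed(seed, {
    q <- matrix(0, n_classes, n_classes)
    for (o in seq_len(n_classes)) {
      d <- stats::runif(1, diag_range[1L], diag_range[2L])
      q[o, ] <- (1 - d) / (n_classes - 1)
      q[o, o] <- d
    }
    q
  })
}

validate_channel <- function(q, k) {
  if (!is.matrix(q) || nrow(q) != k || ncol(q) != k)
    stop("channel must be a ", k, "x", k, " matrix", call. = FALSE)
  if (any(q < 0) || any(abs(rowSums(q) - 1) > 1e-9))
    stop("channel rows must be non-negative and sum to 1", call. = FALSE)
  invisible(q)
}

#' Evolve location spectra along a guide tree
#'
#' True spectra drift along the tree in log-ratio coordinates: starting from
#' `log` of the root composition, each branch adds independent Gaussian
#' increments with per-coordinate standard deviation
#' `drift_rate * branch_length`, and leaf states are mapped back to the
#' simplex by normalized exponentials (softmax). Shared branches therefore
#' produce correlated spectra, and expected spectrum distance grows with
#' path length on the tree.
#'
#' @param cfg A `simulation_config` (root spectrum must be strictly
#'   positive).
#' @return Named list of true `location_spectrum`s, one per leaf
#'   (`n_proteins = NA`).
#' @export
evolve_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  root <- unname(cfg$root_spectrum$values)
  if (any(root <= 0))
    stop("root spectrum must be strictly positive", call. = FALSE)
  tree <- stats::reorder(cfg$guide_tree)
  k <- length(root)
  n_tip <- length(tree$tip.label)
  state <- matrix(NA_real_, n_tip + tree$Nnode, k)
  state[n_tip + 1L, ] <- log(root)
  with_seed(derive_seed(cfg$seed, "evolve"), {
    for (i in seq_len(nrow(tree$edge))) {
      a <- tree$edge[i, 1L]; b <- tree$edge[i, 2L]
      state[b, ] <- state[a, ] +
        stats::rnorm(k, 0, cfg$drift_rate * tree$edge.length[i])
    }
  })
  out <- lapply(seq_len(n_tip), function(i) {
    e <- exp(state[i, ] - max(state[i, ]))
    location_spectrum(e / sum(e), cfg$scheme,
                      organism_id = tree$tip.label[i])
  })
  stats::setNames(out, tree$tip.label)
}

#' Sample a proteome of true single locations
#'
#' Draws `n` proteins i.i.d. from a spectrum; the empirical composition
#' converges to the spectrum as `n` grows.
#'
#' @param spectrum A `location_spectrum`.
#' @param n Number of proteins.
#' @param seed Integer seed.
#' @param source Source string for the records (default `"truth"`).
#' @param id_prefix Prefix for generated protein ids (default the organism
#'   id).
#' @return A single-label `annotation_table`.
#' @export
sample_proteome <- function(spectrum, n, seed, source = "truth",
                            id_prefix = spectrum$organism_id) {
  stopifnot(inherits(spectrum, "location_spectrum"), n >= 1)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  labels <- with_seed(seed, {
    sample(spectrum$classes, n, replace = TRUE, prob = spectrum$values)
  })
  annotation_table(sprintf("%s_p%06d", id_prefix, seq_len(n)),
                   labels, source = source)
}

#' Corrupt true locations through a predictor channel
#'
#' Each protein's predicted label is drawn from the channel row of its true
#' class, independently across proteins — the forward model whose estimated
#' confusion matrix feeds the spectrum correction.
#'
#' @param truth Single-label `annotation_table` of true locations.
#' @param channel Row-stochastic channel matrix over `scheme` classes.
#' @param scheme The `location_scheme` the labels live in.
#' @param seed Integer seed.
#' @param source Source string for the predicted records.
#' @return A single-label `annotation_table` of predictions (same proteins,
#'   same order).
#' @export
corrupt_predictions <- function(truth, channel, scheme, seed,
                                source = "predictor") {
  stopifnot(inherits(truth, "annotation_table"),
            inherits(scheme, "location_scheme"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (any(lengths(truth$labels) != 1L))
    stop("truth must be single-label", call. = FALSE)
  k <- length(scheme$classes)
  validate_channel(channel, k)
  true_idx <- match(unlist(truth$labels), scheme$classes)
  if (anyNA(true_idx))
    stop("truth labels outside the scheme", call. = FALSE)
  pred <- character(length(true_idx))
  with_seed(seed, {
    for (o in seq_len(k)) {
      at <- which(true_idx == o)
      if (length(at))
        pred[at] <- sample(scheme$classes, length(at), replace = TRUE,
                           prob = channel[o, ])
    }
  })
  annotation_table(truth$protein_id, pred, source = source)
}

#' Error-free multi-location annotation tables with known D
#'
#' Generates the scenario behind the analytic agreement model: every protein
#' occupies `k` equally frequent location slots, each slot's class drawn
#' independently and uniformly from the `n_classes` classes, and each of two
#' error-free annotation tables records just ONE uniformly chosen slot,
#' independently. Two picks of the same slot always agree (probability
#' `1/k`); picks of different slots agree exactly when the two slots drew
#' the same class (probability `1/L`) — which is precisely the chance-match
#' term of the analytic model, so the apparent any-match agreement converges
#' to [analytic_agreement()] as `n` grows. (Drawing `k` *distinct* classes
#' per protein instead would make differing picks never match and the
#' agreement collapse to `1/D`, contradicting the analytic arithmetic.)
#' For fractional `D`, a fraction `D - floor(D)` of proteins gets
#' `ceiling(D)` slots and the rest `floor(D)` (so the mean is `D`).
#'
#' @param n Number of proteins.
#' @param mean_locations_D Mean number of native location slots per protein
#'   (`>= 1`, `ceiling(D) <= n_classes`).
#' @param n_classes Number of location classes (labelled `loc01`,
#'   `loc02`, ...).
#' @param seed Integer seed.
#' @return A list with single-label `annotation_table`s `a` and `b`, the
#'   multi-label `truth` table (the distinct classes per protein), and
#'   `n_slots`, the integer slot count per protein.
#' @export
generate_multilabel_tables <- function(n, mean_locations_D, n_classes, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  D <- mean_locations_D
  stopifnot(n >= 1, D >= 1, n_classes >= 2)
  if (ceiling(D) > n_classes)
    stop("ceiling(D) exceeds the number of classes", call. = FALSE)
  classes <- sprintf("loc%02d", seq_len(n_classes))
  ids <- sprintf("p%06d", seq_len(n))
  with_seed(seed, {
    k <- rep.int(floor(D), n)
    frac <- D - floor(D)
    if (frac > 0)
      k[stats::runif(n) < frac] <- ceiling(D)
    # slot classes iid uniform (with replacement; see Details)
    slots <- lapply(k, function(ki)
      classes[sample.int(n_classes, ki, replace = TRUE)])
    pick <- function() vapply(slots, function(s)
      if (length(s) == 1L) s else s[sample.int(length(s), 1L)], "")
    a <- pick(); b <- pick()
    list(a = annotation_table(ids, a, source = "setA"),
         b = annotation_table(ids, b, source = "setB"),
         truth = annotation_table(ids, lapply(slots, unique),
                                  source = "truth"),
         n_slots = k)
  })
}

#' Alignment-hit tables with planted family structure
#'
#' Builds a protein universe partitioned into families and emits pairwise
#' alignment hits such that all within-family pairs lie strictly above the
#' HVAL clustering threshold and all background (between-family) pairs lie
#' at or below it — ground truth for cluster-recovery tests.
#'
#' @param family_sizes Integer vector of family sizes (size-1 families give
#'   singletons with no hits).
#' @param n_background_pairs Number of random between-family hit pairs.
#' @param seed Integer seed.
#' @param pid_range,len_range Ranges for the within-family percent identity
#'   and alignment length; the worst corner must stay above `threshold`.
#' @param threshold HVAL threshold the planted structure is separated at
#'   (default 4).
#' @return A list: `hits` (data frame), `universe` (character), `truth`
#'   (`family_assignment` with the smallest member as seed).
#' @export
generate_hit_table <- function(family_sizes, n_background_pairs = 0, seed,
                               pid_range = c(40, 90), len_range = c(100, 400),
                               threshold = 4) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  family_sizes <- as.integer(family_sizes)
  stopifnot(length(family_sizes) >= 1L, all(family_sizes >= 1L))
  if (hval(len_range[1L], pid_range[1L]) <= threshold)
    stop("pid/len ranges allow within-family HVAL <= threshold (",
         format(hval(len_range[1L], pid_range[1L])), ")", call. = FALSE)
  fam_ids <- sprintf("F%02d", seq_along(family_sizes))
  members <- lapply(seq_along(family_sizes), function(i)
    sprintf("%s_m%02d", fam_ids[i], seq_len(family_sizes[i])))
  universe <- unlist(members)
  fam_of <- rep(seq_along(family_sizes), family_sizes)
  with_seed(seed, {
    q <- character(); t <- character(); pid <- numeric(); len <- integer()
    for (m in members) {
      if (length(m) < 2L) next
      pr <- utils::combn(m, 2L)
      npair <- ncol(pr)
      q <- c(q, pr[1L, ]); t <- c(t, pr[2L, ])
      pid <- c(pid, stats::runif(npair, pid_range[1L], pid_range[2L]))
      len <- c(len, sample(seq(len_range[1L], len_range[2L]), npair,
                           replace = TRUE))
    }
    if (n_background_pairs > 0) {
      if (length(unique(fam_of)) < 2L)
        stop("background pairs need at least two families", call. = FALSE)
      got <- 0L
      while (got < n_background_pairs) {
        i <- sample.int(length(universe), 1L)
        j <- sample.int(length(universe), 1L)
        if (fam_of[i] == fam_of[j]) next
        L <- sample(seq(len_range[1L], len_range[2L]), 1L)
        # background PID at or below the curve + threshold
        pmax_bg <- min(hssp_curve(L) + threshold, 100)
        q <- c(q, universe[i]); t <- c(t, universe[j])
        pid <- c(pid, stats::runif(1, 0, pmax_bg))
        len <- c(len, L)
        got <- got + 1L
      }
    }
    evalue <- 10^stats::runif(length(q), -30, -1)
    truth <- structure(
      list(families = lapply(members, function(m)
        list(seed = min(m), members = sort(m))),
        threshold = threshold),
      class = "family_assignment")
    list(hits = alignment_hits(q, t, pid, len, evalue),
         universe = universe, truth = truth)
  })
}
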