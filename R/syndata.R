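#' Synthetic dataset generator specification
#'
#' Describes an imbalanced two-class compound set with sparse binary
#' feature blocks and a handful of class-informative bits. The defaults
#' emulate the baseline cholestasis study conditions at quarter scale:
#' 172 negative / 53 positive compounds (about 3.3:1), four blocks whose
#' background set-bit rates match the observed fingerprint coverages, and
#' informative features with the presence-rate gaps seen among the
#' top-ranked descriptors (0.69/0.47, 0.55/0.33, 0.40/0.22, 0.21/0.08
#' positive/negative rates).
#'
#' @param n_pos,n_neg class sizes.
#' @param blocks list of `list(block, n_features, background_rate)`.
#' @param informative list of `list(block, rate_pos, rate_neg, count)`;
#'   informative features occupy the first columns of their block.
#' @param seed integer seed.
#' @export
generator_spec <- function(n_pos = 53L, n_neg = 172L,
                           blocks = list(
                             list(block = "target", n_features = 270L, background_rate = 0.009),
                             list(block = "pathway", n_features = 512L, background_rate = 0.114),
                             list(block = "substructure", n_features = 220L, background_rate = 0.145),
                             list(block = "transporter", n_features = 9L, background_rate = 0.070)),
                           informative = list(
                             list(block = "pathway", rate_pos = 0.69, rate_neg = 0.47, count = 1L),
                             list(block = "pathway", rate_pos = 0.55, rate_neg = 0.33, count = 1L),
                             list(block = "target", rate_pos = 0.40, rate_neg = 0.22, count = 1L),
                             list(block = "target", rate_pos = 0.21, rate_neg = 0.08, count = 1L)),
                           seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) stop_config("both classes need >= 1 compound")
  rates <- c(unlist(lapply(blocks, `[[`, "background_rate")),
             unlist(lapply(informative, `[[`, "rate_pos")),
             unlist(lapply(informative, `[[`, "rate_neg")))
  if (any(rates < 0 | rates > 1)) stop_config("rates must lie in [0, 1]")
  for (b in blocks)
    if (sum(vapply(informative,
                   function(i) if (identical(i$block, b$block)) i$count else 0L,
                   numeric(1))) > b$n_features)
      stop_config("more informative features than block width in ", b$block)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 blocks = blocks, informative = informative,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a labeled synthetic fingerprint dataset
#'
#' Every bit is drawn independently Bernoulli with its feature's
#' class-conditional rate (informative features) or block background rate.
#' Fully reproducible under the spec seed. Feature columns are
#' block-qualified (e.g. `pathway:pw_001`); informative columns are the
#' first of their block and are listed in the `informative` attribute of
#' the result for recovery tests.
#'
#' @param spec a [generator_spec()].
#' @return a [labeled_dataset()]; negatives first (`neg_001`, ...), then
#'   positives (`pos_001`, ...).
#' @export
make_binary_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_neg + spec$n_pos
  y <- c(rep(0L, spec$n_neg), rep(1L, spec$n_pos))
  ids <- c(sprintf("neg_%03d", seq_len(spec$n_neg)),
           sprintf("pos_%03d", seq_len(spec$n_pos)))
  info_rows <- list()
  abbr <- c(target = "tg", pathway = "pw", substructure = "sb", transporter = "tr")
  cols <- lapply(spec$blocks, function(b) {
    inf <- Filter(function(i) identical(i$block, b$block), spec$informative)
    rate_pos <- rate_neg <- rep(b$background_rate, b$n_features)
    idx <- 0L
    for (i in inf) {
      take <- idx + seq_len(i$count)
      rate_pos[take] <- i$rate_pos
      rate_neg[take] <- i$rate_neg
      idx <- idx + i$count
    }
    m <- matrix(0L, n, b$n_features)
    for (j in seq_len(b$n_features)) {
      r <- ifelse(y == 1L, rate_pos[j], rate_neg[j])
      m[, j] <- stats::rbinom(n, 1L, r)
    }
    colnames(m) <- sprintf("%s:%s_%03d", b$block, abbr[[b$block]],
                           seq_len(b$n_features))
    if (idx > 0L)
      info_rows[[b$block]] <<- data.frame(
        feature_id = colnames(m)[seq_len(idx)],
        rate_pos = rate_pos[seq_len(idx)], rate_neg = rate_neg[seq_len(idx)],
        stringsAsFactors = FALSE)
    m
  })
  x <- do.call(cbind, cols)
  rownames(x) <- ids
  d <- labeled_dataset(x, y, sprintf("syndata seed=%d", spec$seed))
  attr(d, "informative") <- do.call(rbind, unname(info_rows))
  d
}

#' Generate activity records with a known binarization
#'
#' Random compound-target bioactivity records, deliberately including
#' duplicate (compound, target) pairs with differing pChEMBL values so the
#' max-aggregation rule is exercised. The expected binary matrix is
#' computed independently at generation time (plain loop over pairs) for
#' oracle testing of [binarize_activities()].
#'
#' @param n_compounds,n_targets universe sizes.
#' @param density fraction of (compound, target) pairs with records.
#' @param pchembl_range range of generated pChEMBL values.
#' @param seed integer seed.
#' @param threshold activity cutoff used for the expected matrix.
#' @return list with `records` (data.frame) and `expected`
#'   ([binary_matrix]).
#' @export
make_activity_records <- function(n_compounds = 20L, n_targets = 12L,
                                  density = 0.3, pchembl_range = c(3.5, 8),
                                  seed = 1L, threshold = 5.0) {
  if (density <= 0 || density > 1) stop_config("density must be in (0, 1]")
  set.seed(as.integer(seed))
  compounds <- sprintf("c%03d", seq_len(n_compounds))
  targets <- sprintf("T%03d", seq_len(n_targets))
  pairs <- expand.grid(compound_id = compounds, target_id = targets,
                       stringsAsFactors = FALSE)
  pairs <- pairs[stats::runif(nrow(pairs)) < density, , drop = FALSE]
  if (nrow(pairs) == 0L) pairs <- data.frame(compound_id = compounds[1],
                                             target_id = targets[1])
  n_rec <- sample(1:3, nrow(pairs), replace = TRUE)
  records <- pairs[rep(seq_len(nrow(pairs)), n_rec), , drop = FALSE]
  records$pchembl <- round(stats::runif(nrow(records), pchembl_range[1],
                                        pchembl_range[2]), 2)
  records$standard_type <- sample(STANDARD_TYPES, nrow(records), replace = TRUE)
  rownames(records) <- NULL
  # independent expected-matrix computation: explicit loop over pairs
  seen_c <- unique(records$compound_id)
  seen_t <- unique(records$target_id)
  expected <- matrix(0L, length(seen_c), length(seen_t),
                     dimnames = list(seen_c, seen_t))
  for (ci in seen_c) for (ti in seen_t) {
    v <- records$pchembl[records$compound_id == ci & records$target_id == ti]
    if (length(v) && max(v) >= threshold) expected[ci, ti] <- 1L
  }
  list(records = records, expected = binary_matrix(expected, block = "target"))
}

#' Generate a toy interactome/pathway fixture
#'
#' Small random maps - targets with random first-degree interactors,
#' proteins assigned to random pathways, a random liver-expressed pathway
#' subset - plus a random compound-target matrix and the brute-force
#' expected pathway matrix (computed per compound per pathway by direct
#' set checks) for oracle testing of [derive_pathway_matrix()].
#'
#' @param n_targets,n_interactors,n_pathways map sizes.
#' @param n_compounds rows of the generated target matrix.
#' @param density set-bit rate of the target matrix.
#' @param liver_fraction fraction of pathways marked liver-expressed.
#' @param seed integer seed.
#' @return list with `target_matrix`, `interactome`, `membership`,
#'   `filter`, `expected`.
#' @export
make_interactome_fixture <- function(n_targets = 5L, n_interactors = 6L,
                                     n_pathways = 4L, n_compounds = 10L,
                                     density = 0.35, liver_fraction = 0.75,
                                     seed = 1L) {
  stopifnot(n_targets >= 1L, n_interactors >= 1L, n_pathways >= 1L)
  set.seed(as.integer(seed))
  targets <- sprintf("T%02d", seq_len(n_targets))
  interactors <- sprintf("I%02d", seq_len(n_interactors))
  pathways <- sprintf("P%02d", seq_len(n_pathways))
  im <- lapply(stats::setNames(targets, targets), function(t)
    interactors[stats::runif(n_interactors) < 0.4])
  im <- Filter(length, im)
  prots <- c(targets, interactors)
  pm <- lapply(stats::setNames(prots, prots), function(p)
    pathways[stats::runif(n_pathways) < 0.5])
  pm <- Filter(length, pm)
  liver <- sort(sample(pathways, max(1L, round(liver_fraction * n_pathways))))
  f <- expression_filter(liver_genes = targets, liver_pathways = liver)
  bits <- matrix(stats::rbinom(n_compounds * n_targets, 1L, density),
                 n_compounds, n_targets,
                 dimnames = list(sprintf("c%02d", seq_len(n_compounds)), targets))
  tm <- binary_matrix(bits, block = "target")
  expected <- matrix(0L, n_compounds, length(liver),
                     dimnames = list(rownames(bits), liver))
  for (i in seq_len(n_compounds)) {
    active <- targets[bits[i, ] == 1L]
    prot_set <- active
    for (t in active) if (!is.null(im[[t]])) prot_set <- c(prot_set, im[[t]])
    for (p in liver) {
      hit <- FALSE
      for (pr in unique(prot_set))
        if (!is.null(pm[[pr]]) && p %in% pm[[pr]]) { hit <- TRUE; break }
      if (hit) expected[i, p] <- 1L
    }
  }
  list(target_matrix = tm, interactome = im, membership = pm, filter = f,
       expected = binary_matrix(expected, block = "pathway"))
}

TRANSPORTERS <- c("BCRP", "BSEP", "MATE1", "MDR1", "MRP3",
                  "OATP1B1", "OATP1B3", "OCT1", "OCT2")

#' Generate per-algorithm transporter votes
#'
#' Uniform random binary votes for the nine hepatic transporters, five
#' algorithms each (LR, RF, kNN, SVR, XGB) except OATP1B1 which lacks SVR.
#' The expected >= 3-vote consensus matrix is computed during generation
#' for oracle testing of [transporter_consensus()].
#'
#' @param n_compounds number of compounds.
#' @param seed integer seed.
#' @param p_active per-vote activity rate, default 0.5.
#' @return list with `votes` (a [transporter_vote_table()]) and `expected`
#'   ([binary_matrix]).
#' @export
make_transporter_votes <- function(n_compounds = 15L, seed = 1L,
                                   p_active = 0.5) {
  stopifnot(n_compounds >= 1L)
  set.seed(as.integer(seed))
  compounds <- sprintf("c%03d", seq_len(n_compounds))
  algos <- c("LR", "RF", "kNN", "SVR", "XGB")
  rows <- list()
  expected <- matrix(0L, n_compounds, length(TRANSPORTERS),
                     dimnames = list(compounds, TRANSPORTERS))
  for (ci in compounds) for (tr in TRANSPORTERS) {
    a <- if (tr == "OATP1B1") setdiff(algos, "SVR") else algos
    v <- stats::rbinom(length(a), 1L, p_active)
    rows[[paste(ci, tr)]] <- data.frame(compound_id = ci, transporter = tr,
                                        algorithm = a, prediction = v,
                                        stringsAsFactors = FALSE)
    if (sum(v) >= 3L) expected[ci, tr] <- 1L
  }
  list(votes = transporter_vote_table(do.call(rbind, c(rows, make.row.names = FALSE))),
       expected = binary_matrix(expected, block = "transporter"))
}
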