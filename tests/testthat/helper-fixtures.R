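# shared fixture builders; everything is generated in code

# minimal labeled dataset with given class sizes and i.i.d. Bernoulli bits
tiny_dataset <- function(n_neg, n_pos, n_features = 10, rate = 0.3, seed = 1) {
  set.seed(seed)
  n <- n_neg + n_pos
  x <- matrix(rbinom(n * n_features, 1, rate), n, n_features)
  rownames(x) <- sprintf("c%04d", seq_len(n))
  colnames(x) <- sprintf("f%03d", seq_len(n_features))
  labeled_dataset(x, c(rep(0, n_neg), rep(1, n_pos)))
}

# a binary matrix from explicit rows
bm <- function(..., block = "target") {
  rows <- list(...)
  m <- do.call(rbind, rows)
  binary_matrix(m, block = block)
}

# small activity record table
recs <- function(compound, target, pchembl, standard_type = "IC50") {
  data.frame(compound_id = compound, target_id = target, pchembl = pchembl,
             standard_type = standard_type, stringsAsFactors = FALSE)
}

fast_gb <- function(seed = 1) {
  learner_spec("gradient_boosting", list(nrounds = 20L, max_depth = 3L),
               seed = seed)
}

fast_rf <- function(seed = 1) {
  learner_spec("random_forest", list(num.trees = 100L), seed = seed)
}
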