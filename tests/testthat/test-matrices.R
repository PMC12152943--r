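test_that("binarize_activities applies max aggregation and the inclusive >=5 rule", {
  m <- binarize_activities(recs(c("c1", "c1"), c("t1", "t1"), c(4.2, 5.7),
                                c("IC50", "Ki")))
  expect_equal(unname(as.matrix(m)["c1", "t1"]), 1L)
  expect_equal(unname(as.matrix(binarize_activities(
    recs("c1", "t1", 5.0, "Ki")))["c1", "t1"]), 1L)
  expect_equal(unname(as.matrix(binarize_activities(
    recs("c1", "t1", 4.99)))["c1", "t1"]), 0L)
  # pair with no record stays 0
  m2 <- binarize_activities(recs(c("c1", "c2"), c("t1", "t2"), c(6, 6)))
  expect_equal(unname(as.matrix(m2)["c1", "t2"]), 0L)
  expect_equal(matrix_block(m2), "target")
})

test_that("binarize_activities is idempotent under record duplication", {
  set.seed(11)
  for (i in 1:10) {
    r <- make_activity_records(n_compounds = 8, n_targets = 6, density = 0.4,
                               seed = i)$records
    dup <- rbind(r, r[sample(nrow(r), 3), ])
    expect_identical(as.matrix(binarize_activities(r)),
                     as.matrix(binarize_activities(dup)))
  }
})

test_that("binarize_activities rejects non-finite pChEMBL naming the row", {
  bad <- recs(c("c1", "c2"), c("t1", "t2"), c(6, NaN))
  expect_error(binarize_activities(bad), "non-finite.*c2", class = "cholecon_schema_error")
})

test_that("tissue filter restricts columns, keeps rows, warns on empty filter", {
  m <- bm(c1 = c(t1 = 1, t2 = 0), c2 = c(0, 1))
  f <- expression_filter(liver_genes = "t1")
  out <- filter_targets_by_tissue(m, f)
  expect_equal(colnames(out), "t1")
  expect_equal(rownames(out), c("c1", "c2"))  # all-zero row c2 retained
  expect_identical(as.matrix(filter_targets_by_tissue(
    m, expression_filter(liver_genes = c("t1", "t2", "t9")))), as.matrix(m))
  expect_warning(empty <- filter_targets_by_tissue(m, expression_filter()),
                 "removed every")
  expect_equal(ncol(empty), 0L)
})

test_that("merge_predicted_targets implements +all / +2-C / +3-C semantics", {
  known <- bm(c1 = c(t1 = 1))
  tool <- function(tg) bm(c1 = stats::setNames(1L, tg))
  tools <- list(tool("t2"), tool("t2"), tool("t3"))
  feat_on <- function(m) sort(colnames(m)[as.matrix(m)["c1", ] == 1])
  expect_equal(feat_on(merge_predicted_targets(known, tools, 2)), c("t1", "t2"))
  expect_equal(feat_on(merge_predicted_targets(known, tools, 1)),
               c("t1", "t2", "t3"))
  expect_equal(feat_on(merge_predicted_targets(known, tools, 3)), "t1")
  expect_error(merge_predicted_targets(known, tools, 4),
               class = "cholecon_config_error")
})

test_that("merge_predicted_targets is monotone in min_tools and ORs at 1", {
  set.seed(3)
  mk <- function(seed) {
    set.seed(seed)
    binary_matrix(matrix(rbinom(30, 1, 0.4), 5, 6,
                         dimnames = list(paste0("c", 1:5), paste0("t", 1:6))),
                  block = "target")
  }
  known <- mk(1); tools <- lapply(2:4, mk)
  counts <- sapply(1:3, function(k)
    sum(merge_predicted_targets(known, tools, k)))
  expect_true(all(diff(counts) <= 0))
  or_all <- Reduce(`|`, lapply(c(list(known), tools), as.matrix)) * 1L
  expect_equal(unname(as.matrix(merge_predicted_targets(known, tools, 1))),
               unname(or_all))
})

test_that("pathway expansion matches the hand-traced toy", {
  m <- bm(c1 = c(T1 = 1))
  im <- list(T1 = "I1")
  pm <- list(T1 = "P1", I1 = "P2")
  f <- expression_filter(liver_pathways = c("P1", "P2"))
  out <- derive_pathway_matrix(m, im, pm, f)
  expect_equal(as.matrix(out)["c1", c("P1", "P2")], c(P1 = 1L, P2 = 1L))
  # pathway filter drops P1
  out2 <- derive_pathway_matrix(m, im, pm, expression_filter(liver_pathways = "P2"))
  expect_equal(colnames(out2), "P2")
  expect_equal(unname(as.matrix(out2)["c1", "P2"]), 1L)
  # empty interactome: direct-target pathways only
  out3 <- derive_pathway_matrix(m, list(), pm, f)
  expect_equal(as.matrix(out3)["c1", ], c(P1 = 1L, P2 = 0L))
  # interactor-only mode drops the direct target's own pathway
  out4 <- derive_pathway_matrix(m, im, pm, f, include_direct = FALSE)
  expect_equal(as.matrix(out4)["c1", ], c(P1 = 0L, P2 = 1L))
})

test_that("pathway expansion agrees with the brute-force oracle on random toys", {
  for (s in 1:25) {
    fx <- make_interactome_fixture(n_targets = 5, n_interactors = 6,
                                   n_pathways = 4, n_compounds = 8, seed = s)
    got <- derive_pathway_matrix(fx$target_matrix, fx$interactome,
                                 fx$membership, fx$filter)
    expect_identical(as.matrix(got), as.matrix(fx$expected))
  }
})

test_that("transporter consensus needs >= 3 active votes, also for 4-vote lists", {
  df <- rbind(
    data.frame(compound_id = "c1", transporter = "BSEP",
               algorithm = c("LR", "RF", "kNN", "SVR", "XGB"),
               prediction = c(1, 1, 1, 0, 0)),
    data.frame(compound_id = "c1", transporter = "MDR1",
               algorithm = c("LR", "RF", "kNN", "SVR", "XGB"),
               prediction = c(1, 1, 0, 0, 0)),
    data.frame(compound_id = "c1", transporter = "OATP1B1",
               algorithm = c("LR", "RF", "kNN", "XGB"),
               prediction = c(1, 1, 1, 0)))
  out <- transporter_consensus(transporter_vote_table(df))
  expect_equal(as.matrix(out)["c1", ], c(BSEP = 1L, MDR1 = 0L, OATP1B1 = 1L))
})

test_that("transporter consensus errors on a compound/transporter with no votes", {
  df <- data.frame(compound_id = c("c1", "c1", "c2"),
                   transporter = c("BSEP", "MDR1", "BSEP"),
                   algorithm = "LR", prediction = 1)
  expect_error(transporter_consensus(transporter_vote_table(df)),
               "c2.*MDR1|MDR1.*c2", class = "cholecon_schema_error")
})

test_that("concat_blocks inner-joins compounds and preserves bits", {
  a <- bm(c1 = c(t1 = 1, t2 = 0), c2 = c(1, 1), c3 = c(0, 0), block = "target")
  b <- bm(c1 = c(p1 = 1), c2 = c(0), block = "pathway")
  expect_message(out <- concat_blocks(list(a, b)), "dropped")
  expect_equal(rownames(out), c("c1", "c2"))
  expect_equal(colnames(out), c("target:t1", "target:t2", "pathway:p1"))
  expect_equal(matrix_block(out), "combined")
  # set-bit count preserved on surviving compounds
  expect_equal(sum(out), sum(as.matrix(a)[c("c1", "c2"), ]) + sum(as.matrix(b)))
  # single block is identity up to feature qualification
  one <- concat_blocks(list(a))
  expect_equal(unname(as.matrix(one)), unname(as.matrix(a)))
  # disjoint compound sets
  d <- bm(z9 = c(p1 = 1), block = "pathway")
  expect_error(concat_blocks(list(a, d)), class = "cholecon_schema_error")
})

test_that("unique_across matches a brute-force all-pairs row comparison", {
  brute <- function(ms) {
    ids <- rownames(ms[[1]])
    keep <- logical(length(ids))
    for (i in seq_along(ids)) {
      dup <- FALSE
      for (m in ms) for (j in seq_along(ids)) if (j != i &&
          all(as.matrix(m)[i, ] == as.matrix(m)[j, ])) dup <- TRUE
      keep[i] <- !dup
    }
    ids[keep]
  }
  for (s in 1:10) {
    set.seed(s)
    mk <- function(block, nf) binary_matrix(
      matrix(rbinom(12 * nf, 1, 0.3), 12, nf,
             dimnames = list(paste0("c", 1:12), paste0(block, 1:nf))),
      block = block)
    ms <- list(mk("target", 3), mk("pathway", 4), mk("substructure", 5))
    expect_equal(unique_across(ms[[1]], ms[[2]], ms[[3]]), brute(ms))
  }
})

test_that("a duplicate in any single fingerprint space disqualifies", {
  tg <- bm(c1 = c(t1 = 1, t2 = 0), c2 = c(0, 1), c3 = c(1, 1), c4 = c(0, 0))
  pw <- bm(c1 = c(p1 = 1, p2 = 1), c2 = c(1, 1), c3 = c(0, 1), c4 = c(1, 0),
           block = "pathway")
  sb <- bm(c1 = c(s1 = 1, s2 = 0), c2 = c(0, 0), c3 = c(1, 1), c4 = c(0, 1),
           block = "substructure")
  # c1/c2 share a pathway row although their target and substructure rows
  # are distinct: both are excluded
  expect_equal(unique_across(tg, pw, sb), c("c3", "c4"))
})

test_that("coverage is bitcount over matrix size, with degenerate errors", {
  set.seed(2)
  m <- binary_matrix(matrix(rbinom(40, 1, 0.25), 8, 5,
                            dimnames = list(paste0("c", 1:8), paste0("t", 1:5))))
  expect_equal(coverage(m), sum(as.matrix(m)) / 40)
  zero <- binary_matrix(matrix(0L, 3, 4, dimnames = list(letters[1:3], LETTERS[1:4])))
  expect_equal(coverage(zero), 0)
  nocol <- suppressWarnings(filter_targets_by_tissue(m, expression_filter()))
  expect_error(coverage(nocol), class = "cholecon_schema_error")
})

test_that("binary matrix CSV round-trip is lossless", {
  set.seed(5)
  m <- binary_matrix(matrix(rbinom(30, 1, 0.4), 6, 5,
                            dimnames = list(paste0("c", 1:6), paste0("f", 1:5))),
                     block = "substructure")
  path <- withr::local_tempfile(fileext = ".csv")
  write_binary_matrix(m, path)
  back <- read_binary_matrix(path, block = "substructure")
  expect_identical(as.matrix(back), as.matrix(m))
  expect_equal(matrix_block(back), "substructure")
})
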