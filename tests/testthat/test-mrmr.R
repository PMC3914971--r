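test_that("discretization applies the mean +/- alpha*sd rule per probe", {
  m <- cna_matrix(matrix(c(0, 0, 10,
                           2, 2, 2,
                           1, 2, 3), nrow = 3,
                         dimnames = list(NULL, c("skewed", "flat", "linear"))),
                  c("ACA", "ACA", "SCC"))
  dx <- discretize_cna(m, alpha = 1)
  # hand-computed: mean 10/3, sample sd 5.7735 -> only 10 crosses the upper cut
  expect_identical(unname(dx$states[, "skewed"]), c(0L, 0L, 1L))
  # zero-variance probe maps entirely to state 0
  expect_identical(unname(dx$states[, "flat"]), c(0L, 0L, 0L))
  # (1,2,3): mean 2, sd 1 -> all within [1, 3] closed? boundaries are strict
  expect_identical(unname(dx$states[, "linear"]), c(0L, 0L, 0L))
  # huge alpha flattens everything
  dx2 <- discretize_cna(m, alpha = 100)
  expect_true(all(dx2$states == 0L))
  expect_error(discretize_cna(m, alpha = 0), "alpha")
})

test_that("mutual information matches hand and brute-force computations", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_error(mutual_information(1:3, 1:4), "length mismatch")

  # joint counts [[2,1],[1,2]] over n = 6: direct summation of the four cells
  x <- c(0, 0, 0, 1, 1, 1)
  y <- c(0, 0, 1, 0, 1, 1)
  pj <- c(2, 1, 1, 2) / 6
  px <- c(0.5, 0.5)
  expected <- sum(pj * log2(pj / c(px[1] * px[1], px[1] * px[2],
                                   px[2] * px[1], px[2] * px[2])))
  expect_equal(mutual_information(x, y), expected)
})

test_that("MI is symmetric, non-negative, and I(x,x) is the entropy", {
  set.seed(1)
  for (rep in 1:20) {
    x <- sample(c(-1L, 0L, 1L), 30, replace = TRUE)
    y <- sample(c(-1L, 0L, 1L), 30, replace = TRUE)
    expect_equal(mutual_information(x, y), mutual_information(y, x))
    expect_gte(mutual_information(x, y), 0)
    p <- table(x) / length(x)
    expect_equal(mutual_information(x, x), -sum(p * log2(p)))
  }
})

test_that("MaxRel sorts by relevance with stable ties and zero-variance floor", {
  out <- small_cohort(seed = 6, effect_size = 3, penetrance = 1)
  dx <- discretize_cna(out$matrix)
  ranked <- max_rel_rank(dx, top_n = ncol(out$matrix$values))
  # agrees with per-probe MI computed independently
  lab <- out$matrix$labels
  rel <- vapply(seq_len(ncol(dx$states)),
                function(j) mutual_information(dx$states[, j], lab), 0)
  names(rel) <- colnames(dx$states)
  expect_equal(unname(rel[ranked$probe_id]), ranked$score)
  expect_true(all(diff(ranked$score) <= 0))
  # planted parents outrank every pure-noise probe
  planted <- unique(c(out$truth$informative, unlist(out$truth$partners)))
  worst_parent <- max(match(out$truth$informative, ranked$probe_id))
  first_null <- min(match(setdiff(ranked$probe_id, planted),
                          ranked$probe_id))
  expect_lt(worst_parent, first_null)

  # identical columns tie and keep input order, adjacent ranks
  v <- out$matrix$values[, 1:6]
  v[, 4] <- v[, 2]
  colnames(v) <- paste0("q", 1:6)
  dup <- discretize_cna(cna_matrix(v, lab))
  r2 <- max_rel_rank(dup, top_n = 6)
  pos2 <- match("q2", r2$probe_id)
  expect_identical(r2$probe_id[pos2 + 1L], "q4")

  # zero-variance probe gets relevance 0 and sinks below informative probes
  v[, 6] <- 2
  dz <- discretize_cna(cna_matrix(v, lab))
  r3 <- max_rel_rank(dz, top_n = 6)
  expect_equal(r3$score[match("q6", r3$probe_id)], 0)
  expect_true(match("q6", r3$probe_id) >
                max(match(r3$probe_id[r3$score > 0], r3$probe_id)))

  expect_equal(nrow(max_rel_rank(dx, top_n = 1)), 1L)
  expect_error(max_rel_rank(discretize_cna(
    cna_matrix(v, rep("ACA", length(lab)))), top_n = 2), "both classes")
})

test_that("mRMR matches the brute-force greedy oracle on small instances", {
  for (cfg in list(list(seed = 1, p = 8), list(seed = 2, p = 12),
                   list(seed = 3, p = 20))) {
    out <- small_cohort(seed = cfg$seed, p_total = cfg$p,
                        n_informative = 2L, block_size = 1L)
    dx <- discretize_cna(out$matrix)
    got <- mrmr_rank(dx, top_n = cfg$p)
    expected <- brute_mrmr_oracle(dx$states, out$matrix$labels, cfg$p)
    expect_same_ranking(got, expected)
    # quotient form agrees with its oracle too
    got_q <- mrmr_rank(dx, top_n = cfg$p, criterion = "quotient")
    expected_q <- brute_mrmr_oracle(dx$states, out$matrix$labels, cfg$p,
                                    criterion = "quotient")
    expect_same_ranking(got_q, expected_q)
  }
})

test_that("mRMR round 1 equals MaxRel's top probe and output has no duplicates", {
  out <- small_cohort(seed = 8)
  dx <- discretize_cna(out$matrix)
  mr <- mrmr_rank(dx, top_n = 50)
  mx <- max_rel_rank(dx, top_n = 50)
  expect_identical(mr$probe_id[1L], mx$probe_id[1L])
  expect_false(anyDuplicated(mr$probe_id) > 0)
  expect_identical(mr$rank, seq_len(50L))
  expect_warning(mrmr_rank(dx, top_n = 10000), "truncating")
})

test_that("exact-clone partners tie on relevance, parents win, clones defer", {
  # jitter 0 makes partners exact copies: relevance ties are broken by input
  # order (parent first) and redundancy pushes clones far down the mRMR list
  out <- small_cohort(seed = 10, n_pos = 40L, n_neg = 30L, p_total = 60L,
                      n_informative = 3L, block_size = 2L, jitter_sd = 0,
                      effect_size = 2.5)
  dx <- discretize_cna(out$matrix)
  mx <- max_rel_rank(dx, top_n = 60)
  mr <- mrmr_rank(dx, top_n = 60)
  for (parent in names(out$truth$partners)) {
    partners <- out$truth$partners[[parent]]
    expect_equal(mx$score[match(partners, mx$probe_id)],
                 rep(mx$score[match(parent, mx$probe_id)], length(partners)))
    expect_lt(match(parent, mr$probe_id),
              min(match(partners, mr$probe_id)))
    # clones are deferred relative to their MaxRel positions
    expect_gt(min(match(partners, mr$probe_id)),
              min(match(partners, mx$probe_id)))
  }
})

test_that("ranking files round-trip", {
  out <- small_cohort(seed = 1)
  r <- mrmr_rank(discretize_cna(out$matrix), top_n = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ranking(r, f)
  back <- read_ranking(f)
  expect_identical(back$probe_id, r$probe_id)
  expect_equal(back$score, r$score)
})
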