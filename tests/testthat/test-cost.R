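test_that("sad, mad and ssd match hand-computed examples and basic identities", {
  a <- c(3, 1, 0, 2); b <- c(1, 1, 2, 2)
  expect_equal(sad(a, b), 4)
  expect_equal(mad_score(a, b), 2)
  expect_equal(sad(a, a), 0)
  expect_equal(mad_score(a, a), 0)
  expect_equal(sad(a, b), sad(b, a))
  expect_equal(ssd_tail(a, b, 1:4), 0)
  expect_equal(ssd_tail(c(0, 0, 1, 1, 1, 1, 1), rep(2, 7), 3:7), -5)
  expect_error(sad(a, c(1, 2)), "identical bin edges")
})

test_that("mad <= sad and sad >= |ssd| on random histograms", {
  set.seed(21)
  for (i in 1:50) {
    a <- rpois(10, 4); b <- rpois(10, 4)
    expect_lte(mad_score(a, b), sad(a, b))
    expect_gte(sad(a, b), abs(sum(a - b)))
  }
})

test_that("combined_centile handles domination and matches a brute-force scan", {
  # a row dominated in every column passes at the column minima
  m <- rbind(c(1, 1, 1), c(2, 2, 2))
  expect_equal(combined_centile(m)$centile, 0)
  # brute-force oracle over the integer percentile grid
  brute <- function(sm) {
    for (q in 0:100) {
      cuts <- apply(sm, 2, quantile, probs = q / 100, type = 7)
      pass <- apply(sm, 1, function(r) all(r <= cuts + 1e-12))
      if (2 * sum(pass) >= nrow(sm)) return(q)
    }
    100
  }
  set.seed(31)
  for (i in 1:60) {
    sm <- matrix(runif(20 * 15), 20, 15)
    expect_identical(combined_centile(sm)$centile, brute(sm))
  }
  # anti-aligned columns force a high centile: with rows strong in some
  # scores and weak in others, only a high global percentile lets half
  # the rows pass all columns simultaneously
  sm2 <- cbind(c(1, 2, 3, 4, 5, 6), c(6, 5, 4, 3, 2, 1))
  expect_identical(combined_centile(sm2)$centile, brute(sm2))
  expect_gt(combined_centile(sm2)$centile, 50)
})

test_that("a score table can demand the 90th centile before half its rows pass", {
  # 11 pairings x 15 scores: one uniformly strong row, five rows that
  # are strong except for a single 90th-percentile score each, and five
  # weak rows that each top at least one score. The per-column 56th
  # centile passes only one row; only at the 90th do half pass all 15
  # scores simultaneously. (With fewer pairings the type-7 percentile
  # grid cannot isolate 90 exactly.)
  M <- matrix(0, 11, 15)
  for (j in 1:15) {
    ranks <- integer(11)
    bad <- 7:11
    mx <- bad[(j - 1) %% 5 + 1]
    if (j <= 5) {
      ten_row <- 1 + j
      good <- setdiff(1:6, ten_row)
      ranks[1] <- 1
      ranks[good[-1]] <- 2:5
      ranks[ten_row] <- 10
      ranks[mx] <- 11
      ranks[setdiff(bad, mx)] <- c(6, 7, 8, 9)
    } else {
      ranks[1:6] <- ((j + 0:5) %% 6) + 1
      ranks[mx] <- 11
      ranks[setdiff(bad, mx)] <- 7:10
    }
    M[, j] <- ranks
  }
  brute_pass <- function(sm, q) {
    cuts <- apply(sm, 2, quantile, probs = q / 100, type = 7)
    sum(apply(sm, 1, function(r) all(r <= cuts + 1e-12)))
  }
  cc <- combined_centile(M)
  expect_identical(brute_pass(M, 56), 1L)
  expect_identical(brute_pass(M, 89), 1L)
  expect_identical(brute_pass(M, 90), 6L)
  expect_identical(cc$centile, 90L)
})

test_that("envelope scores are zero inside the band and count excesses", {
  set.seed(8)
  reals <- lapply(1:4, function(i) random_hist())
  tail_idx <- amplitude_tail_cutoffs(reals[[1L]])
  norm <- score_normalization(reals, tail_idx)
  norm[] <- 1
  # a histogram inside the band everywhere scores all zeros
  M <- sapply(reals, function(h) as.vector(h$counts))
  inside <- hist_from_counts(matrix(round(rowMeans(M)),
                                    nrow(reals[[1]]$counts)))
  # clip to the band to guarantee containment
  lo <- matrix(apply(M, 1, min), nrow(inside$counts))
  hi <- matrix(apply(M, 1, max), nrow(inside$counts))
  inside$counts <- pmin(pmax(inside$counts, lo), hi)
  expect_true(all(envelope_scores(inside, reals, tail_idx, norm) == 0))
  # exceeding the max by 2 counts in one bin gives SAD = MAD = 2 in the
  # views containing that bin
  above <- inside
  above$counts[3, 2] <- hi[3, 2] + 2
  es <- envelope_scores(above, reals, tail_idx, norm)
  expect_equal(unname(es["env_sad_joint"]), 2)
  expect_equal(unname(es["env_mad_joint"]), 2)
  # amplitude-marginal view: deviation relative to the marginal band
  margs <- sapply(reals, function(h) rowSums(h$counts))
  mv <- rowSums(above$counts)
  expect_equal(unname(es["env_sad_amp_all"]),
               sum(pmax(mv - apply(margs, 1, max), 0) +
                     pmax(apply(margs, 1, min) - mv, 0)))
})

test_that("worst-real envelope baseline is the leave-one-out maximum", {
  set.seed(9)
  reals <- lapply(1:4, function(i) random_hist())
  tail_idx <- amplitude_tail_cutoffs(reals[[1L]])
  norm <- score_normalization(reals, tail_idx)
  base <- worst_real_envelope(reals, tail_idx, norm)
  per <- sapply(seq_along(reals), function(i)
    envelope_scores(reals[[i]], reals[-i], tail_idx, norm))
  expect_equal(base, apply(per, 1, max))
})

test_that("verdict logic separates best, acceptable and rejected fits", {
  set.seed(12)
  reals <- lapply(1:4, function(i) random_hist(8, 3, 5))
  ref <- reals[[4L]]
  tail_idx <- amplitude_tail_cutoffs(ref)
  norm <- score_normalization(reals, tail_idx)
  rows <- list()
  for (i in 1:3) for (j in (i + 1):4)
    rows[[length(rows) + 1L]] <- score_vector15(reals[[i]], reals[[j]],
                                                tail_idx, norm)
  cutoffs <- cutoffs_at_centile(do.call(rbind, rows), 90)
  # identical to the reference and inside the envelope: cost 0, best
  cb <- evaluate_cost(ref, ref, reals, cutoffs)
  expect_equal(cb$total_cost, 0)
  expect_identical(cb$verdict, "best_possible")
  # single amplitude SAD pushed beyond its cutoff: rejected, cost > 0
  off <- ref
  bump <- ceiling(cutoffs$cutoffs[["sad_amp_all"]] * norm[["amp_all"]]) + 2
  off$counts[1, 1] <- off$counts[1, 1] + bump
  cb2 <- evaluate_cost(off, ref, reals, cutoffs)
  expect_identical(cb2$verdict, "rejected")
  expect_gt(cb2$total_cost, 0)
  # rise-time-only violation with amplitude criteria intact: acceptable
  # (zero scores against impossible rise cutoffs fail the all-34 check
  # but not the amplitude-only one)
  cut3 <- cutoffs
  cut3$cutoffs[c("sad_rise_all", "mad_rise_all", "sad_joint",
                 "mad_joint")] <- -1
  cb3 <- evaluate_cost(ref, ref, reals, cut3)
  expect_identical(cb3$verdict, "acceptable")
  expect_gt(cb3$total_cost, 0)
})

test_that("total cost is monotone: worsening any score never lowers it", {
  set.seed(14)
  reals <- lapply(1:4, function(i) random_hist(8, 3, 5))
  ref <- reals[[4L]]
  tail_idx <- amplitude_tail_cutoffs(ref)
  norm <- score_normalization(reals, tail_idx)
  rows <- list()
  for (i in 1:3) for (j in (i + 1):4)
    rows[[length(rows) + 1L]] <- score_vector15(reals[[i]], reals[[j]],
                                                tail_idx, norm)
  cutoffs <- cutoffs_at_centile(do.call(rbind, rows), 50)
  sim <- random_hist(8, 3, 5)
  c0 <- evaluate_cost(sim, ref, reals, cutoffs)$total_cost
  # worsening only scores (not improving any): perturb bins below the
  # top-50% amplitude tail, where SSDs are untouched, away from the
  # reference
  low <- seq_len(tail_idx[["top50"]] - 1L)
  for (k in 1:10) {
    worse <- sim
    i <- sample(low, 1); j <- sample(3, 1)
    away <- if (worse$counts[i, j] >= ref$counts[i, j]) k * 3 else
      -min(worse$counts[i, j], k * 3)
    worse$counts[i, j] <- worse$counts[i, j] + away
    if (abs(worse$counts[i, j] - ref$counts[i, j]) <
        abs(sim$counts[i, j] - ref$counts[i, j])) next
    c1 <- evaluate_cost(worse, ref, reals, cutoffs)$total_cost
    expect_gte(c1, c0 - 1e-12)
  }
})
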