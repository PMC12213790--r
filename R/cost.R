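#' Sum of absolute deviations between two binned distributions
#'
#' @param a,b Numeric count vectors (or [event_histogram2d()] objects)
#'   on identical bin edges.
#' @return `sum(|a - b|)`.
#' @export
sad <- function(a, b) {
  ab <- score_pair(a, b)
  sum(abs(ab$a - ab$b))
}

#' Maximal absolute deviation between two binned distributions
#' @inheritParams sad
#' @return `max(|a - b|)`.
#' @export
mad_score <- function(a, b) {
  ab <- score_pair(a, b)
  if (length(ab$a) == 0L) return(0)
  max(abs(ab$a - ab$b))
}

#' Sum of signed deviations over a high-amplitude tail
#'
#' Constrains the low-count high-amplitude tail of a simulated
#' distribution to hold at least as much mass as the real one: the
#' fitness requirement is `ssd_tail(...) >= 0`.
#'
#' @param sim,real Amplitude-marginal count vectors on identical edges.
#' @param tail_bins Logical or integer index of the tail bins.
#' @return `sum(sim - real)` over the tail bins.
#' @export
ssd_tail <- function(sim, real, tail_bins) {
  ab <- score_pair(sim, real)
  sum(ab$a[tail_bins] - ab$b[tail_bins])
}

score_pair <- function(a, b) {
  if (inherits(a, "event_histogram2d")) {
    if (!inherits(b, "event_histogram2d") ||
        !isTRUE(all.equal(a$amp_edges, b$amp_edges)) ||
        !isTRUE(all.equal(a$rise_edges, b$rise_edges)))
      stop("histograms must share identical bin edges")
    return(list(a = as.vector(a$counts), b = as.vector(b$counts)))
  }
  if (length(a) != length(b))
    stop("distributions must share identical bin edges")
  list(a = as.numeric(a), b = as.numeric(b))
}

#' Amplitude tail cutoffs from a reference histogram
#'
#' Amplitude values below which 50%, 90% and 98% of the reference
#' events lie; the bins at or above each cutoff define the top-50%,
#' top-10% and top-2% scoring views.
#'
#' @param ref_hist Reference [event_histogram2d()].
#' @return Integer vector of first tail bin indices, named `top50`,
#'   `top10`, `top2`.
#' @export
amplitude_tail_cutoffs <- function(ref_hist) {
  amarg <- rowSums(ref_hist$counts)
  tot <- sum(amarg)
  if (tot <= 0) return(c(top50 = 1L, top10 = 1L, top2 = 1L))
  cw <- cumsum(amarg) / tot
  first_at <- function(q) {
    i <- which(cw >= q)
    if (length(i) == 0L) length(amarg) else min(i) + 1L
  }
  c(top50 = min(first_at(0.5), length(amarg)),
    top10 = min(first_at(0.9), length(amarg)),
    top2 = min(first_at(0.98), length(amarg)))
}

## the six scoring views of a histogram, as count vectors
hist_views <- function(hist, tail_idx) {
  amarg <- rowSums(hist$counts)
  na <- length(amarg)
  list(amp_all = amarg,
       amp_top50 = amarg[tail_idx["top50"]:na],
       amp_top10 = amarg[tail_idx["top10"]:na],
       amp_top2 = amarg[tail_idx["top2"]:na],
       rise_all = colSums(hist$counts),
       joint = as.vector(hist$counts))
}

#' Per-view normalization scales from the set of real histograms
#'
#' Counts in each view are divided by the average bin count of that view
#' over all real distributions before scoring, increasing the relative
#' weight of distribution tails.
#'
#' @param real_hists List of [event_histogram2d()].
#' @param tail_idx Output of [amplitude_tail_cutoffs()].
#' @return Named numeric vector of scales per view.
#' @export
score_normalization <- function(real_hists, tail_idx) {
  acc <- NULL
  for (h in real_hists) {
    v <- vapply(hist_views(h, tail_idx), mean, 0)
    acc <- if (is.null(acc)) v else acc + v
  }
  sc <- acc / length(real_hists)
  sc[sc <= 0] <- 1
  sc
}

#' The 15 discrepancy scores between a simulated and a real histogram
#'
#' Six SADs and six MADs over the views (all amplitudes, top-50%,
#' top-10% and top-2% amplitude tails, all rise times, joint 2-D), and
#' three SSDs over the three amplitude tails (simulated minus real).
#' Views are normalized by the per-view average real bin count.
#'
#' @param sim_hist,ref_hist [event_histogram2d()] on identical edges.
#' @param tail_idx Output of [amplitude_tail_cutoffs()].
#' @param norm Output of [score_normalization()].
#' @return Named numeric vector of length 15.
#' @export
score_vector15 <- function(sim_hist, ref_hist, tail_idx, norm) {
  vs <- hist_views(sim_hist, tail_idx)
  vr <- hist_views(ref_hist, tail_idx)
  nm <- names(vs)
  sads <- vapply(nm, function(k) sad(vs[[k]] / norm[k], vr[[k]] / norm[k]),
                 0)
  mads <- vapply(nm, function(k)
    mad_score(vs[[k]] / norm[k], vr[[k]] / norm[k]), 0)
  tails <- c("amp_top50", "amp_top10", "amp_top2")
  ssds <- vapply(tails, function(k)
    sum(vs[[k]] / norm[k] - vr[[k]] / norm[k]), 0)
  c(stats::setNames(sads, paste0("sad_", nm)),
    stats::setNames(mads, paste0("mad_", nm)),
    stats::setNames(ssds, paste0("ssd_", sub("amp_", "", tails))))
}

#' Combined-centile cutoffs for the 15 scores
#'
#' Finds the smallest global percentile (an integer, the same for every
#' score) whose per-column cutoffs are simultaneously satisfied by at
#' least half of all file pairings, and returns that percentile together
#' with the 15 per-score cutoffs. Percentiles use the standard
#' linear-interpolation definition (R quantile type 7).
#'
#' @param score_matrix Numeric matrix, one row per file pairing, one
#'   column per score.
#' @return List of class `cutoff_set` with `centile` and `cutoffs`.
#' @export
combined_centile <- function(score_matrix) {
  score_matrix <- as.matrix(score_matrix)
  n <- nrow(score_matrix)
  if (n < 1L) stop("need at least one pairing (>= 2 files)")
  eps <- 1e-12
  for (q in 0:100) {
    cutoffs <- apply(score_matrix, 2L, stats::quantile, probs = q / 100,
                     names = FALSE, type = 7)
    pass <- rowSums(sweep(score_matrix, 2L, cutoffs + eps, `<=`)) ==
      ncol(score_matrix)
    if (2L * sum(pass) >= n)
      return(structure(list(centile = q, cutoffs = cutoffs),
                       class = "cutoff_set"))
  }
  structure(list(centile = 100L,
                 cutoffs = apply(score_matrix, 2L, max)),
            class = "cutoff_set")
}

#' Cutoff values at a given centile
#'
#' Applies a previously estimated global centile to a (possibly
#' different, e.g. longer-file) score matrix to obtain the per-score
#' cutoff values used by the cost function.
#'
#' @param score_matrix Numeric matrix of scores (rows = pairings).
#' @param centile Integer percentile.
#' @return A `cutoff_set`.
#' @export
cutoffs_at_centile <- function(score_matrix, centile) {
  structure(list(centile = centile,
                 cutoffs = apply(as.matrix(score_matrix), 2L,
                                 stats::quantile, probs = centile / 100,
                                 names = FALSE, type = 7)),
            class = "cutoff_set")
}

#' Envelope-deviation scores against a set of real histograms
#'
#' For each bin the deviation is the signed distance by which the
#' simulated count leaves the `[min, max]` band over the real
#' histograms (positive above the band, negative below, zero inside).
#' SAD/MAD analogues are the sum and max of absolute deviations over the
#' same six views; SSD analogues are signed sums over the three
#' amplitude tails.
#'
#' @param sim_hist An [event_histogram2d()].
#' @param real_hists List of at least two [event_histogram2d()].
#' @param tail_idx Output of [amplitude_tail_cutoffs()].
#' @param norm Output of [score_normalization()].
#' @return Named numeric vector of 15 envelope scores.
#' @export
envelope_scores <- function(sim_hist, real_hists, tail_idx, norm) {
  stopifnot(length(real_hists) >= 2L)
  vs <- hist_views(sim_hist, tail_idx)
  vreal <- lapply(real_hists, hist_views, tail_idx = tail_idx)
  nm <- names(vs)
  devs <- lapply(nm, function(k) {
    M <- do.call(rbind, lapply(vreal, `[[`, k))
    lo <- apply(M, 2L, min)
    hi <- apply(M, 2L, max)
    x <- vs[[k]]
    (pmax(x - hi, 0) - pmax(lo - x, 0)) / norm[k]
  })
  names(devs) <- nm
  sads <- vapply(nm, function(k) sum(abs(devs[[k]])), 0)
  mads <- vapply(nm, function(k)
    if (length(devs[[k]])) max(abs(devs[[k]])) else 0, 0)
  tails <- c("amp_top50", "amp_top10", "amp_top2")
  ssds <- vapply(tails, function(k) sum(devs[[k]]), 0)
  c(stats::setNames(sads, paste0("env_sad_", nm)),
    stats::setNames(mads, paste0("env_mad_", nm)),
    stats::setNames(ssds, paste0("env_ssd_", sub("amp_", "", tails))))
}

#' Worst-real envelope baseline
#'
#' Leave-one-out envelope scores of each real histogram against the
#' others; the baseline is the per-score maximum (the "worst outlier"
#' level a candidate must not exceed).
#'
#' @inheritParams envelope_scores
#' @return Named numeric vector of 15 baseline values.
#' @export
worst_real_envelope <- function(real_hists, tail_idx, norm) {
  stopifnot(length(real_hists) >= 3L)
  per <- vapply(seq_along(real_hists), function(i)
    envelope_scores(real_hists[[i]], real_hists[-i], tail_idx, norm),
    numeric(15L))
  apply(per, 1L, max)
}

#' Precomputed scoring context
#'
#' Bundles everything the per-candidate cost evaluation needs that does
#' not depend on the candidate: the reference views, the per-view
#' envelope bands over the real histograms, the normalization scales,
#' the cutoffs and the worst-real envelope baseline. Used by
#' [evaluate_cost()] and by the fitting loop, where it is computed once.
#'
#' @param ref_hist The selected reference real histogram.
#' @param real_hists All real histograms.
#' @param cutoffs A `cutoff_set`.
#' @param tail_idx,norm,env_baseline Optional precomputed pieces.
#' @return List of class `scoring_context`.
#' @export
make_scoring_context <- function(ref_hist, real_hists, cutoffs,
                                 tail_idx = NULL, norm = NULL,
                                 env_baseline = NULL) {
  if (is.null(tail_idx)) tail_idx <- amplitude_tail_cutoffs(ref_hist)
  if (is.null(norm)) norm <- score_normalization(real_hists, tail_idx)
  if (is.null(env_baseline))
    env_baseline <- worst_real_envelope(real_hists, tail_idx, norm)
  ref_views <- hist_views(ref_hist, tail_idx)
  vreal <- lapply(real_hists, hist_views, tail_idx = tail_idx)
  nm <- names(ref_views)
  env_lo <- env_hi <- vector("list", length(nm))
  names(env_lo) <- names(env_hi) <- nm
  for (k in nm) {
    M <- do.call(rbind, lapply(vreal, `[[`, k))
    env_lo[[k]] <- apply(M, 2L, min)
    env_hi[[k]] <- apply(M, 2L, max)
  }
  tails <- c("amp_top50", "amp_top10", "amp_top2")
  tail_mass <- abs(vapply(tails, function(k)
    sum(ref_views[[k]] / norm[k]), 0))
  structure(list(ref_views = ref_views, env_lo = env_lo, env_hi = env_hi,
                 cutoffs = cutoffs, tail_idx = tail_idx, norm = norm,
                 env_baseline = env_baseline, tail_mass = tail_mass),
            class = "scoring_context")
}

## candidate cost against a precomputed scoring context
cost_from_context <- function(sim_hist, ctx, dist = NULL,
                              realized = NULL) {
  vs <- hist_views(sim_hist, ctx$tail_idx)
  nm <- names(vs)
  norm <- ctx$norm
  sads <- mads <- numeric(length(nm))
  env_sads <- env_mads <- numeric(length(nm))
  env_dev <- vector("list", length(nm))
  for (i in seq_along(nm)) {
    k <- nm[i]
    d <- (vs[[k]] - ctx$ref_views[[k]]) / norm[k]
    sads[i] <- sum(abs(d))
    mads[i] <- max(abs(d), 0)
    ed <- (pmax(vs[[k]] - ctx$env_hi[[k]], 0) -
             pmax(ctx$env_lo[[k]] - vs[[k]], 0)) / norm[k]
    env_dev[[i]] <- ed
    env_sads[i] <- sum(abs(ed))
    env_mads[i] <- max(abs(ed), 0)
  }
  tails <- c("amp_top50", "amp_top10", "amp_top2")
  ti <- match(tails, nm)
  ssds <- vapply(ti, function(i)
    sum(vs[[i]] - ctx$ref_views[[i]]) / norm[i], 0)
  env_ssds <- vapply(ti, function(i) sum(env_dev[[i]]), 0)
  sc <- c(stats::setNames(sads, paste0("sad_", nm)),
          stats::setNames(mads, paste0("mad_", nm)),
          stats::setNames(ssds, paste0("ssd_", sub("amp_", "", tails))))
  env <- c(stats::setNames(env_sads, paste0("env_sad_", nm)),
           stats::setNames(env_mads, paste0("env_mad_", nm)),
           stats::setNames(env_ssds,
                           paste0("env_ssd_", sub("amp_", "", tails))))
  shape <- if (is.null(dist))
    list(non_unimodal = FALSE, rise_mean_high = FALSE,
         rise_skew_low = FALSE, amp_cliff = FALSE, violations = 0L,
         penalties = numeric(4L))
  else check_shape_constraints(dist, realized)
  sadmad <- 1:12
  ssd_i <- 13:15
  cut <- ctx$cutoffs$cutoffs
  eps <- 1e-12
  sadmad_ok <- sc[sadmad] <= cut[sadmad] + eps
  ssd_ok <- sc[ssd_i] >= -eps
  env_ok <- env <= ctx$env_baseline + eps
  all34 <- all(sadmad_ok) && all(ssd_ok) && all(env_ok) &&
    shape$violations == 0L
  amp_idx <- c(1:4, 7:10)                 # amplitude SADs and MADs
  acceptable <- all(sc[amp_idx] <= cut[amp_idx] + eps) && all(ssd_ok) &&
    !shape$non_unimodal
  verdict <- if (all34) "best_possible"
  else if (acceptable) "acceptable" else "rejected"
  denom <- pmax(cut[sadmad], eps)
  total <- sum(pmax(sc[sadmad] - cut[sadmad], 0) / denom) +
    sum(pmax(-sc[ssd_i], 0) / (1 + ctx$tail_mass)) +
    sum(pmax(env - ctx$env_baseline, 0) / (1 + ctx$env_baseline)) +
    10 * shape$violations
  structure(list(ref_scores = sc, envelope_scores = env, shape = shape,
                 total_cost = total, verdict = verdict),
            class = "cost_breakdown")
}

#' Evaluate the 34-component cost of a candidate distribution
#'
#' Combines the 15 reference-discrepancy scores, the 15
#' envelope-deviation scores and the 4 shape penalties into a scalar
#' cost and a verdict. The fit is `best_possible` when every component
#' is satisfied (SAD/MAD at or below their cutoffs, SSDs non-negative,
#' envelope scores at or below the worst-real baseline, no shape
#' violation); `acceptable` when all amplitude SAD, MAD and SSD scores
#' and the unimodality constraint are satisfied (rise-time scores,
#' envelope scores and the skewness and cliff constraints excluded);
#' otherwise `rejected`.
#'
#' @param sim_hist Histogram of events detected in the simulated trace.
#' @param ref_hist The selected reference real histogram.
#' @param real_hists All real histograms (for the envelope).
#' @param cutoffs A `cutoff_set` for the 15 scores.
#' @param dist The candidate [minis_source_distribution()] (for shape
#'   constraints); may be `NULL` to skip them.
#' @param tail_idx,norm See [score_vector15()].
#' @param env_baseline Output of [worst_real_envelope()].
#' @param realized Optional pre-computed realized histogram of `dist`.
#' @return List of class `cost_breakdown`: `ref_scores`,
#'   `envelope_scores`, `shape`, `total_cost`, `verdict`.
#' @export
evaluate_cost <- function(sim_hist, ref_hist, real_hists, cutoffs,
                          dist = NULL, tail_idx = NULL, norm = NULL,
                          env_baseline = NULL, realized = NULL) {
  ctx <- make_scoring_context(ref_hist, real_hists, cutoffs,
                              tail_idx = tail_idx, norm = norm,
                              env_baseline = env_baseline)
  cost_from_context(sim_hist, ctx, dist = dist, realized = realized)
}
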