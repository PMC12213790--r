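#' Pairwise SAD matrices over a set of real distribution files
#'
#' Computes, separately for the amplitude and rise-time marginals, the
#' matrix of pairwise sums of absolute deviations between all real
#' histograms (counts normalized by the average bin count over the set),
#' the per-row medians (diagonal excluded), and the indices of the
#' "worst" (largest median, most discrepant) and "best" (smallest
#' median) reference distributions. Ties break to the lowest index.
#'
#' @param real_hists List of at least 3 [event_histogram2d()] on
#'   identical edges.
#' @return List of class `sad_matrix` with elements `amplitude` and
#'   `rise_time`, each holding `matrix`, `medians`, `worst`, `best`.
#' @export
build_sad_matrix <- function(real_hists) {
  k <- length(real_hists)
  if (k < 3L) stop("need at least 3 real files")
  marg <- lapply(real_hists, hist2d_marginals)
  one <- function(which_marg) {
    vecs <- lapply(marg, `[[`, which_marg)
    scale <- mean(vapply(vecs, mean, 0))
    if (scale <= 0) scale <- 1
    M <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      M[i, j] <- M[j, i] <- sum(abs(vecs[[i]] - vecs[[j]])) / scale
    med <- vapply(seq_len(k), function(i) stats::median(M[i, -i]), 0)
    list(matrix = M, medians = med,
         worst = which.max(med), best = which.min(med))
  }
  structure(list(amplitude = one("amplitude"),
                 rise_time = one("rise_time")),
            class = "sad_matrix")
}

#' Wilcoxon signed-rank paired test
#'
#' One-sided paired-samples signed-rank test. Zero differences are
#' dropped (Wilcoxon's original treatment) and ties receive average
#' ranks. For `n <= exact_limit` the p-value is computed by exact
#' enumeration of all sign assignments (a shifted convolution over the
#' doubled average ranks, exact also under ties); above that a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param alternative `"greater"` tests whether the median of `x - y` is
#'   positive; `"less"` the opposite.
#' @param exact_limit Largest n for which the exact distribution is
#'   enumerated (default 25).
#' @return List with `W_pos` (sum of positive ranks), `W_neg`, `n`
#'   (non-zero pairs), `p` (one-sided), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("greater", "less"),
                                 exact_limit = 25L) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(W_pos = 0, W_neg = 0, n = 0L, p = 1, method = "degenerate"))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  ## test statistic: rank sum supporting the alternative
  if (alternative == "greater") {
    w <- w_pos
  } else {
    w <- w_neg
  }
  if (n <= exact_limit) {
    p <- signed_rank_upper_tail(r, w)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  list(W_pos = w_pos, W_neg = w_neg, n = n, p = p, method = method)
}

## exact P(W >= w) where W is the sum of a random subset of the average
## ranks r (each included independently with probability 1/2); computed
## by convolution over doubled ranks, which are integers
signed_rank_upper_tail <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1L)                # f[s + 1] = #subsets with sum s
  f[1L] <- 1
  for (v in r2) {
    idx <- total:v
    f[idx + 1L] <- f[idx + 1L] + f[idx - v + 1L]
  }
  w2 <- 2 * w
  ## sum over s >= w2 (guard numerical fuzz in w)
  lo <- as.integer(ceiling(w2 - 1e-9))
  sum(f[(lo:total) + 1L]) / 2^length(r2)
}

#' Final statistical acceptance test of a fitted distribution
#'
#' Builds the real-real SAD matrices, selects the worst and best
#' reference real distributions for each marginal, forms the
#' simulated-real SAD score sets (excluding the reference file from the
#' comparisons), and runs one-sided Wilcoxon signed-rank paired tests:
#' the underfit test asks whether the simulated-real median SAD is
#' significantly larger than the worst real-real median, and the overfit
#' ("excellent fit") test whether it is significantly smaller than the
#' best real-real median. The fit is accepted when neither underfit test
#' (amplitude, rise time) is significant at the Bonferroni-corrected
#' level `alpha / 2`.
#'
#' @param sim_hist Histogram of events detected in the fitted simulated
#'   trace, binned identically to the real histograms.
#' @param real_hists List of at least 3 real histograms.
#' @param alpha Family significance level before Bonferroni correction
#'   (default 0.05; each one-sided test is evaluated at `alpha / 2`).
#' @return List of class `acceptance_verdict` with per-marginal test
#'   results, `accepted` and `excellent`.
#' @export
accept_fit <- function(sim_hist, real_hists, alpha = 0.05) {
  sm <- build_sad_matrix(real_hists)
  marg_sim <- hist2d_marginals(sim_hist)
  one <- function(which_marg) {
    part <- sm[[which_marg]]
    vecs <- lapply(real_hists, function(h) hist2d_marginals(h)[[which_marg]])
    scale <- mean(vapply(vecs, mean, 0))
    if (scale <= 0) scale <- 1
    sv <- marg_sim[[which_marg]]
    k <- length(real_hists)
    test_against <- function(ref) {
      others <- setdiff(seq_len(k), ref)
      sim_set <- vapply(others, function(j)
        sum(abs(sv - vecs[[j]])) / scale, 0)
      real_set <- part$matrix[ref, others]
      list(sim_set = sim_set, real_set = real_set)
    }
    wt <- test_against(part$worst)
    under <- wilcoxon_signed_rank(wt$sim_set, wt$real_set, "greater")
    bt <- test_against(part$best)
    over <- wilcoxon_signed_rank(bt$sim_set, bt$real_set, "less")
    list(worst_ref = part$worst, best_ref = part$best,
         underfit = under, overfit = over)
  }
  amp <- one("amplitude")
  rise <- one("rise_time")
  thr <- alpha / 2
  accepted <- amp$underfit$p >= thr && rise$underfit$p >= thr
  excellent <- amp$overfit$p < thr && rise$overfit$p < thr
  structure(list(amplitude = amp, rise_time = rise,
                 alpha = alpha, accepted = accepted,
                 excellent = excellent),
            class = "acceptance_verdict")
}

#' @export
print.acceptance_verdict <- function(x, ...) {
  fmt <- function(m, t) sprintf(
    "  %-9s %-8s W+=%g W-=%g n=%d p=%.4g (Bonferroni-corrected %.4g)",
    m, t$.label, t$W_pos, t$W_neg, t$n, t$p, min(2 * t$p, 1))
  for (m in c("amplitude", "rise_time")) {
    u <- x[[m]]$underfit; u$.label <- "underfit"
    o <- x[[m]]$overfit; o$.label <- "overfit"
    cat(fmt(m, u), "\n")
    cat(fmt(m, o), "\n")
  }
  cat(sprintf("accepted: %s; excellent: %s\n", x$accepted, x$excellent))
  invisible(x)
}
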