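# Independent oracles used across tests: Monte-Carlo prior-sampling
# integration for the marginal likelihoods, brute-force pair counting for
# AUC, and a naive O(n*m) midpoint counter for binning. These deliberately
# share no code with the package's quadrature/rank implementations.

# log E_prior[ L(x | Y) ] by direct prior sampling over all five hidden
# parameters; returns the log estimate and the MC standard error of the log.
mc_signal_marginal <- function(profile, phi, n_draws = 2e5, seed = 1,
                               chunk = 5e4) {
  set.seed(seed)
  ll <- numeric(n_draws)
  done <- 0
  while (done < n_draws) {
    m <- min(chunk, n_draws - done)
    s <- rgamma(m, phi$gS$shape, phi$gS$rate)
    b <- rgamma(m, phi$gB$shape, phi$gB$rate)
    tt <- rgamma(m, phi$gT$shape, phi$gT$rate)
    kp <- rgamma(m, phi$gKp$shape, phi$gKp$rate)
    kt <- rgamma(m, phi$gKt$shape, phi$gKt$rate)
    acc <- numeric(m)
    for (j in seq_along(profile$offsets)) {
      d <- profile$offsets[j]
      lam <- if (d == 0) s
             else if (d < 0) b + (s - b) * exp(-kp * abs(d))
             else tt + (s - tt) * exp(-kt * d)
      acc <- acc + dpois(profile$counts[j], lam, log = TRUE)
    }
    ll[(done + 1):(done + m)] <- acc
    done <- done + m
  }
  mx <- max(ll)
  w <- exp(ll - mx)
  list(est = mx + log(mean(w)),
       se = stats::sd(w) / (sqrt(n_draws) * mean(w)))
}

# Background-only marginal: B is a scalar shared by all bins, so the
# per-draw log-likelihood has the closed vector form
# sum(x)*log(B) - n*B - sum(log x!).
mc_background_marginal <- function(profile, gB, n_draws = 2e5, seed = 1) {
  set.seed(seed)
  b <- rgamma(n_draws, gB$shape, gB$rate)
  x <- profile$counts
  ll <- sum(x) * log(b) - length(x) * b - sum(lgamma(x + 1))
  mx <- max(ll)
  w <- exp(ll - mx)
  list(est = mx + log(mean(w)),
       se = stats::sd(w) / (sqrt(n_draws) * mean(w)))
}

# Tie-aware AUC by explicit double loop over all (pos, neg) pairs.
brute_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Naive midpoint binning: for each bin offset, count fragments whose
# midpoint falls in the bin's genomic span (same boundary convention as
# documented: boundary midpoints go transcriptionally downstream).
naive_bin_counts <- function(frags, chrom, anchor_pos, strand, offsets,
                             bin_width = 200L) {
  idx <- as.character(GenomicRanges::seqnames(frags)) == chrom
  mids <- (GenomicRanges::start(frags)[idx] - 1 +
             GenomicRanges::end(frags)[idx]) %/% 2
  a0 <- anchor_pos - 1
  half <- bin_width %/% 2
  vapply(offsets, function(j) {
    if (strand == "+") {
      lo <- a0 - half + j * bin_width
      sum(mids >= lo & mids < lo + bin_width)
    } else {
      hi <- a0 + half - j * bin_width
      sum(mids > hi - bin_width & mids <= hi)
    }
  }, numeric(1))
}

# A reproducible, moderately-expressed test profile drawn from the
# generative model (fixed hidden parameters, seeded Poisson noise).
fixture_profile <- function(seed = 401, s = 30, b = 2, t = 8,
                            kp = 0.8, kt = 0.4) {
  set.seed(seed)
  h <- hidden_params(s, b, t, kp, kt)
  offs <- -25:25
  binned_profile(rpois(51, expected_lambda(h, offs)), offs,
                 anchor_id = "fixture")
}

# Near-degenerate hyperparameters: shape large enough that the marginal
# collapses onto the likelihood at the prior means.
degenerate_phi <- function(means = c(s = 50, b = 2, t = 10, kp = 0.5, kt = 0.3),
                           shape = 1e10) {
  hyper_params(gamma_hyper(shape, shape / means[["s"]]),
               gamma_hyper(shape, shape / means[["b"]]),
               gamma_hyper(shape, shape / means[["t"]]),
               gamma_hyper(shape, shape / means[["kp"]]),
               gamma_hyper(shape, shape / means[["kt"]]))
}
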