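## Core generative model of RPol II occupancy around a transcription start
## site: Poisson counts in 200-bp bins whose means are governed by five
## strictly positive gene-specific parameters (S, B, T, Kp, Kt), themselves
## Gamma-distributed genome-wide.

#' Binned RPol II fragment profile around an anchor
#'
#' Container for integer fragment counts in fixed-width bins at signed
#' offsets around an anchor position (a TSS or a candidate bin center).
#' Offsets are in bin units and transcriptionally oriented: negative offsets
#' are upstream of the anchor after strand flipping, offset 0 is the anchor
#' bin itself.
#'
#' @param counts Non-negative integer vector, one count per offset.
#' @param offsets Signed integer vector of bin offsets; must be contiguous
#'   and contain 0. Defaults to a symmetric window implied by `length(counts)`.
#' @param anchor_id,chrom,anchor_pos,strand Optional provenance: label,
#'   chromosome, 1-based genomic coordinate of the anchor base, and strand
#'   (`"+"` or `"-"`).
#' @param bin_width Bin width in bp (default 200).
#' @return An object of class `binned_profile`.
#' @export
binned_profile <- function(counts, offsets = NULL, anchor_id = NA_character_,
                           chrom = NA_character_, anchor_pos = NA_integer_,
                           strand = "+", bin_width = 200) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    mirtss_stop("counts must be non-negative integers", "mirtss_invalid_profile")
  }
  if (is.null(offsets)) {
    n_up <- (length(counts) - 1L) %/% 2L
    offsets <- seq.int(-n_up, length.out = length(counts))
  }
  offsets <- as.integer(offsets)
  if (length(offsets) != length(counts)) {
    mirtss_stop("offsets and counts lengths differ", "mirtss_invalid_profile")
  }
  if (any(diff(offsets) != 1L) || !any(offsets == 0L)) {
    mirtss_stop("offsets must be contiguous and include 0",
                "mirtss_invalid_profile")
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    mirtss_stop("bin_width must be positive", "mirtss_invalid_profile")
  }
  if (!strand %in% c("+", "-")) {
    mirtss_stop("strand must be '+' or '-'", "mirtss_invalid_profile")
  }
  structure(
    list(anchor_id = anchor_id, chrom = chrom,
         anchor_pos = as.integer(anchor_pos), strand = strand,
         bin_width = as.integer(bin_width),
         offsets = offsets, counts = as.integer(counts)),
    class = "binned_profile"
  )
}

#' @export
print.binned_profile <- function(x, ...) {
  cat(sprintf("<binned_profile> %s %s:%s(%s)  %d bins of %d bp, %d fragments\n",
              x$anchor_id, x$chrom, x$anchor_pos, x$strand,
              length(x$counts), x$bin_width, sum(x$counts)))
  invisible(x)
}

#' Gene-specific hidden occupancy parameters
#'
#' The five strictly positive latent parameters describing one locus:
#' `s` expected fragments in the TSS bin, `b` expected fragments per
#' background bin, `t` expected fragments per steady transcript bin, and the
#' upstream/downstream per-bin decay rates `kp` and `kt`.
#'
#' @param s,b,t,kp,kt Strictly positive finite scalars.
#' @return An object of class `hidden_params`.
#' @export
hidden_params <- function(s, b, t, kp, kt) {
  v <- c(s = s, b = b, t = t, kp = kp, kt = kt)
  if (anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
    mirtss_stop("hidden parameters must be strictly positive and finite",
                "mirtss_invalid_params")
  }
  structure(as.list(v), class = "hidden_params")
}

#' Gamma law for one hidden parameter
#'
#' Shape/rate parametrization throughout; the mean is `shape/rate`. Use
#' [gamma_hyper_from_shape_scale()] to convert from shape/scale.
#'
#' @param shape,rate Strictly positive scalars.
#' @return An object of class `gamma_hyper` with fields `shape`, `rate`, `mean`.
#' @export
gamma_hyper <- function(shape, rate) {
  if (!is.finite(shape) || !is.finite(rate) || shape <= 0 || rate <= 0) {
    mirtss_stop("gamma_hyper requires shape > 0 and rate > 0",
                "mirtss_invalid_params")
  }
  structure(list(shape = shape, rate = rate, mean = shape / rate),
            class = "gamma_hyper")
}

#' @rdname gamma_hyper
#' @param scale Scale parameter (`1/rate`).
#' @export
gamma_hyper_from_shape_scale <- function(shape, scale) {
  gamma_hyper(shape = shape, rate = 1 / scale)
}

#' @rdname gamma_hyper
#' @param mean,cv Mean and coefficient of variation of the law
#'   (`shape = 1/cv^2`, `rate = shape/mean`).
#' @export
gamma_hyper_from_mean_cv <- function(mean, cv) {
  shape <- 1 / cv^2
  gamma_hyper(shape = shape, rate = shape / mean)
}

#' Genome-wide hyperparameters (the 10-scalar Phi)
#'
#' Five Gamma laws, one per hidden parameter. `gB` doubles as the background
#' law (its shape/rate are the alpha/beta of the background-only marginal in
#' the scan score).
#'
#' @param gS,gB,gT,gKp,gKt [gamma_hyper()] objects.
#' @return An object of class `hyper_params`.
#' @export
hyper_params <- function(gS, gB, gT, gKp, gKt) {
  comps <- list(gS = gS, gB = gB, gT = gT, gKp = gKp, gKt = gKt)
  ok <- vapply(comps, inherits, logical(1), what = "gamma_hyper")
  if (!all(ok)) {
    mirtss_stop("all five components must be gamma_hyper objects",
                "mirtss_invalid_params")
  }
  structure(comps, class = "hyper_params")
}

#' @export
print.hyper_params <- function(x, ...) {
  cat("<hyper_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-4s shape=%.4g rate=%.4g  (mean %.4g)\n",
                nm, x[[nm]]$shape, x[[nm]]$rate, x[[nm]]$mean))
  }
  invisible(x)
}

#' Expected RPol II occupancy at a signed bin offset
#'
#' The TSS bin (offset 0) has mean `s`; upstream bins decay exponentially
#' from `s` towards the background asymptote `b` at rate `kp` per bin;
#' downstream bins decay from `s` towards the steady transcript level `t` at
#' rate `kt` per bin.
#'
#' @param h A [hidden_params()] object.
#' @param d Integer vector of signed bin offsets (negative = upstream).
#' @return Positive numeric vector of expected fragment counts per bin.
#' @export
expected_lambda <- function(h, d) {
  if (!inherits(h, "hidden_params")) h <- do.call(hidden_params, as.list(h))
  d <- as.numeric(d)
  if (anyNA(d) || any(d != round(d))) {
    mirtss_stop("offsets must be integers", "mirtss_invalid_params")
  }
  lam <- rep(h$s, length(d))
  up <- d < 0
  dn <- d > 0
  lam[up] <- h$b + (h$s - h$b) * exp(-h$kp * abs(d[up]))
  lam[dn] <- h$t + (h$s - h$t) * exp(-h$kt * d[dn])
  lam
}

#' Poisson log-likelihood of a profile under fixed hidden parameters
#'
#' @param profile A [binned_profile()].
#' @param h A [hidden_params()] object.
#' @return Scalar log-likelihood (sum over bins of Poisson log-PMFs).
#' @export
profile_loglik <- function(profile, h) {
  stopifnot(inherits(profile, "binned_profile"))
  lam <- expected_lambda(h, profile$offsets)
  sum(dpois(profile$counts, lam, log = TRUE))
}

#' Integration settings for marginal likelihoods
#'
#' Hidden-parameter marginalization uses product Gauss-Legendre quadrature on
#' each Gamma prior's quantile scale (deterministic); a seeded Monte-Carlo
#' prior-sampling fallback is available.
#'
#' @param n_nodes Nodes per dimension for quadrature (default 15).
#' @param method `"quadrature"` (default) or `"mc"`.
#' @param mc_draws Number of prior draws for the MC method.
#' @param mc_seed Seed for the MC method (required when `method = "mc"`).
#' @return An object of class `integration_settings`.
#' @export
integration_settings <- function(n_nodes = 15, method = c("quadrature", "mc"),
                                 mc_draws = 1e5, mc_seed = 1L) {
  method <- match.arg(method)
  if (n_nodes < 2) mirtss_stop("need at least 2 nodes", "mirtss_invalid_params")
  structure(list(n_nodes = as.integer(n_nodes), method = method,
                 mc_draws = as.integer(mc_draws), mc_seed = as.integer(mc_seed)),
            class = "integration_settings")
}

## Gauss-Legendre nodes/weights mapped through a Gamma prior's quantile
## function, so that sum(w * f(node)) approximates E_prior[f(Y)].
gamma_quad_nodes <- function(g, n) {
  gl <- pracma::gaussLegendre(n, 0, 1)
  nodes <- qgamma(gl$x, shape = g$shape, rate = g$rate)
  ## qgamma can underflow to 0 for extreme quantiles of tiny-shape priors;
  ## likelihood code requires strictly positive parameter values.
  nodes <- pmax(nodes, .Machine$double.xmin)
  list(nodes = nodes, weights = gl$w)
}

grid_stats <- function(profile, phi, integ) {
  n <- integ$n_nodes
  qs <- gamma_quad_nodes(phi$gS, n)
  qb <- gamma_quad_nodes(phi$gB, n)
  qt <- gamma_quad_nodes(phi$gT, n)
  qkp <- gamma_quad_nodes(phi$gKp, n)
  qkt <- gamma_quad_nodes(phi$gKt, n)
  cpp_profile_grid(as.integer(profile$counts), as.integer(profile$offsets),
                   qs$nodes, qs$weights, qb$nodes, qb$weights,
                   qt$nodes, qt$weights, qkp$nodes, qkp$weights,
                   qkt$nodes, qkt$weights)
}

## Batched variant over a count matrix sharing one offsets vector; returns
## the n x 11 stats matrix (logM, posterior means, posterior log-means).
grid_stats_matrix <- function(counts, offsets, phi, n_nodes) {
  qs <- gamma_quad_nodes(phi$gS, n_nodes)
  qb <- gamma_quad_nodes(phi$gB, n_nodes)
  qt <- gamma_quad_nodes(phi$gT, n_nodes)
  qkp <- gamma_quad_nodes(phi$gKp, n_nodes)
  qkt <- gamma_quad_nodes(phi$gKt, n_nodes)
  cpp_profiles_grid(counts, as.integer(offsets),
                    qs$nodes, qs$weights, qb$nodes, qb$weights,
                    qt$nodes, qt$weights, qkp$nodes, qkp$weights,
                    qkt$nodes, qkt$weights)
}

mc_signal_loglik <- function(profile, phi, integ) {
  with_seed(integ$mc_seed, {
    n <- integ$mc_draws
    s <- rgamma(n, phi$gS$shape, phi$gS$rate)
    b <- rgamma(n, phi$gB$shape, phi$gB$rate)
    tt <- rgamma(n, phi$gT$shape, phi$gT$rate)
    kp <- rgamma(n, phi$gKp$shape, phi$gKp$rate)
    kt <- rgamma(n, phi$gKt$shape, phi$gKt$rate)
    ll <- numeric(n)
    for (j in seq_along(profile$offsets)) {
      d <- profile$offsets[j]
      lam <- if (d == 0) s
             else if (d < 0) b + (s - b) * exp(-kp * abs(d))
             else tt + (s - tt) * exp(-kt * d)
      ll <- ll + dpois(profile$counts[j], lam, log = TRUE)
    }
    m <- max(ll)
    m + log(mean(exp(ll - m)))
  })
}

#' Marginal log-likelihood of a profile under the TSS (signal) model
#'
#' Integrates the Poisson profile likelihood over the five Gamma-distributed
#' hidden parameters. Deterministic given the integration settings.
#'
#' @param profile A [binned_profile()] centered on the putative TSS bin.
#' @param phi A [hyper_params()] object.
#' @param integ [integration_settings()].
#' @return Scalar log marginal likelihood.
#' @export
signal_marginal_loglik <- function(profile, phi, integ = integration_settings()) {
  stopifnot(inherits(profile, "binned_profile"), inherits(phi, "hyper_params"))
  out <- if (integ$method == "mc") {
    mc_signal_loglik(profile, phi, integ)
  } else {
    unname(grid_stats(profile, phi, integ)[1L])
  }
  if (!is.finite(out)) {
    mirtss_stop("hidden-parameter integration returned a non-finite value",
                "mirtss_integration_error")
  }
  out
}

#' Marginal log-likelihood under the background-only model
#'
#' All bins share one background level B with a Gamma(alpha, beta) prior;
#' the Gamma-Poisson marginal is available in closed form.
#'
#' @param profile A [binned_profile()].
#' @param gB The background [gamma_hyper()] law.
#' @return Scalar log marginal likelihood.
#' @export
background_marginal_loglik <- function(profile, gB) {
  stopifnot(inherits(profile, "binned_profile"), inherits(gB, "gamma_hyper"))
  x <- profile$counts
  n <- length(x)
  sx <- sum(x)
  lgamma(gB$shape + sx) - lgamma(gB$shape) +
    gB$shape * log(gB$rate) -
    (gB$shape + sx) * log(gB$rate + n) -
    sum(lgamma(x + 1))
}

#' TSS scan score: signal-vs-background marginal log-likelihood ratio
#'
#' `delta_f = signal_marginal_loglik - background_marginal_loglik`, the
#' background law being `phi$gB`. Higher values indicate a more TSS-like
#' occupancy pattern around the evaluated bin.
#'
#' @inheritParams signal_marginal_loglik
#' @return Scalar score.
#' @export
delta_f <- function(profile, phi, integ = integration_settings()) {
  signal_marginal_loglik(profile, phi, integ) -
    background_marginal_loglik(profile, phi$gB)
}
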