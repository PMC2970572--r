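## Gold-standard construction from coding genes and EM estimation of the
## ten genome-wide Gamma hyperparameters from expressed-gene profiles.

#' Select the coding-gene gold standard
#'
#' Retains genes that are long enough and transcriptionally isolated, then
#' partitions them by expression call: Present genes form the expressed pool
#' (a seeded fraction goes to training, the rest to testing), Absent genes
#' form the unexpressed (negative-control) pool, Marginal genes are dropped.
#'
#' A gene is retained when its span exceeds `min_len` bp and no other gene's
#' span or TSS lies within `isolation` bp of its TSS, which avoids RPol II
#' signal bleeding in from neighbouring transcription units.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`, `tss`
#'   (1-based coordinate of the TSS base), `span_start`, `span_end` (1-based
#'   closed span), `call` (`"P"`, `"M"` or `"A"`) and `intensity`.
#' @param min_len Minimum span length in bp (default 10000).
#' @param isolation Required clear distance around the TSS in bp (default 10000).
#' @param split_fraction Fraction of expressed survivors assigned to the
#'   training split (default 0.25).
#' @param seed Integer seed for the train/test split.
#' @return An object of class `gold_standard`: lists `train_expressed`,
#'   `test_expressed`, `unexpressed` of gene ids, plus `split_seed`.
#' @export
select_gold_standard <- function(genes, min_len = 10000, isolation = 10000,
                                 split_fraction = 0.25, seed = 1L) {
  req <- c("gene_id", "chrom", "strand", "tss", "span_start", "span_end", "call")
  if (!all(req %in% names(genes))) {
    mirtss_stop(paste("genes table must have columns:",
                      paste(req, collapse = ", ")), "mirtss_invalid_input")
  }
  span_len <- genes$span_end - genes$span_start
  long_enough <- span_len > min_len

  ## isolation: any OTHER gene whose TSS or span comes within `isolation`
  ## bp of this gene's TSS disqualifies it
  n <- nrow(genes)
  isolated <- logical(n)
  for (i in seq_len(n)) {
    same <- which(genes$chrom == genes$chrom[i])
    same <- setdiff(same, i)
    if (length(same) == 0) { isolated[i] <- TRUE; next }
    tssd <- abs(genes$tss[same] - genes$tss[i])
    ## distance from this TSS to the other gene's span interval
    spand <- pmax(0, pmax(genes$span_start[same] - genes$tss[i],
                          genes$tss[i] - genes$span_end[same]))
    isolated[i] <- all(tssd > isolation & spand > isolation)
  }

  keep <- genes[long_enough & isolated, , drop = FALSE]
  expressed <- keep$gene_id[keep$call == "P"]
  unexpressed <- keep$gene_id[keep$call == "A"]
  if (length(expressed) == 0 || length(unexpressed) == 0) {
    mirtss_stop("gold standard has an empty expressed or unexpressed pool",
                "mirtss_empty_pool")
  }
  n_train <- max(1L, round(split_fraction * length(expressed)))
  train <- with_seed(seed, sample(expressed, n_train))
  structure(
    list(train_expressed = sort(train),
         test_expressed = sort(setdiff(expressed, train)),
         unexpressed = sort(unexpressed),
         split_seed = as.integer(seed)),
    class = "gold_standard"
  )
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold_standard> train %d / test %d expressed, %d unexpressed (seed %d)\n",
              length(x$train_expressed), length(x$test_expressed),
              length(x$unexpressed), x$split_seed))
  invisible(x)
}

#' EM fitting settings
#'
#' @param tol Relative change in the marginal log-likelihood below which the
#'   EM loop stops (default 1e-5).
#' @param max_iter Maximum EM iterations (default 200).
#' @param n_nodes Quadrature nodes per hidden dimension in the E-step.
#' @return A list of settings.
#' @export
fit_settings <- function(tol = 1e-5, max_iter = 200L, n_nodes = 15L) {
  list(tol = tol, max_iter = as.integer(max_iter), n_nodes = as.integer(n_nodes))
}

profiles_to_matrix <- function(profiles) {
  offs <- profiles[[1]]$offsets
  for (p in profiles) {
    if (!identical(p$offsets, offs)) {
      mirtss_stop("all training profiles must share one offset window",
                  "mirtss_invalid_input")
    }
  }
  counts <- t(vapply(profiles, function(p) as.integer(p$counts),
                     integer(length(offs))))
  list(counts = counts, offsets = offs)
}

## Method-of-moments initialization from naive per-gene estimates: the
## central bin estimates S, the outermost upstream/downstream bins estimate
## B and T, and a log-excess regression over the first upstream/downstream
## bins estimates the decay rates.
init_hyperparams <- function(profiles, n_edge = 5L) {
  pm <- profiles_to_matrix(profiles)
  counts <- pm$counts
  offs <- pm$offsets
  up_edge <- which(offs < 0)
  up_edge <- up_edge[order(offs[up_edge])][seq_len(min(n_edge, length(up_edge)))]
  dn_edge <- which(offs > 0)
  dn_edge <- dn_edge[order(-offs[dn_edge])][seq_len(min(n_edge, length(dn_edge)))]
  c0 <- which(offs == 0)

  s0 <- pmax(counts[, c0], 0.5)
  b0 <- pmax(rowMeans(counts[, up_edge, drop = FALSE]), 0.25)
  t0 <- pmax(rowMeans(counts[, dn_edge, drop = FALSE]), 0.25)

  decay_rate <- function(side_offs, asymp) {
    ## slope of log(excess over asymptote) against |d| for |d| <= 8
    idx <- which(offs %in% side_offs)
    rates <- vapply(seq_len(nrow(counts)), function(i) {
      d <- abs(offs[idx])
      ex <- pmax(counts[i, idx] - asymp[i], 0.25)
      fit <- stats::lm.fit(cbind(1, d), log(ex))
      max(min(-fit$coefficients[2], 5), 0.05)
    }, numeric(1))
    rates
  }
  kp0 <- decay_rate(-(1:8), b0)
  kt0 <- decay_rate(1:8, t0)

  mom <- function(v) {
    m <- mean(v); va <- max(stats::var(v), 1e-8)
    shape <- max(m^2 / va, 0.05)
    gamma_hyper(shape, shape / m)
  }
  hyper_params(mom(s0), mom(b0), mom(t0), mom(kp0), mom(kt0))
}

## Gamma shape from expected sufficient statistics: solves
## log(shape) - digamma(shape) = c by Newton iteration (c > 0 by Jensen).
solve_gamma_shape <- function(c, tol = 1e-10, max_iter = 100L) {
  if (!is.finite(c) || c <= 0) return(NA_real_)
  a <- (3 - c + sqrt((c - 3)^2 + 24 * c)) / (12 * c)
  for (i in seq_len(max_iter)) {
    f <- log(a) - digamma(a) - c
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < tol * a) { a <- a_new; break }
    a <- a_new
  }
  a
}

#' Fit the ten genome-wide hyperparameters by EM
#'
#' E-step: posterior expectations of each hidden parameter and of its
#' logarithm per gene, under the current hyperparameters, by deterministic
#' quadrature. M-step: per-parameter Gamma update matching the posterior
#' expected sufficient statistics (Newton solve of the digamma equation for
#' the shape; rate = shape/mean). The objective is the summed marginal
#' log-likelihood, which is non-decreasing along iterations up to
#' quadrature error.
#'
#' @param profiles List of [binned_profile()] objects sharing one offset
#'   window (training genes).
#' @param init Optional initial [hyper_params()]; defaults to a
#'   method-of-moments initialization from naive per-gene estimates.
#' @param settings [fit_settings()].
#' @return An object of class `fit_result`: `phi`, `objective_trace`,
#'   `converged`, `n_iter`, `per_gene_posthidden` (data.frame of posterior
#'   means per gene) and `skipped` (gene ids with non-finite E-steps).
#' @export
fit_hyperparams <- function(profiles, init = NULL, settings = fit_settings()) {
  if (length(profiles) < 2) {
    mirtss_stop("need at least 2 training profiles", "mirtss_invalid_input")
  }
  pm <- profiles_to_matrix(profiles)
  ids <- vapply(profiles, function(p) p$anchor_id, character(1))
  if (anyNA(ids)) ids <- paste0("gene", seq_along(profiles))
  phi <- if (is.null(init)) init_hyperparams(profiles) else init
  trace <- numeric(0)
  converged <- FALSE
  skipped <- character(0)
  stats_mat <- NULL

  for (iter in seq_len(settings$max_iter)) {
    st <- grid_stats_matrix(pm$counts, pm$offsets, phi, settings$n_nodes)
    ok <- is.finite(st[, "logM"]) & apply(is.finite(st), 1, all)
    if (!all(ok)) {
      bad <- ids[!ok]
      warning(sprintf("E-step non-finite for %d gene(s): %s -- skipped",
                      length(bad), paste(head(bad, 5), collapse = ", ")))
      skipped <- union(skipped, bad)
      st <- st[ok, , drop = FALSE]
      pm$counts <- pm$counts[ok, , drop = FALSE]
      ids <- ids[ok]
      if (nrow(st) < 2) {
        mirtss_stop("fewer than 2 genes with finite E-step",
                    "mirtss_integration_error")
      }
    }
    obj <- sum(st[, "logM"])
    trace <- c(trace, obj)
    stats_mat <- st

    phi_new <- phi
    for (par in c("S", "B", "T", "Kp", "Kt")) {
      m <- mean(st[, par])
      ml <- mean(st[, paste0("log", par)])
      shape <- solve_gamma_shape(log(m) - ml)
      if (!is.finite(shape)) next  # degenerate posterior; keep previous law
      phi_new[[paste0("g", par)]] <- gamma_hyper(shape, shape / m)
    }

    if (iter > 1) {
      rel <- abs(trace[iter] - trace[iter - 1]) /
        (abs(trace[iter - 1]) + .Machine$double.eps)
      if (rel < settings$tol) { converged <- TRUE; phi <- phi_new; break }
    }
    phi <- phi_new
  }

  post <- data.frame(gene_id = ids,
                     s = stats_mat[, "S"], b = stats_mat[, "B"],
                     t = stats_mat[, "T"], kp = stats_mat[, "Kp"],
                     kt = stats_mat[, "Kt"], stringsAsFactors = FALSE)
  structure(
    list(phi = phi, objective_trace = trace, converged = converged,
         n_iter = length(trace), per_gene_posthidden = post,
         skipped = skipped, settings = settings),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d iterations (%s), objective %.2f\n",
              x$n_iter, if (x$converged) "converged" else "max_iter",
              tail(x$objective_trace, 1)))
  print(x$phi)
  invisible(x)
}

#' Posterior means of the hidden parameters for one profile
#'
#' @inheritParams signal_marginal_loglik
#' @return A [hidden_params()] object of posterior means.
#' @export
posterior_hidden_means <- function(profile, phi, integ = integration_settings()) {
  st <- grid_stats(profile, phi, integ)
  if (any(!is.finite(st))) {
    mirtss_stop("hidden-parameter integration returned a non-finite value",
                "mirtss_integration_error")
  }
  hidden_params(st[["S"]], st[["B"]], st[["T"]], st[["Kp"]], st[["Kt"]])
}

#' Write / read hyperparameters as a flat key-value text file
#'
#' Ten named scalars plus free metadata lines (`meta.<key>`), one `key<TAB>value`
#' pair per line.
#'
#' @param phi A [hyper_params()] object.
#' @param path Output file path.
#' @param metadata Named character vector or list of extra metadata.
#' @return `write_hyperparams` returns `path` invisibly; `read_hyperparams`
#'   returns a list with elements `phi` and `metadata`.
#' @export
write_hyperparams <- function(phi, path, metadata = list()) {
  stopifnot(inherits(phi, "hyper_params"))
  keys <- character(0); vals <- character(0)
  for (nm in names(phi)) {
    keys <- c(keys, paste0(nm, ".shape"), paste0(nm, ".rate"))
    vals <- c(vals, format(phi[[nm]]$shape, digits = 17),
              format(phi[[nm]]$rate, digits = 17))
  }
  for (nm in names(metadata)) {
    keys <- c(keys, paste0("meta.", nm))
    vals <- c(vals, as.character(metadata[[nm]]))
  }
  writeLines(paste(keys, vals, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_hyperparams
#' @export
read_hyperparams <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("key", "value"),
                    colClasses = "character", quote = "")
  kv <- setNames(tab$value, tab$key)
  g <- function(nm) gamma_hyper(as.numeric(kv[[paste0(nm, ".shape")]]),
                                as.numeric(kv[[paste0(nm, ".rate")]]))
  phi <- hyper_params(g("gS"), g("gB"), g("gT"), g("gKp"), g("gKt"))
  meta_keys <- grep("^meta\\.", names(kv), value = TRUE)
  meta <- as.list(kv[meta_keys])
  names(meta) <- sub("^meta\\.", "", meta_keys)
  list(phi = phi, metadata = meta)
}
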