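# Weibull size distribution d(.), copy likelihood (geometric mean of fragment
# and gap size probabilities), the effectiveness test at level tau, and the
# abundance measures eTPM / FPKM / TPM.

#' Construct a Weibull size model
#'
#' @param eta Scale parameter (fragmentation intensity; experiment-wide).
#' @param delta Shape parameter. With `delta_rule = "constant"` this is the
#'   shape used for every isoform; with `"loglinear"` the shape of isoform i
#'   is `delta * log(len(i))`.
#' @param delta_rule `"constant"` (default) or `"loglinear"`.
#' @param prob_floor Lower bound applied to all size probabilities so that
#'   negative-log weights stay finite (default 1e-12).
#' @return A `weibull_size_model` object.
#' @export
weibull_size_model <- function(eta, delta, delta_rule = c("constant", "loglinear"),
                               prob_floor = 1e-12) {
  delta_rule <- match.arg(delta_rule)
  stopifnot(eta > 0, delta > 0, prob_floor > 0, prob_floor < 1)
  structure(list(eta = eta, delta = delta, delta_rule = delta_rule,
                 prob_floor = prob_floor),
            class = "weibull_size_model")
}

#' @export
print.weibull_size_model <- function(x, ...) {
  cat("Weibull size model: eta =", format(x$eta, digits = 5),
      ", delta =", format(x$delta, digits = 5),
      paste0("(", x$delta_rule, ")"), "\n")
  invisible(x)
}

model_shape <- function(model, isoform_length) {
  if (model$delta_rule == "constant") model$delta
  else model$delta * log(pmax(isoform_length, 2))
}

#' Fit the Weibull size model by maximum likelihood
#'
#' Estimates the scale `eta` and shape from observed fragment lengths. With
#' fewer than 30 observations (or degenerate zero-variance input) the fit
#' falls back to the supplied defaults with a warning. When per-observation
#' isoform lengths are supplied and `delta_rule = "loglinear"`, the shape
#' coefficient of `a * log(len(i))` is estimated instead of a single global
#' shape.
#'
#' @param fragment_lengths Integer vector of observed fragment sizes.
#' @param isoform_lengths Optional vector (same length) of source-isoform
#'   lengths, enabling the log-linear shape rule.
#' @param delta_rule `"constant"` (default) or `"loglinear"`.
#' @param fallback Model returned when the fit is impossible
#'   (default `weibull_size_model(eta = 200, delta = 1.8)`).
#' @param prob_floor Probability floor for the returned model.
#' @param truncation Optional size-selection window `c(lo, hi)`. When given,
#'   the observed sizes are treated as a truncated sample of the underlying
#'   fragmentation distribution and the likelihood is conditioned on the
#'   window, recovering the pre-selection shape and scale; sequencing
#'   libraries are size-selected, so the assembler fits with the empirical
#'   window by default.
#' @return A `weibull_size_model`.
#' @export
fit_size_model <- function(fragment_lengths, isoform_lengths = NULL,
                           delta_rule = c("constant", "loglinear"),
                           fallback = weibull_size_model(200, 1.8),
                           prob_floor = 1e-12, truncation = NULL) {
  delta_rule <- match.arg(delta_rule)
  x <- as.numeric(fragment_lengths)
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 30L || stats::sd(x) == 0) {
    warning("size-model fit needs >= 30 varying observations; using defaults")
    return(fallback)
  }
  if (!is.null(truncation)) {
    lo <- truncation[1L]; hi <- truncation[2L]
    stopifnot(lo < hi)
    x <- x[x >= lo & x <= hi]
    if (length(x) < 30L) {
      warning("too few observations inside the truncation window; using defaults")
      return(fallback)
    }
    init <- suppressWarnings(fitdistrplus::fitdist(x, "weibull"))$estimate
    nll <- function(par) {
      sh <- exp(par[1L]); sc <- exp(par[2L])
      z <- pweibull(hi, sh, sc) - pweibull(lo, sh, sc)
      if (z <= 0) return(1e10)
      -sum(dweibull(x, sh, sc, log = TRUE)) + length(x) * log(z)
    }
    fit <- optim(log(c(init["shape"], init["scale"])), nll,
                 method = "L-BFGS-B",
                 lower = log(c(0.2, 10)), upper = log(c(50, 1e5)))
    return(weibull_size_model(exp(fit$par[2L]), exp(fit$par[1L]),
                              prob_floor = prob_floor))
  }
  if (delta_rule == "loglinear" && !is.null(isoform_lengths)) {
    ll <- as.numeric(isoform_lengths)
    stopifnot(length(ll) == length(fragment_lengths))
    ll <- ll[is.finite(x) & x > 0]
    nll <- function(par) {
      a <- exp(par[1L]); eta <- exp(par[2L])
      -sum(dweibull(x, shape = a * log(pmax(ll, 2)), scale = eta, log = TRUE))
    }
    fit <- optim(c(log(0.3), log(mean(x))), nll, method = "Nelder-Mead")
    return(weibull_size_model(exp(fit$par[2L]), exp(fit$par[1L]),
                              delta_rule = "loglinear", prob_floor = prob_floor))
  }
  fit <- suppressWarnings(fitdistrplus::fitdist(x, "weibull"))
  weibull_size_model(unname(fit$estimate["scale"]), unname(fit$estimate["shape"]),
                     prob_floor = prob_floor)
}

#' Size probability d(x)
#'
#' Weibull density at `x` with the isoform's shape and the experiment-wide
#' scale, floored at `prob_floor` (and capped at 1 so negative-log weights
#' are non-negative). Sizes are integer base counts, so the density is
#' evaluated at `max(x, 0.5)`: the half-base continuity correction keeps the
#' probability of a zero-length gap finite (abutting fragments are a real
#' feature of size-selected libraries) instead of degenerating to 0 (shape
#' > 1) or infinity (shape < 1) at the x = 0 singularity.
#'
#' @param model A `weibull_size_model`.
#' @param isoform_length Length of the isoform the copy belongs to (used only
#'   under the log-linear shape rule).
#' @param x Size (bases), `x >= 0`; vectorized.
#' @return Numeric vector of probabilities in `[prob_floor, 1]`.
#' @export
size_density <- function(model, isoform_length, x) {
  sh <- model_shape(model, isoform_length)
  d <- dweibull(pmax(x, 0.5), shape = sh, scale = model$eta)
  pmin(pmax(d, model$prob_floor), 1)
}

#' Likelihood of a transcript copy
#'
#' Geometric mean of the size probabilities of all fragments and all gaps in
#' the copy (gaps include the leading TSS-to-first-fragment and trailing
#' last-fragment-to-TES gaps), computed in log space.
#'
#' @param copy A `transcript_copy` (list with `fragment_lengths` and
#'   `gap_lengths`), or any list with those two fields.
#' @param model A `weibull_size_model`.
#' @param isoform_length Isoform length for the shape rule.
#' @return The likelihood L(t) in (0, 1].
#' @export
copy_likelihood <- function(copy, model, isoform_length) {
  fl <- copy$fragment_lengths
  gl <- copy$gap_lengths
  if (length(fl) == 0L) stop("copy has no fragments")
  if (length(gl) != length(fl) + 1L)
    stop("copy must have |fragments| + 1 gaps")
  lp <- log(size_density(model, isoform_length, c(fl, gl)))
  exp(mean(lp))
}

#' Effectiveness p-value of a copy likelihood
#'
#' Probability mass of the size density over the region I(t) where the density
#' does not exceed `L`: the tail probability of a highest-density-region test.
#' For unimodal Weibull densities the region has at most two crossing points,
#' found by root-finding; the probability uses the closed-form CDF.
#'
#' @param model A `weibull_size_model`.
#' @param isoform_length Isoform length for the shape rule.
#' @param L Copy likelihood, `L > 0`.
#' @return p in `[0, 1]`; monotone non-decreasing in `L`.
#' @export
effectiveness_pvalue <- function(model, isoform_length, L) {
  stopifnot(L > 0)
  sh <- model_shape(model, isoform_length)
  eta <- model$eta
  dfun <- function(x) dweibull(x, shape = sh, scale = eta)
  if (sh <= 1) {
    # monotone decreasing density: I(t) = [x2, Inf)
    d0 <- if (sh == 1) 1 / eta else Inf
    if (L >= d0) return(1)
    x2 <- upper_crossing(dfun, L, lo = 0, start = eta)
    return(1 - pweibull(x2, shape = sh, scale = eta))
  }
  mode <- eta * ((sh - 1) / sh)^(1 / sh)
  dmax <- dfun(mode)
  if (L >= dmax) return(1)
  x1 <- uniroot(function(x) dfun(x) - L, lower = 0, upper = mode,
                tol = 1e-12)$root
  x2 <- upper_crossing(dfun, L, lo = mode, start = mode * 2)
  pweibull(x1, shape = sh, scale = eta) +
    (1 - pweibull(x2, shape = sh, scale = eta))
}

upper_crossing <- function(dfun, L, lo, start) {
  hi <- start
  while (dfun(hi) > L) hi <- hi * 2
  uniroot(function(x) dfun(x) - L, lower = lo, upper = hi, tol = 1e-12)$root
}

#' Classify a copy as effective or ineffective
#'
#' A copy is effective when the effectiveness p-value of its likelihood
#' exceeds `tau`, so that `tau` bounds the probability of falsely calling a
#' model-typical copy ineffective. `paper_literal = TRUE` switches to the
#' opposite inequality (effective iff p <= tau).
#'
#' @param copy A `transcript_copy` (or list with `fragment_lengths`,
#'   `gap_lengths`).
#' @param model A `weibull_size_model`.
#' @param isoform_length Isoform length for the shape rule.
#' @param tau Significance level in (0,1); default 0.05.
#' @param paper_literal Use the literal printed inequality direction.
#' @return Logical.
#' @export
classify_effective <- function(copy, model, isoform_length, tau = 0.05,
                               paper_literal = FALSE) {
  stopifnot(tau > 0, tau < 1)
  L <- copy_likelihood(copy, model, isoform_length)
  p <- effectiveness_pvalue(model, isoform_length, L)
  if (paper_literal) p <= tau else p > tau
}

#' Construct a transcript copy record
#'
#' @param locus_id Locus identifier.
#' @param exon_path Integer vector of splice-graph exon indices (TSS to TES).
#' @param fragment_ids Character vector of member fragment ids, in transcript
#'   order.
#' @param fragment_lengths Integer vector of fragment sizes (transcript
#'   coordinates).
#' @param gap_lengths Integer vector of gap sizes, length
#'   `length(fragment_ids) + 1` (TSS gap, between-fragment gaps, TES gap).
#' @return A `transcript_copy` list.
#' @export
transcript_copy <- function(locus_id, exon_path, fragment_ids,
                            fragment_lengths, gap_lengths) {
  stopifnot(length(gap_lengths) == length(fragment_ids) + 1L,
            length(fragment_lengths) == length(fragment_ids),
            all(gap_lengths >= 0))
  structure(list(locus_id = locus_id, exon_path = exon_path,
                 fragment_ids = fragment_ids,
                 fragment_lengths = as.integer(fragment_lengths),
                 gap_lengths = as.integer(gap_lengths),
                 likelihood = NA_real_, pvalue = NA_real_, effective = NA),
            class = "transcript_copy")
}

#' Per-isoform abundance measures
#'
#' Computes, for each isoform, eTPM from its effective-copy count and the
#' read-count-based reference measures FPKM and TPM:
#' \deqn{eTPM_i = eT_i \cdot 10^6 / \sum_j eT_j}
#' \deqn{FPKM_i = N_i \cdot 10^9 / (len(i) \cdot N)}
#' \deqn{TPM_i = \frac{N_i\, len(r) / len(i)}{\sum_j N_j\, len(r)/len(j)} \cdot 10^6}
#' Zero totals yield all-zero columns.
#'
#' @param isoform_stats A data.frame/data.table with columns `isoform_id`,
#'   `length`, `eT`, `N` (fragment count); optional `gene_id` and descriptive
#'   columns are carried through.
#' @param expected_fragment_length Expected fragment length `len(r)` used by
#'   the TPM normalization (default 250).
#' @return An abundance `data.table` with added columns `eTPM`, `FPKM`, `TPM`.
#' @export
compute_abundance <- function(isoform_stats, expected_fragment_length = 250) {
  dt <- data.table::as.data.table(isoform_stats)
  if (nrow(dt) == 0L) {
    dt[, `:=`(eTPM = numeric(), FPKM = numeric(), TPM = numeric())]
    return(dt[])
  }
  stopifnot(all(dt$length > 0))
  if (any(dt$eT < 0) || any(dt$N < 0)) stop("negative counts")
  if (!"gene_id" %in% names(dt)) dt[, gene_id := isoform_id]
  tot_eT <- sum(dt$eT)
  dt[, eTPM := if (tot_eT > 0) eT * 1e6 / tot_eT else 0]
  tot_N <- sum(dt$N)
  dt[, FPKM := if (tot_N > 0) N * 1e9 / (length * tot_N) else 0]
  lr <- expected_fragment_length
  denom <- sum(dt$N * lr / dt$length)
  dt[, TPM := if (denom > 0) (N * lr / length) * 1e6 / denom else 0]
  dt[]
}

#' Serialize model parameters to a YAML-style list
#' @param model A `weibull_size_model`.
#' @return A plain list suitable for `yaml::as.yaml`.
#' @export
size_model_params <- function(model) {
  list(eta = model$eta, delta = model$delta, delta_rule = model$delta_rule,
       prob_floor = model$prob_floor)
}

#' Restore a model from serialized parameters
#' @param params A list as produced by [size_model_params()].
#' @return A `weibull_size_model`.
#' @export
size_model_from_params <- function(params) {
  weibull_size_model(params$eta, params$delta, params$delta_rule,
                     params$prob_floor)
}
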