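#' Benjamini-Hochberg step-up adjustment
#'
#' Own implementation of the BH step-up procedure:
#' `adj_(i) = min_{k >= i} min(1, m p_(k) / k)` for ordered p-values, mapped
#' back to the input order. Monotone and order-preserving.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` passed through).
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  ok <- !is.na(p)
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out[ok] <- adj
  out
}

#' Moderated two-group differential abundance test
#'
#' Per-feature two-sample comparison on a log2 matrix. In `"eb"` mode the
#' pooled per-feature variance is shrunk towards a common prior with an
#' empirical-Bayes scheme: the prior degrees of freedom `d0` and prior
#' variance `s0^2` are estimated by the method of moments on `log s^2`
#' across features (scaled-F model), the posterior variance is
#' `(d0 s0^2 + d s^2) / (d0 + d)` and the moderated t statistic has
#' `d0 + d` degrees of freedom. `"welch"` mode runs ordinary Welch t tests
#' as a non-moderated cross-check. Per-feature complete-case analysis;
#' two-sided p-values; BH adjustment appended.
#'
#' @param x a log2 [QuantMatrix-class] (imputed, or with missing values
#'   handled complete-case per feature).
#' @param group1,group2 sample selections: either vectors of sample ids or a
#'   single compartment name found in `colData(x)$compartment`. The reported
#'   `log2fc` is group1 minus group2.
#' @param moderation `"eb"` or `"welch"`.
#' @param alpha BH-adjusted significance level for the `significant` flag.
#' @param fcThreshold fold-change threshold (linear scale) for the
#'   `significant` flag.
#' @param priorDf,priorVar optional overrides of the estimated `(d0, s0^2)`
#'   (eb mode); `priorDf = Inf` yields a z-test against `s0^2`, `priorDf = 0`
#'   the ordinary pooled t-test.
#'
#' @return `data.frame`: `feature_id`, `log2fc`, `t_stat`, `df_total`, `p`,
#'   `adj_p`, `significant`, `degenerate`. Attributes `"prior_df"` and
#'   `"prior_var"` report the EB prior. The `degenerate` flag marks
#'   zero-variance features with unequal means under `"welch"`.
#' @export
moderatedTTest <- function(x, group1, group2, moderation = c("eb", "welch"),
                           alpha = 0.05, fcThreshold = 1.5,
                           priorDf = NULL, priorVar = NULL) {
  moderation <- match.arg(moderation)
  v <- quantValues(x)
  s1 <- .resolveSamples(x, group1)
  s2 <- .resolveSamples(x, group2)
  if (length(s1) < 2L || length(s2) < 2L)
    stop("need >= 2 samples per group")
  x1 <- v[, s1, drop = FALSE]
  x2 <- v[, s2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  ss1 <- rowSums((x1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x2 - m2)^2, na.rm = TRUE)
  fc <- m1 - m2
  usable <- n1 >= 2L & n2 >= 2L
  d <- n1 + n2 - 2
  s2pool <- ifelse(usable, (ss1 + ss2) / d, NA_real_)
  degenerate <- rep(FALSE, nrow(v))
  if (moderation == "eb") {
    prior <- .ebPrior(s2pool[usable & s2pool > 0], d[usable & s2pool > 0])
    d0 <- if (!is.null(priorDf)) priorDf else prior$d0
    s02 <- if (!is.null(priorVar)) priorVar else prior$s02
    if (is.infinite(d0)) {
      stilde <- rep(s02, nrow(v))
      dft <- rep(Inf, nrow(v))
    } else {
      stilde <- (d0 * s02 + d * s2pool) / (d0 + d)
      dft <- d0 + d
    }
    se <- sqrt(stilde * (1 / n1 + 1 / n2))
    tst <- fc / se
    p <- ifelse(is.infinite(dft), 2 * pnorm(-abs(tst)),
                2 * pt(-abs(tst), dft))
    zero <- usable & se == 0
    p[zero & fc == 0] <- 1
    tst[zero & fc == 0] <- 0
  } else {
    v1 <- ifelse(n1 > 1, ss1 / (n1 - 1), NA_real_)
    v2 <- ifelse(n2 > 1, ss2 / (n2 - 1), NA_real_)
    se2 <- v1 / n1 + v2 / n2
    tst <- fc / sqrt(se2)
    dft <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(tst), dft)
    zero <- usable & se2 == 0
    p[zero & fc == 0] <- 1
    tst[zero & fc == 0] <- 0
    p[zero & fc != 0] <- 0
    degenerate[zero & fc != 0] <- TRUE
    d0 <- NA_real_; s02 <- NA_real_
  }
  p[!usable] <- NA_real_
  adj <- bhAdjust(p)
  res <- data.frame(
    feature_id = rownames(v), log2fc = fc, t_stat = tst,
    df_total = if (length(dft) == 1L) rep(dft, nrow(v)) else dft,
    p = p, adj_p = adj,
    significant = !is.na(adj) & adj <= alpha & abs(fc) >= log2(fcThreshold),
    degenerate = degenerate,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "prior_df") <- d0
  attr(res, "prior_var") <- s02
  attr(res, "contrast") <- "log2fc = group1 - group2"
  res
}

# method-of-moments estimation of the scaled-F prior on log s^2
.ebPrior <- function(s2, d) {
  if (length(s2) < 2L)
    return(list(d0 = 0, s02 = if (length(s2)) mean(s2) else 0))
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(d / 2))
  if (is.na(evar) || evar <= 0)
    # no excess dispersion beyond chi-square sampling noise: the variances
    # are exchangeable and the prior collapses to their mean
    return(list(d0 = Inf, s02 = mean(s2)))
  d0 <- 2 * .trigammaInverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton inversion of the trigamma function
.trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

# sample ids from a vector of ids or a compartment name
.resolveSamples <- function(x, sel) {
  ids <- colnames(quantValues(x))
  if (length(sel) == 1L && sel %in% COMPARTMENTS) {
    comp <- .compartments(x, require_all = FALSE)
    return(ids[comp == sel])
  }
  missing <- setdiff(sel, ids)
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  sel
}

#' Compartment-unique differential signature
#'
#' Set logic for proteins uniquely regulated in one compartment relative to
#' both of the others (e.g. the PC-unique signature): `up` contains features
#' significant with `log2fc >= log2(fc)` in *both* contrasts (compartment
#' minus other), `down` symmetrically with `log2fc <= -log2(fc)`. The two
#' sets are disjoint by construction.
#'
#' @param daVsA,daVsB two [moderatedTTest()] tables whose group1 is the
#'   compartment of interest (e.g. PC vs NAT and PC vs TUMOR).
#' @param fc fold-change threshold (linear).
#' @param alpha BH-adjusted p-value threshold.
#' @return list with character vectors `up` and `down`.
#' @export
pcUniqueSignature <- function(daVsA, daVsB, fc = 1.5, alpha = 0.05) {
  common <- intersect(daVsA$feature_id, daVsB$feature_id)
  if (length(common) < length(daVsA$feature_id) ||
      length(common) < length(daVsB$feature_id))
    warning("feature universes differ; intersecting")
  a <- daVsA[match(common, daVsA$feature_id), ]
  b <- daVsB[match(common, daVsB$feature_id), ]
  lfc <- log2(fc)
  sig_a <- !is.na(a$adj_p) & a$adj_p <= alpha
  sig_b <- !is.na(b$adj_p) & b$adj_p <= alpha
  up <- common[sig_a & sig_b & a$log2fc >= lfc & b$log2fc >= lfc]
  down <- common[sig_a & sig_b & a$log2fc <= -lfc & b$log2fc <= -lfc]
  list(up = up, down = down)
}
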