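#' Incidence frequency counts
#'
#' `f[j]` is the number of distinct mutations present in exactly `j` of the
#' `n` samples.
#'
#' @param presence Logical mutation-by-sample matrix (see
#'   [presence_matrix()]).
#' @return Integer vector of length `ncol(presence)`.
#' @export
freq_counts <- function(presence) {
  n <- ncol(presence)
  j <- rowSums(presence)
  tabulate(j[j >= 1], nbins = n)
}

#' Exact subsampling expectation of the accumulation curve
#'
#' For `t <= n` samples drawn without replacement, the expected number of
#' distinct mutations is
#' \deqn{E[S(t)] = \sum_j f_j \left(1 - \binom{n-j}{t} / \binom{n}{t}\right),}
#' the exact mean over all size-`t` sample subsets.
#'
#' @param f Frequency counts (from [freq_counts()]).
#' @param n Number of samples the counts were taken from.
#' @param t Subset sizes (each `<= n`).
#' @return Numeric vector `E[S(t)]`.
#' @export
sac_interpolate <- function(f, n, t) {
  if (any(t > n)) stop("interpolation requires t <= n")
  vapply(t, function(tt)
    sum(f * (1 - choose(n - seq_along(f), tt) / choose(n, tt))), numeric(1))
}

# Pade approximant [M-1/M] of a power series with coefficients b0..b_{2M-1}
# (numerator degree M-1, denominator degree M, q0 = 1)
.pade <- function(b, M) {
  L <- M - 1
  # q solves: b[L+j] + sum_k q_k b[L+j-k] = 0, j = 1..M (1-based: b[i] = b_{i-1})
  A <- matrix(0, M, M)
  rhs <- numeric(M)
  for (j in seq_len(M)) {
    for (k in seq_len(M)) {
      idx <- L + j - k
      A[j, k] <- if (idx >= 0) b[idx + 1] else 0
    }
    rhs[j] <- -b[L + j + 1]
  }
  q <- solve(A, rhs)
  q <- c(1, q)
  p <- vapply(0:L, function(i)
    sum(b[seq_len(i + 1)] * rev(q[seq_len(i + 1)])), numeric(1))
  list(p = p, q = q)
}

.polyval <- function(coef, x) {
  # coef[1] + coef[2] x + ...
  out <- 0
  for (i in rev(seq_along(coef))) out <- out * x + coef[i]
  out
}

#' Species-accumulation extrapolation of mutation discovery
#'
#' Combines the exact subsampling expectation for `t <= n` with an
#' extrapolation of the unseen-mutation count for `t > n`. Two extrapolators
#' are provided:
#' \describe{
#'   \item{`"incidence"` (default)}{the Colwell--Mao incidence-based
#'     unseen-species extrapolator: with the bias-corrected Chao2 estimate
#'     of the unseen count \eqn{\hat f_0 = \frac{n-1}{n} f_1^2 / (2 f_2)},
#'     the expected number of new mutations after `m` additional samples is
#'     \eqn{\hat f_0 [1 - (1 - f_1/(n \hat f_0 + f_1))^{m}]}. For presence
#'     data over a handful of sampling units (the multisite regime, n of 2-6)
#'     this estimator is asymptotically unbiased under independent
#'     per-sample presence and recovers the Bernoulli closed form exactly in
#'     expectation.}
#'   \item{`"pade"`}{a Good--Toulmin power-series extrapolation stabilized
#'     by a rational-function (Pade) approximation: the alternating series
#'     \eqn{\Delta(x) = \sum_j (-1)^{j+1} f_j x^j} (`x = (t-n)/n`) diverges
#'     beyond `x = 1`; a `[M-1/M]` approximant in
#'     \eqn{\Delta(x) = x P(x)/Q(x)} keeps it finite with a horizontal
#'     asymptote. The order is the largest `M` with `2M <= min(mt, n)` whose
#'     extrapolant is positive, non-decreasing, and pole-free on
#'     `(n, t_max]`, falling back to lower orders and ultimately to
#'     `f_1 x/(1 + x f_2/f_1)`. With very few sampling units (n <= 6) the
#'     approximant is built from too few coefficients to be reliable at long
#'     range, which is why it is not the default here.}
#' }
#'
#' @param f Frequency counts.
#' @param n Number of samples observed.
#' @param t_max Largest sample count extrapolated to (default 100; the value
#'   at `t_max` is reported as the asymptote, i.e. a lower bound on the total
#'   mutation burden).
#' @param mt Maximum number of power-series terms used by `"pade"`
#'   (default 20).
#' @param method `"incidence"` or `"pade"`.
#' @param bootstrap_reps Bootstrap replicates over mutations for the
#'   confidence band (default 0 = none).
#' @param seed Seed for the bootstrap.
#' @return Object of class `accumulation_curve`: list with `f`, `n`,
#'   `observed` (distinct mutations at `n`), `t`, `predicted`, `asymptote`,
#'   `order` (Pade denominator degree; NA for `"incidence"`), `method`, and
#'   optionally `ci` (2 x t_max matrix of 2.5/97.5 percent bootstrap
#'   quantiles).
#' @export
accumulation_extrapolate <- function(f, n, t_max = 100, mt = 20,
                                     method = c("incidence", "pade"),
                                     bootstrap_reps = 0, seed = 1) {
  method <- match.arg(method)
  if (n < 2) stop("need at least 2 samples")
  if (length(f) < n) f <- c(f, rep(0, n - length(f)))
  if (sum(f) == 0) stop("all frequency counts are zero")
  t <- seq_len(t_max)
  fit_fun <- function(ff) {
    if (t_max <= n) return(list(delta = function(m) 0, order = NA_integer_))
    if (method == "incidence") .sac_colwell(ff, n) else .sac_fit(ff, n, t_max, mt)
  }
  fit <- fit_fun(f)
  pred <- ifelse(t <= n, sac_interpolate(f, n, pmin(t, n)),
                 sum(f) + fit$delta(t - n))
  out <- structure(list(f = f, n = n, observed = sum(f), t = t,
                        predicted = pred, asymptote = pred[t_max],
                        order = fit$order, method = method),
                   class = "accumulation_curve")
  if (bootstrap_reps > 0) {
    set.seed(seed)
    js <- rep(seq_along(f), f)
    boot <- matrix(NA_real_, bootstrap_reps, t_max)
    for (r in seq_len(bootstrap_reps)) {
      fb <- tabulate(sample(js, replace = TRUE), nbins = n)
      fitb <- fit_fun(fb)
      boot[r, ] <- ifelse(t <= n, sac_interpolate(fb, n, pmin(t, n)),
                          sum(fb) + fitb$delta(t - n))
    }
    out$ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
  }
  out
}

# Colwell-Mao incidence extrapolator; delta(m) = expected new species after
# m additional sampling units
.sac_colwell <- function(f, n) {
  f1 <- f[1]
  f2 <- if (length(f) >= 2) f[2] else 0
  if (f1 == 0) return(list(delta = function(m) rep(0, length(m)),
                           order = NA_integer_))
  f0 <- if (f2 > 0) ((n - 1) / n) * f1^2 / (2 * f2) else
    ((n - 1) / n) * f1 * (f1 - 1) / 2
  if (f0 <= 0) return(list(delta = function(m) rep(0, length(m)),
                           order = NA_integer_))
  rate <- f1 / (n * f0 + f1)
  list(delta = function(m) f0 * (1 - (1 - rate)^m), order = NA_integer_)
}

.sac_fit <- function(f, n, t_max, mt) {
  J <- min(mt, n)
  b <- (-1)^(seq_len(J) + 1) * f[seq_len(J)]   # Delta(x) = x * R(x); b = R coefs
  xg <- seq(1e-6, (t_max - n) / n, length.out = 200)
  for (M in rev(seq_len(floor(J / 2)))) {
    if (2 * M > J) next
    pq <- tryCatch(.pade(b, M), error = function(e) NULL)
    if (is.null(pq)) next
    qv <- .polyval(pq$q, xg)
    if (any(qv <= 0)) next                       # pole or sign flip on the grid
    dv <- xg * .polyval(pq$p, xg) / qv
    if (any(dv < -1e-9) || any(diff(dv) < -1e-9)) next
    delta <- function(m) {
      x <- m / n
      x * .polyval(pq$p, x) / .polyval(pq$q, x)
    }
    return(list(delta = delta, order = M))
  }
  f1 <- max(f[1], 0)
  f2 <- if (length(f) >= 2) f[2] else 0
  if (f1 > 0 && f2 > 0)
    return(list(delta = function(m) f1 * (m / n) / (1 + (m / n) * f2 / f1),
                order = 0L))
  list(delta = function(m) f1 * (m / n) / (1 + m / n), order = 0L)
}

#' @export
print.accumulation_curve <- function(x, ...) {
  lab <- if (identical(x$method, "pade"))
    paste0("pade, order ", x$order) else "incidence"
  cat("accumulation_curve: observed", x$observed, "mutations in", x$n,
      "samples; asymptote at t =", max(x$t), "is", round(x$asymptote, 1),
      paste0("(", lab, ")"), "\n")
  invisible(x)
}

#' Fraction of the total mutation burden detected with k samples
#'
#' `fraction(k)` is the mean number of distinct mutations observed over all
#' size-`k` sample subsets (the exact interpolation), divided by the curve's
#' asymptote (the extrapolated lower bound on the total burden).
#'
#' @param curve `accumulation_curve`.
#' @return data.frame `k`, `fraction` for `k = 1..n`.
#' @export
detected_fraction_curve <- function(curve) {
  if (curve$asymptote <= 0) stop("asymptote must be positive")
  k <- seq_len(curve$n)
  data.frame(k = k,
             fraction = sac_interpolate(curve$f, curve$n, k) / curve$asymptote)
}

#' Train-on-3 / test-on-4 validation of the extrapolation model
#'
#' For each patient with at least four samples, the model is fitted on every
#' 3-sample subset of the patient's first four samples and extrapolated one
#' step to `t = 4`; the average prediction is paired with the observed number
#' of distinct mutations in those four samples.
#'
#' @param presence_list Named list of logical mutation-by-sample matrices,
#'   one per patient (at least 4 columns each; extra columns beyond the
#'   fourth are ignored).
#' @param mt Maximum power-series terms (default 20).
#' @param method Extrapolator (see [accumulation_extrapolate()]).
#' @return data.frame `patient_id`, `predicted`, `observed`.
#' @export
validate_extrapolation <- function(presence_list, mt = 20,
                                   method = c("incidence", "pade")) {
  method <- match.arg(method)
  out <- lapply(names(presence_list), function(p) {
    m <- presence_list[[p]]
    if (ncol(m) < 4) return(NULL)
    m <- m[, 1:4, drop = FALSE]
    m <- m[rowSums(m) > 0, , drop = FALSE]
    preds <- vapply(1:4, function(drop_col) {
      tr <- m[, -drop_col, drop = FALSE]
      f <- freq_counts(tr)
      if (sum(f) == 0) return(NA_real_)
      fit <- if (method == "incidence") .sac_colwell(f, 3) else
        .sac_fit(f, 3, t_max = 4, mt = mt)
      sum(f) + fit$delta(1)
    }, numeric(1))
    data.frame(patient_id = p, predicted = mean(preds, na.rm = TRUE),
               observed = nrow(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
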