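#' Tarone-modified distribution-free Benjamini-Yekutieli Q values
#'
#' Multiple-testing adjustment for discrete p-values under arbitrary
#' dependence.  The Benjamini-Yekutieli procedure inflates each p-value by
#' `m * H(m)` (with `H` the harmonic number) over its rank; the Tarone
#' modification replaces the total test count with the number of tests
#' that could possibly attain the significance level under consideration,
#' which for discrete statistics is the count of tests whose smallest
#' attainable p-value (`minp`) does not exceed the p-value at hand.
#'
#' With p-values sorted ascending, `m_k = #\{j : minp_j <= p_(k)\}`,
#' the raw value is `q_(k) = p_(k) * m_k * H(m_k) / k`, and the reported
#' `Q_(k) = min_{l >= k} q_(l)`, capped at 1.  When all `minp` are zero
#' the procedure reduces exactly to standard Benjamini-Yekutieli.
#'
#' `tarone_by_log10q()` is the log10-space workhorse used by the peak
#' caller (linear-scale p-values for deep ChIP peaks underflow doubles);
#' `tarone_by_qvalues()` is the linear-scale convenience wrapper.
#'
#' @param p p-values in `[0, 1]`.
#' @param minp smallest attainable p-value of each test (same length;
#'   `minp_j <= p_j`).  Defaults to all zero (plain Benjamini-Yekutieli).
#' @return vector of Q values (estimated FDR) in the input order.
#' @export
#' @examples
#' tarone_by_qvalues(c(0.01, 0.02, 0.03))          # all 0.055
#' tarone_by_qvalues(c(0.001, 0.5), c(0.0005, 0.4)) # 0.001, 0.75
tarone_by_qvalues <- function(p, minp = rep(0, length(p))) {
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  if (any(minp < 0 | minp > 1)) stop("minp outside [0, 1]")
  10^tarone_by_log10q(log10(p), log10(minp))
}

#' @rdname tarone_by_qvalues
#' @param log10_p,log10_minp log10-scale p-values and attainable minima.
#' @return for `tarone_by_log10q()`, log10 Q values (all `<= 0`).
#' @export
tarone_by_log10q <- function(log10_p, log10_minp = rep(-Inf, length(log10_p))) {
  n <- length(log10_p)
  if (length(log10_minp) != n) stop("p and minp lengths differ")
  if (n == 0) return(numeric(0))
  if (any(log10_p > 0)) stop("p-values outside [0, 1]")
  if (any(log10_minp > log10_p + 1e-9))
    stop("minp exceeds p for the same test")
  ord <- order(log10_p)
  lp <- log10_p[ord]
  m <- findInterval(lp, sort(log10_minp))   # tests attainable at p_(k)
  H <- cumsum(1 / seq_len(n))
  lq <- lp + log10(m) + log10(H[m]) - log10(seq_len(n))
  lq <- rev(cummin(rev(lq)))                # step-up monotonization
  lq <- pmin(lq, 0)                         # cap Q at 1
  out <- numeric(n)
  out[ord] <- lq
  out
}
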