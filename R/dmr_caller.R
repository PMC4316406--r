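#' Normalized log2 methylation ratio (M value)
#'
#' M = log2((k1/n1) / (k2/n2)): the library-size-normalized log2 ratio of
#' embryo over endosperm read counts in a region. Undefined (NA) when either
#' count is zero; those regions are handled by the zero-count rule of
#' [call_dmrs()] instead.
#'
#' @param k1,k2 region read counts (embryo, endosperm).
#' @param n1,n2 library sizes: total mapped reads per tissue.
#' @return numeric vector (NA where a count is zero).
#' @export
m_value <- function(k1, k2, n1, n2) {
  stopifnot(all(k1 >= 0), all(k2 >= 0), all(n1 > 0), all(n2 > 0))
  ifelse(k1 > 0 & k2 > 0, log2((k1 / n1) / (k2 / n2)), NA_real_)
}

#' Conditional binomial p-value for differential counts
#'
#' Under the null hypothesis that a region is equally methylated in both
#' tissues, the embryo count conditioned on the regional total K = k1 + k2 is
#' Binomial(K, p0) with p0 = n1/(n1 + n2). The two-sided p-value is the
#' minimal-likelihood sum: the total probability of all outcomes j in 0..K
#' whose point probability does not exceed that of the observed k1 (ties
#' included). Full summation over 0..K is used for K <= `exact_limit`;
#' above that the same quantity is computed as two binomial tails with the
#' opposite-side cutoff located by binary search on the unimodal point
#' probabilities, which is equally exact but O(log K). K = 0 returns p = 1.
#'
#' @param k1,k2 region read counts (vectors recycle).
#' @param n1,n2 library sizes.
#' @param method "auto" (full summation up to `exact_limit`, tail method
#'   above), "exact" (always full summation) or "tail" (always the
#'   binary-search two-tail method).
#' @param exact_limit largest K handled by full summation under "auto".
#' @return numeric vector of p-values in \[0, 1\].
#' @export
region_p_value <- function(k1, k2, n1, n2, method = c("auto", "exact",
                                                      "tail"),
                           exact_limit = 10000) {
  method <- match.arg(method)
  stopifnot(all(k1 >= 0), all(k2 >= 0), n1 > 0, n2 > 0)
  m <- max(length(k1), length(k2))
  k1 <- rep_len(k1, m); k2 <- rep_len(k2, m)
  p0 <- n1 / (n1 + n2)
  K <- k1 + k2
  p <- numeric(m)
  for (i in seq_len(m)) {
    if (K[i] == 0) { p[i] <- 1; next }
    use_exact <- method == "exact" ||
      (method == "auto" && K[i] <= exact_limit)
    p[i] <- if (use_exact) p_exact_condbinom(k1[i], K[i], p0)
            else p_tail_condbinom(k1[i], K[i], p0)
  }
  p
}

# exact minimal-likelihood two-sided binomial p by full summation
p_exact_condbinom <- function(k, K, p0) {
  probs <- stats::dbinom(0:K, K, p0)
  obs <- probs[k + 1]
  # relative tolerance guards against ties lost to floating-point noise
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Same minimal-likelihood region expressed as two binomial tails: the
# binomial pmf is unimodal, so {j : P(j) <= P(k)} is a left tail plus a
# right tail; the cutoff on the side opposite the observation is found by
# binary search on the monotone flank. O(log K) instead of O(K).
p_tail_condbinom <- function(k, K, p0) {
  t <- stats::dbinom(k, K, p0) * (1 + 1e-7)
  mode <- floor((K + 1) * p0)
  if (stats::dbinom(mode, K, p0) <= t) return(1)
  if (k < mode) {
    right <- if (stats::dbinom(K, K, p0) > t) 0 else {
      lo <- mode; hi <- K  # smallest j on the decreasing flank with P <= t
      while (lo < hi) {
        mid <- (lo + hi) %/% 2
        if (stats::dbinom(mid, K, p0) <= t) hi <- mid else lo <- mid + 1
      }
      stats::pbinom(lo - 1, K, p0, lower.tail = FALSE)
    }
    p <- stats::pbinom(k, K, p0) + right
  } else {
    left <- if (stats::dbinom(0, K, p0) > t) 0 else {
      lo <- 0; hi <- mode  # smallest j on the increasing flank with P > t
      while (lo < hi) {
        mid <- (lo + hi) %/% 2
        if (stats::dbinom(mid, K, p0) > t) hi <- mid else lo <- mid + 1
      }
      stats::pbinom(lo - 1, K, p0)
    }
    p <- stats::pbinom(k - 1, K, p0, lower.tail = FALSE) + left
  }
  min(1, p)
}

#' Call differentially methylated regions
#'
#' Applies the normalized-log2 + p-value rule to every methylation region:
#' a region is up-methylated in embryo when (M > 0, or the endosperm count is
#' 0 with a positive embryo count) and p < `alpha`; symmetrically for
#' endosperm; otherwise it is not differential. The comparison with `alpha`
#' is strict (p exactly equal to `alpha` is not differential).
#'
#' @param regions region data.frame from [unify()] (or any table carrying
#'   `k_embryo`, `k_endosperm`).
#' @param n_embryo,n_endosperm library sizes (total mapped reads).
#' @param alpha significance level (default 0.001).
#' @param method p-value method passed to [region_p_value()].
#' @return `regions` with columns `m_value`, `p_value`, `status`
#'   (up_embryo/up_endosperm/not_differential) appended; per-status totals
#'   are available via [summarize_dmr_calls()].
#' @export
call_dmrs <- function(regions, n_embryo, n_endosperm, alpha = 0.001,
                      method = "auto") {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  stopifnot(all(c("k_embryo", "k_endosperm") %in% names(regions)))
  k1 <- regions$k_embryo; k2 <- regions$k_endosperm
  M <- m_value(k1, k2, n_embryo, n_endosperm)
  p <- region_p_value(k1, k2, n_embryo, n_endosperm, method = method)
  sig <- p < alpha
  up_e <- sig & k1 > 0 & (ifelse(is.na(M), FALSE, M > 0) | k2 == 0)
  up_n <- sig & k2 > 0 & (ifelse(is.na(M), FALSE, M < 0) | k1 == 0)
  status <- ifelse(up_e, "up_embryo",
                   ifelse(up_n, "up_endosperm", "not_differential"))
  regions$m_value <- M
  regions$p_value <- p
  regions$status <- status
  regions
}

#' Summarize DMR calls
#'
#' @param calls output of [call_dmrs()] (or any table with a `status`
#'   column).
#' @return list with `n_regions`, `up_embryo`, `up_endosperm`,
#'   `not_differential` and `differential` (= up_embryo + up_endosperm).
#' @export
summarize_dmr_calls <- function(calls) {
  status <- if (is.data.frame(calls)) calls$status else as.character(calls)
  list(n_regions = length(status),
       up_embryo = sum(status == "up_embryo"),
       up_endosperm = sum(status == "up_endosperm"),
       not_differential = sum(status == "not_differential"),
       differential = sum(status != "not_differential"))
}
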