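#' Welch's unequal-variance t test
#'
#' Two-sided unpaired Welch test:
#' `t = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom. Computed via
#' [stats::t.test()].
#'
#' @param a,b Numeric samples, each with n >= 2; at least one must have
#'   non-zero variance.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  if (var(a) == 0 && var(b) == 0) {
    stop("degenerate: both samples have zero variance")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Holm-Bonferroni step-down decisions
#'
#' Orders the unadjusted p-values from lowest to highest and compares the
#' k-th smallest with `alpha / (m - k + 1)`; at the first non-rejection the
#' procedure stops and that hypothesis and all larger p-values are accepted.
#' Decisions are returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha Familywise error rate, in (0, 1).
#' @return Data frame of class `cf_holm`: `p`, `rank`, `threshold`
#'   (the adjusted alpha each p was compared with), `reject`; attributes
#'   `alpha` and `m`.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  thr_sorted <- alpha / (m - seq_len(m) + 1)
  rej_sorted <- logical(m)
  for (k in seq_len(m)) {
    if (p[ord[k]] < thr_sorted[k]) {
      rej_sorted[k] <- TRUE
    } else {
      break  # first failure stops the step-down
    }
  }
  out <- data.frame(p = p, rank = match(seq_along(p), ord),
                    threshold = thr_sorted[match(seq_along(p), ord)],
                    reject = rej_sorted[match(seq_along(p), ord)])
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  class(out) <- c("cf_holm", "data.frame")
  out
}
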