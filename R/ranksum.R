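# Wilcoxon rank-sum machinery shared by marker detection and per-cell
# signature scoring: midranks throughout; an exact tie-aware tail via a
# generating-function DP for small problems; tie-corrected normal
# approximation otherwise.

# Distribution of the doubled-midrank sum over all subsets of size m drawn
# from the doubled midranks d (integers). Returns counts indexed by sum.
.ranksum_dp <- function(d, m) {
  d <- as.integer(d)
  smax <- sum(sort(d, decreasing = TRUE)[seq_len(m)])
  f <- matrix(0, nrow = m + 1, ncol = smax + 1)  # f[j+1, s+1]
  f[1, 1] <- 1
  for (di in d) {
    jmax <- m  # update higher j from lower, in place, descending
    for (j in jmax:1) {
      src <- f[j, 1:(smax + 1 - di)]
      if (any(src != 0))
        f[j + 1, (di + 1):(smax + 1)] <- f[j + 1, (di + 1):(smax + 1)] + src
    }
  }
  f[m + 1, ]
}

#' One- or two-sided Wilcoxon rank-sum p-value for a membership split
#'
#' Tests whether values of the member group rank higher (or lower, or
#' differently) than the rest, using midranks. For small problems
#' (`length(values) <= exact_max_n` and `min(group sizes) <=
#' exact_max_m`) the exact permutation tail under ties is computed by
#' dynamic programming; otherwise a tie-corrected normal approximation
#' (no continuity correction) is used.
#'
#' With `midp = TRUE` the exact tail is the mid-p `P(W > w) + P(W = w)/2`
#' (matching the normal approximation's behaviour at the null center: a
#' fully tied split gives p = 0.5 one-sided); with `midp = FALSE` it is the
#' conventional `P(W >= w)`.
#'
#' @param values numeric vector over the whole universe.
#' @param member logical vector, `TRUE` for the tested group.
#' @param alternative `"greater"` (members rank higher), `"less"`, or
#'   `"two.sided"`.
#' @param midp use mid-p in the exact tail.
#' @param exact_max_n,exact_max_m exact-path size limits.
#' @return p-value, with attributes `statistic` (rank sum W of the member
#'   group) and `method` ("exact" or "normal").
#' @export
ranksum_p <- function(values, member,
                      alternative = c("greater", "less", "two.sided"),
                      midp = FALSE, exact_max_n = 200, exact_max_m = 30) {
  alternative <- match.arg(alternative)
  stopifnot(length(values) == length(member))
  n_tot <- length(values)
  m <- sum(member)
  if (m == 0 || m == n_tot) .stop_fmt("member group must be a proper subset")
  r <- rank(values)  # midranks
  w <- sum(r[member])
  use_exact <- n_tot <= exact_max_n && min(m, n_tot - m) <= exact_max_m
  if (use_exact) {
    flip <- m > n_tot - m  # DP over the smaller side
    mm <- min(m, n_tot - m)
    d <- as.integer(round(2 * r))
    counts <- .ranksum_dp(d, mm)
    total <- sum(counts)
    sums <- seq_along(counts) - 1L
    dw <- as.integer(round(2 * (if (flip) sum(r) - w else w)))
    tail_p <- function(ge) {  # P(S >= ge), mid-p aware
      hi <- sum(counts[sums > ge])
      eq <- sum(counts[sums == ge])
      (hi + if (midp) eq / 2 else eq) / total
    }
    lo_p <- function(le) {
      lo <- sum(counts[sums < le])
      eq <- sum(counts[sums == le])
      (lo + if (midp) eq / 2 else eq) / total
    }
    p <- switch(alternative,
      greater = if (flip) lo_p(dw) else tail_p(dw),
      less = if (flip) tail_p(dw) else lo_p(dw),
      two.sided = {
        ctr <- mm * (n_tot + 1)  # doubled expectation
        dev <- abs(dw - ctr)
        hi <- sum(counts[abs(sums - ctr) > dev])
        eq <- sum(counts[abs(sums - ctr) == dev])
        min(1, (hi + if (midp) eq / 2 else eq) / total)
      })
    method <- "exact"
  } else {
    mu <- m * (n_tot + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n_tot * (n_tot - 1))
    v <- m * (n_tot - m) / 12 * ((n_tot + 1) - tie_term)
    z <- if (v > 0) (w - mu) / sqrt(v) else 0
    p <- switch(alternative,
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z),
      two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    p <- min(1, p)
    method <- "normal"
  }
  attr(p, "statistic") <- w
  attr(p, "method") <- method
  p
}
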