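#' Nonparametric comparison of adapted parameter distributions
#'
#' Kruskal-Wallis omnibus test across two or more groups of adapted
#' parameter values (e.g. `CKR_Total` per patient), tie-corrected, with a
#' chi-square reference distribution on `k - 1` degrees of freedom.
#'
#' @param groups a (preferably named) list of numeric vectors.
#' @return A list of class `nephrosim_test` with `method`, `statistic`
#'   (H), `df`, `p`, and the combined sample size `n`.
#' @examples
#' ckr_kruskal(list(a = 1:5, b = 6:10, c = 11:15))
#' @export
ckr_kruskal <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(!vapply(groups, length, 1L)))
    stop("every group must be nonempty", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    res <- list(statistic = 0, df = length(groups) - 1L, p = 1)
  } else {
    kt <- stats::kruskal.test(x, g)
    res <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                p = kt$p.value)
  }
  structure(c(list(method = "Kruskal-Wallis H"), res, list(n = length(x))),
            class = "nephrosim_test")
}

#' @export
print.nephrosim_test <- function(x, ...) {
  cat(x$method, ": ", sep = "")
  if (!is.null(x$statistic))
    cat(sprintf("statistic = %.4g", x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = %d", as.integer(x$df)))
  if (!is.null(x$z)) cat(sprintf(", z = %.3f", x$z))
  cat(sprintf(", p = %.4g, n = %d\n", x$p, as.integer(x$n)))
  if (!is.null(x$r))
    cat(sprintf("  effect size |r| = %.2f (%s)\n", x$r, effect_label(x$r)))
  invisible(x)
}

# tie term sum(t^3 - t) over tied value groups of the pooled sample
.tie_term <- function(x) {
  t <- table(x)
  sum(t^3 - t)
}

#' Mann-Whitney U test between two samples
#'
#' The U statistic with a standardized z from the tie-corrected normal
#' approximation (no continuity correction) and a two-sided p-value;
#' `method = "exact"` enumerates the null distribution of U by dynamic
#' programming (untied data, small samples).
#'
#' @param a,b numeric samples.
#' @param method `"normal"` (default) or `"exact"` (requires no ties and
#'   at most 8 observations per group).
#' @return A `nephrosim_test` list with `statistic` (U of the first
#'   sample), `z`, `p`, effect size `r = |z|/sqrt(n)` and `n`.
#' @export
ckr_mannwhitney <- function(a, b, method = c("normal", "exact")) {
  method <- match.arg(method)
  stopifnot(length(a) > 0, length(b) > 0)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - .tie_term(c(a, b)) / (N * (N - 1)))
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  if (method == "exact") {
    if (anyDuplicated(c(a, b)))
      stop("exact method requires untied data", call. = FALSE)
    if (max(n1, n2) > 8)
      stop("exact method supports at most 8 observations per group",
           call. = FALSE)
    p <- .mw_exact_p(U, n1, n2)
  } else {
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
  }
  structure(list(method = paste0("Mann-Whitney U (", method, ")"),
                 statistic = U, z = z, p = min(1, p),
                 r = effect_size_r(z, N), n = N),
            class = "nephrosim_test")
}

# exact two-sided p for U by enumerating the count of rank subsets with
# each U value (standard recursion over sample sizes)
.mw_exact_p <- function(U, n1, n2) {
  maxU <- n1 * n2
  # classical recurrence c(m, n, u) = c(m-1, n, u-n) + c(m, n-1, u)
  memo <- new.env(parent = emptyenv())
  cnt <- function(m, n, u) {
    if (u < 0 || u > m * n) return(0)
    if (m == 0 || n == 0) return(as.numeric(u == 0))
    key <- paste(m, n, u)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- cnt(m - 1, n, u - n) + cnt(m, n - 1, u)
    memo[[key]] <- val
    val
  }
  total <- choose(n1 + n2, n1)
  dev <- abs(U - maxU / 2)
  us <- 0:maxU
  extreme <- us[abs(us - maxU / 2) >= dev - 1e-9]
  p <- sum(vapply(extreme, function(u) cnt(n1, n2, u), 0)) / total
  min(1, p)
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics from pooled-rank mean differences with tie
#' correction, following a Kruskal-Wallis omnibus test; p-values are
#' Bonferroni-adjusted over the `k(k-1)/2` comparisons. The z sign is
#' positive when the first-listed group has the higher mean rank.
#'
#' @param groups a named list of numeric vectors (>= 2 groups).
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return A data frame with one row per pair: `z`, `p`, `p_adjusted`,
#'   effect size `r = |z|/sqrt(n_i + n_j)` and the pair sample size `n`.
#' @export
ckr_dunn <- function(groups, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(groups), length(groups) >= 2)
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  rk <- rank(x)
  mean_rank <- tapply(rk, g, mean)
  ns <- lengths(groups)
  sigma2 <- N * (N + 1) / 12 - .tie_term(x) / (12 * (N - 1))
  m <- k * (k - 1) / 2
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(sigma2 * (1 / ns[i] + 1 / ns[j]))
    z <- if (se > 0) (mean_rank[i] - mean_rank[j]) / se else 0
    p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else 1
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               z = unname(z), p = p,
               p_adjusted = if (adjust == "bonferroni") min(1, p * m) else p,
               r = effect_size_r(z, ns[i] + ns[j]),
               n = unname(ns[i] + ns[j]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Effect size r from a standardized statistic
#'
#' Pearson's `r = |z| / sqrt(n)` where `n` is the combined size of the two
#' compared samples. Conventional thresholds: 0.1 small, 0.3 medium, 0.5
#' large.
#'
#' @param z standardized test statistic.
#' @param n combined sample size (> 0).
#' @return `|z| / sqrt(n)`.
#' @examples
#' effect_size_r(5.62, 40)   # 0.89
#' effect_size_r(17.60, 400) # 0.88
#' @export
effect_size_r <- function(z, n) {
  if (any(n <= 0)) stop("`n` must be > 0", call. = FALSE)
  abs(z) / sqrt(n)
}

#' @rdname effect_size_r
#' @param r effect size value.
#' @export
effect_label <- function(r) {
  cut(abs(r), breaks = c(-Inf, 0.1, 0.3, 0.5, Inf),
      labels = c("negligible", "small", "medium", "large"), right = FALSE)
}
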