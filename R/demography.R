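#' Small-sample demographic comparisons
#'
#' Yates-corrected chi-square, Wilcoxon rank-sum and Kruskal-Wallis tests,
#' and numerical sex-ratio summaries for nest censuses.
#'
#' @name demography
NULL

#' Yates continuity-corrected chi-square test for a 2x2 table
#'
#' \deqn{\chi^2 = \sum (\max(|O - E| - 0.5, 0))^2 / E}, df = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list with `statistic`, `df`, `p`.
#' @export
yates_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(dim(tab) != c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins must be positive")
  }
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  # correction is capped at |O - E| so an independent table gives exactly 0
  stat <- sum(pmax(abs(tab - e) - 0.5, 0)^2 / e)
  list(statistic = stat, df = 1L,
       p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# rank-sum distribution by full enumeration (small samples, no ties assumed
# handled by midranks upstream)
wilcox_exact_p <- function(w_obs, ranks, n1) {
  combs <- utils::combn(length(ranks), n1)
  ws <- colSums(matrix(ranks[combs], nrow = n1))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Wilcoxon rank-sum test
#'
#' W is the rank sum of the first sample (midranks for ties). p is exact by
#' full enumeration when the combined sample size is <= 25 , otherwise a
#' tie-corrected normal approximation with continuity correction.
#'
#' @param a,b numeric samples.
#' @return list with `W`, `p`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be non-empty")
  x <- c(a, b)
  if (length(unique(x)) == 1) {
    return(list(W = sum(rank(x)[seq_along(a)]), p = 1, method = "degenerate"))
  }
  r <- rank(x)
  w <- sum(r[seq_along(a)])
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (n <= 25) {
    p <- wilcox_exact_p(w, r, n1)
    return(list(W = w, p = p, method = "exact"))
  }
  mu <- n1 * (n + 1) / 2
  ties <- base::table(x)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * (n + 1 - tie_term)
  z <- (abs(w - mu) - 0.5) / sqrt(v)
  list(W = w, p = 2 * pnorm(-z), method = "normal")
}

#' Kruskal-Wallis test
#'
#' Tie-corrected H with a chi-square reference distribution on k - 1 df.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  x <- unlist(groups)
  n <- length(x)
  if (n < 3) stop("need total n >= 3")
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  rs <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / lengths(groups)) - 3 * (n + 1)
  ties <- base::table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h <- h / corr
  df <- length(groups) - 1
  list(H = h, df = df, p = pchisq(h, df, lower.tail = FALSE))
}

#' Numerical sex ratio per nest
#'
#' nSR = female sexuals / (female + male sexuals), for nests with at least
#' one adult sexual; nests without sexuals are excluded and counted.
#'
#' @param census data.frame with columns nest, queenright (logical),
#'   n_males, n_alate_females.
#' @return list with `per_nest` (nest, queenright, nsr) and `by_status`
#'   (mean and SE of nSR for queenless vs queenright nests).
#' @export
numerical_sex_ratio <- function(census) {
  req <- c("nest", "queenright", "n_males", "n_alate_females")
  stopifnot(all(req %in% names(census)))
  tot <- census$n_males + census$n_alate_females
  keep <- tot > 0
  per <- data.frame(nest = census$nest[keep],
                    queenright = census$queenright[keep],
                    nsr = census$n_alate_females[keep] / tot[keep])
  by_status <- do.call(rbind, lapply(split(per$nsr, per$queenright),
                                     function(v) {
    data.frame(n = length(v), mean = mean(v),
               se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  }))
  by_status$queenright <- rownames(by_status) == "TRUE"
  list(per_nest = per, by_status = by_status,
       n_excluded = sum(!keep))
}
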