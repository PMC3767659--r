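#' Nest spatial statistics and isolation by distance
#'
#' @name spatial
NULL

#' Clark-Evans nearest-neighbour test of spatial randomness
#'
#' R is the ratio of the mean observed nearest-neighbour distance to its
#' expectation under complete spatial randomness. Without edge correction
#' the expectation is `1/(2 sqrt(rho))` with `rho = n/area` and the standard
#' error of the mean distance is `0.26136/sqrt(n rho)`. With the Donnelly
#' boundary correction (the correction recommended by Sinclair 1985) the
#' expectation and variance gain boundary-length terms:
#' `E(r) = 0.5 sqrt(A/n) + (0.0514 + 0.041/sqrt(n)) B/n` and
#' `Var(rbar) = 0.0703 A/n^2 + 0.037 B sqrt(A/n^5)`.
#'
#' @param coords two-column matrix or data.frame of nest coordinates (m).
#' @param area plot area (m^2).
#' @param boundary boundary length (m); required for the corrected test.
#' @param correction "donnelly" (default) or "none".
#' @return list of class `clark_evans_result` with n, area, mean observed
#'   and expected distances, R, z and two-sided p for the chosen correction,
#'   plus the uncorrected R for reference.
#' @export
clark_evans_R <- function(coords, area, boundary = NULL,
                          correction = c("donnelly", "none")) {
  correction <- match.arg(correction)
  xy <- as.matrix(coords)
  n <- nrow(xy)
  if (n < 2) stop("need >= 2 points")
  if (area <= 0) stop("area must be positive")
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  nnd <- apply(d, 1, min)
  if (any(nnd == 0)) warning("coincident points: zero nearest-neighbour distance")
  rbar <- mean(nnd)
  rho <- n / area
  e_unc <- 1 / (2 * sqrt(rho))
  se_unc <- 0.26136 / sqrt(n * rho)
  if (correction == "donnelly") {
    if (is.null(boundary)) stop("boundary length required for the corrected test")
    e_r <- 0.5 * sqrt(area / n) + (0.0514 + 0.041 / sqrt(n)) * boundary / n
    v_r <- 0.0703 * area / n^2 + 0.037 * boundary * sqrt(area / n^5)
    se <- sqrt(v_r)
  } else {
    e_r <- e_unc
    se <- se_unc
  }
  z <- (rbar - e_r) / se
  structure(list(n = n, area = area, boundary = boundary,
                 density = rho,
                 mean_obs_distance = rbar, expected_distance = e_r,
                 R = rbar / e_r, R_uncorrected = rbar / e_unc,
                 z = z, p = 2 * pnorm(-abs(z)), correction = correction),
            class = "clark_evans_result")
}

#' Linearised-F_ST versus log-distance table
#'
#' Builds the isolation-by-distance regression input: pairs of
#' `F_ST/(1-F_ST)` against `ln` Euclidean distance. Pairs at zero distance
#' are excluded (ln undefined) and pairs with `F_ST = 1` are flagged
#' (infinite linearisation).
#'
#' @param fst colony x colony F_ST matrix (dimnames = colony ids).
#' @param coords data.frame with columns colony, x, y.
#' @return data.frame colony1, colony2, fst, lin_fst, distance, ln_distance;
#'   excluded pair counts are attached as attribute `"excluded"`.
#' @export
ibd_table <- function(fst, coords) {
  ids <- rownames(fst)
  if (!all(ids %in% coords$colony)) stop("coordinate ids do not match F_ST matrix")
  xy <- as.matrix(coords[match(ids, coords$colony), c("x", "y")])
  out <- list(); n_zero <- 0L; n_inf <- 0L
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      dd <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      if (dd == 0) { n_zero <- n_zero + 1L; next }
      f <- fst[i, j]
      lin <- if (is.na(f)) NA_real_ else if (f >= 1) Inf else f / (1 - f)
      if (is.finite(lin) || is.na(lin)) {
        out[[length(out) + 1]] <- data.frame(colony1 = ids[i],
                                             colony2 = ids[j],
                                             fst = f, lin_fst = lin,
                                             distance = dd,
                                             ln_distance = log(dd))
      } else n_inf <- n_inf + 1L
    }
  }
  df <- do.call(rbind, out)
  attr(df, "excluded") <- c(zero_distance = n_zero, fst_one = n_inf)
  df
}

#' Mantel test with Spearman rank correlation
#'
#' The statistic is the Spearman correlation between the strictly lower
#' triangles of two symmetric matrices; the null distribution is generated
#' by simultaneous row/column permutation of the second matrix; two-tailed
#' p by the `(count >= |obs| + 1)/(N + 1)` rule.
#'
#' @param a,b square symmetric matrices of equal dimension >= 4.
#' @param n_perms permutations (default 10000).
#' @param seed integer seed.
#' @return list of class `mantel_result` with `statistic`, `p`, `n_perms`.
#' @export
mantel_test <- function(a, b, n_perms = 10000L, seed = 1L) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != ncol(a) || any(dim(a) != dim(b))) {
    stop("matrices must be square and of equal dimension")
  }
  n <- nrow(a)
  if (n < 4) stop("need dimension >= 4")
  lt <- lower.tri(a)
  va <- a[lt]
  if (sd(va) == 0 || sd(b[lt]) == 0) stop("constant matrix: statistic undefined")
  obs <- cor(va, b[lt], method = "spearman")
  set.seed(seed)
  hits <- 0L
  for (k in seq_len(n_perms)) {
    p <- sample.int(n)
    if (abs(cor(va, b[p, p][lt], method = "spearman")) >= abs(obs) - 1e-12) {
      hits <- hits + 1L
    }
  }
  structure(list(statistic = obs, p = perm_pvalue(hits, n_perms),
                 n_perms = n_perms),
            class = "mantel_result")
}
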