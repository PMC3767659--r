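#' Haplotype analyses: collapsing, distances, median-joining networks
#'
#' @name mtdna
NULL

#' Collapse an alignment into haplotypes
#'
#' Sequences identical at all mutually non-N sites are merged; an ambiguous
#' sequence joins the first compatible haplotype in input order. Haplotypes
#' are labelled H1..Hk by first occurrence.
#'
#' @param alignment a [hap_alignment].
#' @param site optional per-sequence sampling-site labels for the frequency
#'   table.
#' @return list with `haplotypes` (a [hap_alignment] of unique sequences),
#'   `assignment` (haplotype label per input sequence), `frequencies`
#'   (overall counts) and `site_frequencies` (site x haplotype table, when
#'   `site` given).
#' @export
collapse_haplotypes <- function(alignment, site = NULL) {
  stopifnot(inherits(alignment, "hap_alignment"))
  m <- alignment$seq
  n_only <- which(colSums(m != "N") == 0)
  if (length(n_only) > 0) {
    warning(length(n_only), " alignment column(s) are entirely N")
  }
  compatible <- function(x, y) {
    ok <- x != "N" & y != "N"
    all(x[ok] == y[ok])
  }
  reps <- integer(0) # row index of each haplotype's representative
  assignment <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    hit <- NA_integer_
    for (h in seq_along(reps)) {
      if (compatible(m[i, ], m[reps[h], ])) { hit <- h; break }
    }
    if (is.na(hit)) {
      reps <- c(reps, i)
      hit <- length(reps)
    }
    assignment[i] <- paste0("H", hit)
  }
  haps <- m[reps, , drop = FALSE]
  rownames(haps) <- paste0("H", seq_along(reps))
  freq <- base::table(factor(assignment, levels = rownames(haps)))
  out <- list(haplotypes = hap_alignment(haps), assignment = assignment,
              frequencies = freq)
  if (!is.null(site)) {
    out$site_frequencies <- base::table(site, factor(assignment,
                                                     levels = rownames(haps)))
  }
  out
}

#' Pairwise substitution counts and uncorrected p-distances
#'
#' Counts differing sites over positions where both sequences are non-N;
#' the percent p-distance is `100 * count / compared sites`.
#'
#' @param alignment a [hap_alignment] (typically collapsed haplotypes).
#' @return list with `substitutions` (integer matrix) and `p_percent`
#'   (numeric matrix, full precision; round to 2 decimals for reporting).
#' @export
pairwise_p_distance <- function(alignment) {
  stopifnot(inherits(alignment, "hap_alignment"))
  m <- alignment$seq
  n <- nrow(m)
  subs <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  pp <- matrix(0, n, n, dimnames = dimnames(subs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ok <- m[i, ] != "N" & m[j, ] != "N"
      if (!any(ok)) {
        subs[i, j] <- subs[j, i] <- NA_integer_
        pp[i, j] <- pp[j, i] <- NA_real_
        next
      }
      s <- sum(m[i, ok] != m[j, ok])
      subs[i, j] <- subs[j, i] <- s
      pp[i, j] <- pp[j, i] <- 100 * s / sum(ok)
    }
  }
  list(substitutions = subs, p_percent = pp)
}

# --- median-joining network -------------------------------------------------

hamming <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  }
  d
}

# minimum spanning network: edge (u,v) belongs iff u and v are not connected
# using only strictly shorter edges (epsilon = 0 criterion)
msn_edges <- function(d) {
  n <- nrow(d)
  if (n < 2) return(matrix(numeric(0), 0, 3))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  ord <- order(w)
  pairs <- pairs[ord, , drop = FALSE]; w <- w[ord]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- matrix(numeric(0), 0, 3)
  k <- 1
  while (k <= length(w)) {
    same <- which(w == w[k]) # process one weight class at a time
    keep <- logical(length(same))
    for (t in seq_along(same)) {
      i <- pairs[same[t], 1]; j <- pairs[same[t], 2]
      keep[t] <- find(i) != find(j)
    }
    for (t in seq_along(same)) {
      if (keep[t]) {
        i <- pairs[same[t], 1]; j <- pairs[same[t], 2]
        edges <- rbind(edges, c(i, j, w[same[t]]))
      }
    }
    for (t in seq_along(same)) { # union after collecting the whole class
      i <- find(pairs[same[t], 1]); j <- find(pairs[same[t], 2])
      if (i != j) parent[i] <- j
    }
    k <- max(same) + 1
  }
  edges
}

#' Median-joining haplotype network (epsilon = 0)
#'
#' Iterates minimum-spanning-network construction over the current sequence
#' set, adds median (majority-consensus) vectors of linked triplets, and
#' prunes obsolete unobserved nodes, following the Bandelt et al. scheme
#' with epsilon = 0 and Hamming connection costs. Only segregating sites
#' enter the computation.
#'
#' @param alignment a [hap_alignment] of >= 2 distinct haplotypes.
#' @param max_iter safety cap on median-addition rounds.
#' @return list with `nodes` (data.frame id, observed flag), `edges`
#'   (data.frame from, to, weight = mutation count), and `sequences`
#'   (character matrix of all node sequences, medians included).
#' @export
median_joining_network <- function(alignment, max_iter = 10L) {
  stopifnot(inherits(alignment, "hap_alignment"))
  m <- alignment$seq
  if (nrow(m) < 2) stop("need >= 2 haplotypes")
  seg <- which(vapply(seq_len(ncol(m)), function(j) {
    length(unique(m[, j])) > 1
  }, TRUE))
  s <- m[, seg, drop = FALSE]
  labels <- rownames(m)
  observed <- rep(TRUE, nrow(s))
  n_median <- 0L

  for (iter in seq_len(max_iter)) {
    d <- hamming(s)
    ed <- msn_edges(d)
    adj <- matrix(FALSE, nrow(s), nrow(s))
    for (e in seq_len(nrow(ed))) adj[ed[e, 1], ed[e, 2]] <-
      adj[ed[e, 2], ed[e, 1]] <- TRUE
    new_medians <- list()
    if (nrow(s) >= 3) {
      trips <- utils::combn(nrow(s), 3)
      for (t in seq_len(ncol(trips))) {
        u <- trips[1, t]; v <- trips[2, t]; w <- trips[3, t]
        links <- adj[u, v] + adj[u, w] + adj[v, w]
        if (links < 2) next
        med <- vapply(seq_len(ncol(s)), function(j) {
          x <- c(s[u, j], s[v, j], s[w, j])
          tx <- base::table(x)
          names(tx)[which.max(tx)] # majority state (ties: alphabetical)
        }, "")
        key <- paste(med, collapse = "")
        existing <- apply(s, 1, paste, collapse = "")
        if (key %in% existing) next
        if (key %in% vapply(new_medians,
                            function(x) paste(x, collapse = ""), "")) next
        new_medians[[length(new_medians) + 1]] <- med
      }
    }
    if (length(new_medians) == 0) break
    for (med in new_medians) {
      n_median <- n_median + 1L
      s <- rbind(s, med)
      labels <- c(labels, paste0("mv", n_median))
      observed <- c(observed, FALSE)
    }
  }

  # prune: drop unobserved nodes that are leaves or redundant pass-throughs
  repeat {
    d <- hamming(s)
    ed <- msn_edges(d)
    deg <- tabulate(c(ed[, 1], ed[, 2]), nbins = nrow(s))
    drop <- which(!observed & deg <= 1)
    if (length(drop) == 0) {
      # degree-2 unobserved node on a path of equal total cost is obsolete
      two <- which(!observed & deg == 2)
      for (v in two) {
        nb <- unique(c(ed[ed[, 1] == v, 2], ed[ed[, 2] == v, 1]))
        if (length(nb) == 2 && d[nb[1], nb[2]] ==
            d[nb[1], v] + d[v, nb[2]]) {
          drop <- c(drop, v)
        }
      }
      drop <- utils::head(drop, 1)
    }
    if (length(drop) == 0) break
    keep <- setdiff(seq_len(nrow(s)), drop)
    s <- s[keep, , drop = FALSE]
    labels <- labels[keep]
    observed <- observed[keep]
  }

  d <- hamming(s)
  ed <- msn_edges(d)
  # full-length sequences for the nodes (medians get non-segregating sites
  # from the first haplotype, which is constant there by definition)
  full <- matrix(rep(m[1, ], nrow(s)), nrow = nrow(s), byrow = TRUE)
  full[, seg] <- s
  rownames(full) <- labels
  edges <- data.frame(from = labels[ed[, 1]], to = labels[ed[, 2]],
                      weight = ed[, 3])
  list(nodes = data.frame(id = labels, observed = observed),
       edges = edges[order(edges$from, edges$to), , drop = FALSE],
       sequences = full)
}
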