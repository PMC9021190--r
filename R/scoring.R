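#' @name scoring
#' @title Spectrum-pair scoring
#'
#' @description
#' A query-reference spectrum pair is scored by a cosine similarity defined
#' over a one-to-one matching of fragment peaks: two peaks may pair when
#' their m/z values agree within the ion tolerance (identity search), or
#' additionally when they are offset by the precursor mass difference
#' (analog / modified-cosine search). Among all one-to-one pairings the
#' exact maximum of the summed intensity products is taken — never a greedy
#' approximation — and divided by the product of the Euclidean norms of the
#' two full preprocessed intensity vectors, so unmatched peaks penalize the
#' score and a cosine of 1 means all signal is shared.
NULL

#' Enumerate tolerance-eligible peak pairs
#'
#' Pair (i, j) is eligible unshifted when `|a$mz[i] - b$mz[j]| <= ion_tol`
#' and, when `shift != 0`, eligible shifted when
#' `|a$mz[i] + shift - b$mz[j]| <= ion_tol`. Each eligible way is emitted
#' once with its flag; the tolerance test is inclusive. The pair weight is
#' the product of the two (preprocessed-scale) intensities.
#'
#' @param a,b `"spectrum"` objects (already preprocessed).
#' @param ion_tol ion tolerance in Da (> 0, inclusive).
#' @param shift precursor m/z shift in Da applied to `a`'s peaks (0 for
#'   identity search).
#' @return a `data.frame` with columns `i` (index into `a`'s peaks), `j`
#'   (index into `b`'s peaks), `weight`, `shifted` (logical), `dmz`
#'   (absolute m/z deviation of that way).
#' @export
eligible_pairs <- function(a, b, ion_tol, shift = 0) {
  stopifnot(ion_tol > 0)
  validate_spectrum(a, allow_empty = TRUE)
  validate_spectrum(b, allow_empty = TRUE)
  ways <- if (shift != 0) c(0, shift) else 0
  out <- vector("list", length(ways) * max(length(a$mz), 1L))
  k <- 0L
  for (w in seq_along(ways)) {
    sh <- ways[w]
    if (length(a$mz) == 0L || length(b$mz) == 0L) next
    amz <- a$mz + sh
    lo <- findInterval(amz - ion_tol, b$mz, left.open = TRUE) + 1L
    hi <- findInterval(amz + ion_tol, b$mz)
    for (i in seq_along(amz)) {
      if (lo[i] > hi[i]) next
      j <- lo[i]:hi[i]
      k <- k + 1L
      out[[k]] <- data.frame(
        i = i, j = j,
        weight = a$intensity[i] * b$intensity[j],
        shifted = sh != 0,
        dmz = abs(amz[i] - b$mz[j])
      )
    }
  }
  if (k == 0L)
    return(data.frame(i = integer(), j = integer(), weight = numeric(),
                      shifted = logical(), dmz = numeric()))
  do.call(rbind, out[seq_len(k)])
}

# Exact maximum-weight bipartite matching on one connected component.
# Lexicographic objective: maximize total weight, then minimize total |dmz|,
# then prefer fewer pairs / lower partner index (determinism). DP over a
# bitmask of the smaller side; `edges` is a data.frame with columns
# li (1..nL, larger side), si (1..nS, smaller side), weight, dmz, row
# (row index into the original pair table). Returns selected `row` indices.
match_component_dp <- function(edges, nL, nS) {
  full <- bitwShiftL(1L, nS)
  # dp value for state (layer i in 1..nL+1, mask): best (W, D) using L-nodes
  # i..nL with availability mask of S-nodes. Stored as two matrices.
  W <- matrix(0, nrow = nL + 1L, ncol = full)
  D <- matrix(0, nrow = nL + 1L, ncol = full)
  by_l <- split(seq_len(nrow(edges)), factor(edges$li, levels = seq_len(nL)))
  masks <- 0:(full - 1L)
  for (i in nL:1) {
    W[i, ] <- W[i + 1L, ]
    D[i, ] <- D[i + 1L, ]
    for (e in by_l[[i]]) {
      bit <- bitwShiftL(1L, edges$si[e] - 1L)
      free <- bitwAnd(masks, bit) == 0L
      cand_w <- edges$weight[e] + W[i + 1L, ][bitwOr(masks[free], bit) + 1L]
      cand_d <- edges$dmz[e] + D[i + 1L, ][bitwOr(masks[free], bit) + 1L]
      cur_w <- W[i, ][masks[free] + 1L]
      cur_d <- D[i, ][masks[free] + 1L]
      take <- cand_w > cur_w | (cand_w == cur_w & cand_d < cur_d)
      idx <- masks[free][take] + 1L
      W[i, idx] <- cand_w[take]
      D[i, idx] <- cand_d[take]
    }
  }
  # reconstruct deterministically: prefer skip on exact ties, then the edge
  # with smaller si / earlier row order
  sel <- integer(0)
  mask <- 0L
  for (i in seq_len(nL)) {
    if (W[i, mask + 1L] == W[i + 1L, mask + 1L] &&
        D[i, mask + 1L] == D[i + 1L, mask + 1L]) next
    for (e in by_l[[i]]) {
      bit <- bitwShiftL(1L, edges$si[e] - 1L)
      if (bitwAnd(mask, bit) != 0L) next
      nxt <- bitwOr(mask, bit)
      if (edges$weight[e] + W[i + 1L, nxt + 1L] == W[i, mask + 1L] &&
          edges$dmz[e] + D[i + 1L, nxt + 1L] == D[i, mask + 1L]) {
        sel <- c(sel, edges$row[e])
        mask <- nxt
        break
      }
    }
  }
  sel
}

# Shortest-augmenting-path assignment (minimization, complete cost matrix,
# nrow <= ncol). Used for components too large for the bitmask DP; exact on
# the weight objective, without the |dmz| tiebreak. Returns for each row the
# assigned column index.
assignment_min <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L); way <- integer(m + 1L)  # index m+1 is the virtual column
  VCOL <- m + 1L
  for (i in seq_len(n)) {
    p[VCOL] <- i
    j0 <- VCOL
    minv <- rep(Inf, m + 1L)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == VCOL) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assign[p[j]] <- j
  assign
}

match_component_lap <- function(edges, nL, nS) {
  # dense maximize-weight assignment; skip is modeled by zero-weight cells
  wmat <- matrix(0, nrow = nS, ncol = nL)
  rmat <- matrix(0L, nrow = nS, ncol = nL)
  for (e in seq_len(nrow(edges))) {
    si <- edges$si[e]; li <- edges$li[e]
    if (edges$weight[e] > wmat[si, li] ||
        (edges$weight[e] == wmat[si, li] && rmat[si, li] == 0L)) {
      wmat[si, li] <- edges$weight[e]
      rmat[si, li] <- edges$row[e]
    }
  }
  if (nS > nL) { wmat <- t(wmat); rmat <- t(rmat) }  # solver wants rows <= cols
  assign <- assignment_min(-wmat)
  sel <- integer(0)
  for (r in seq_len(nrow(wmat))) {
    cc <- assign[r]
    if (cc > 0L && wmat[r, cc] > 0) sel <- c(sel, rmat[r, cc])
  }
  sel
}

#' Score a pair table by exact maximum-weight one-to-one matching
#'
#' Selects the one-to-one assignment of peaks (each peak of `a` and of `b`
#' used at most once) that maximizes the sum of pair weights; the exact
#' optimum is found by dynamic programming over the connected components of
#' the eligibility graph. Ties between equal-weight assignments break toward
#' the pairing with smaller total absolute m/z deviation. The score is the
#' matched weight sum divided by the product of the Euclidean norms of the
#' two full preprocessed intensity vectors.
#'
#' @param pairs output of [eligible_pairs()] on the same two spectra.
#' @param a,b the `"spectrum"` objects the pairs were computed from.
#' @return an object of class `"score_result"`: a list with `score` (cosine
#'   in \[0, 1\]), `n_matched_peaks`, `matched_pairs` (a `data.frame` with
#'   columns `i`, `j`, `shifted`, `weight`, `dmz`), and `precursor_delta`
#'   (`b` precursor minus `a` precursor, Da).
#' @export
max_matching_score <- function(pairs, a, b) {
  delta <- b$precursor_mz - a$precursor_mz
  empty <- data.frame(i = integer(), j = integer(), shifted = logical(),
                      weight = numeric(), dmz = numeric())
  res <- structure(list(score = 0, n_matched_peaks = 0L,
                        matched_pairs = empty, precursor_delta = delta),
                   class = "score_result")
  norm_a <- sqrt(sum(a$intensity^2))
  norm_b <- sqrt(sum(b$intensity^2))
  if (length(a$mz) == 0L || length(b$mz) == 0L) {
    attr(res, "empty_input") <- TRUE
    return(res)
  }
  if (nrow(pairs) == 0L || norm_a == 0 || norm_b == 0) return(res)

  # a pair (i, j) eligible both unshifted and shifted enters the matching as
  # one edge; the way with smaller dmz (unshifted first on ties) is reported
  ord <- order(pairs$i, pairs$j, pairs$dmz, pairs$shifted)
  pairs <- pairs[ord, , drop = FALSE]
  edge <- pairs[!duplicated(pairs[c("i", "j")]), , drop = FALSE]
  edge$row <- seq_len(nrow(edge))

  # connected components of the bipartite eligibility graph
  na <- length(a$mz); nb <- length(b$mz)
  parent <- seq_len(na + nb)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (e in seq_len(nrow(edge))) {
    ra <- find(edge$i[e]); rb <- find(na + edge$j[e])
    if (ra != rb) parent[rb] <- ra
  }
  comp_of_edge <- vapply(seq_len(nrow(edge)), function(e) find(edge$i[e]), integer(1))

  sel <- integer(0)
  for (cid in unique(comp_of_edge)) {
    ce <- edge[comp_of_edge == cid, , drop = FALSE]
    ai <- sort(unique(ce$i)); bj <- sort(unique(ce$j))
    if (length(ai) >= length(bj)) {
      nL <- length(ai); nS <- length(bj)
      ce$li <- match(ce$i, ai); ce$si <- match(ce$j, bj)
    } else {
      nL <- length(bj); nS <- length(ai)
      ce$li <- match(ce$j, bj); ce$si <- match(ce$i, ai)
    }
    if (nS <= 20L && (nL + 1) * 2^nS <= 4e6) {
      sel <- c(sel, match_component_dp(ce, nL, nS))
    } else {
      sel <- c(sel, match_component_lap(ce, nL, nS))
    }
  }
  if (length(sel) == 0L) return(res)
  chosen <- edge[match(sort(sel), edge$row), c("i", "j", "shifted", "weight", "dmz")]
  chosen <- chosen[order(chosen$i), , drop = FALSE]
  rownames(chosen) <- NULL
  res$score <- sum(chosen$weight) / (norm_a * norm_b)
  res$n_matched_peaks <- nrow(chosen)
  res$matched_pairs <- chosen
  res
}

#' Cosine similarity between two spectra (identity search)
#'
#' Eligibility at zero precursor shift, then the exact maximum-weight
#' matching of [max_matching_score()]. Symmetric in its two arguments.
#'
#' @param a,b preprocessed `"spectrum"` objects.
#' @param ion_tol ion tolerance in Da.
#' @return a `"score_result"`; an empty-after-preprocess spectrum yields
#'   score 0 with attribute `empty_input`.
#' @export
cosine_similarity <- function(a, b, ion_tol = 0.1) {
  max_matching_score(eligible_pairs(a, b, ion_tol, shift = 0), a, b)
}

#' Modified cosine (analog search)
#'
#' Adds to the identity eligibility all peak pairs offset by the precursor
#' mass difference `b$precursor_mz - a$precursor_mz`, so a structural analog
#' whose fragments shift with the modification can still match. A peak is
#' used through at most one of its eligible ways. Scores from
#' `modified_cosine(a, b)` and `modified_cosine(b, a)` agree (the shift sign
#' flips).
#'
#' @inheritParams cosine_similarity
#' @return a `"score_result"`.
#' @export
modified_cosine <- function(a, b, ion_tol = 0.1) {
  shift <- b$precursor_mz - a$precursor_mz
  max_matching_score(eligible_pairs(a, b, ion_tol, shift = shift), a, b)
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> cosine %.4f, %d matched peak%s, precursor delta %+.4f Da\n",
              x$score, x$n_matched_peaks,
              if (x$n_matched_peaks == 1L) "" else "s", x$precursor_delta))
  invisible(x)
}
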