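# Independent oracles used across the suite. These deliberately share no
# code with the package: plain double loops and exhaustive enumeration.

# every tolerance-eligible (i, j, weight) triple, by direct double loop
oracle_pairs <- function(a, b, tol, shift = 0) {
  out <- matrix(numeric(0), ncol = 3)
  for (i in seq_along(a$mz)) {
    for (j in seq_along(b$mz)) {
      ok <- abs(a$mz[i] - b$mz[j]) <= tol ||
        (shift != 0 && abs(a$mz[i] + shift - b$mz[j]) <= tol)
      if (ok) out <- rbind(out, c(i, j, a$intensity[i] * b$intensity[j]))
    }
  }
  out
}

# exhaustive maximum over all one-to-one matchings (branch and bound on the
# complete enumeration tree; exact)
oracle_best_weight <- function(pairs) {
  if (nrow(pairs) == 0) return(0)
  pairs <- pairs[order(-pairs[, 3]), , drop = FALSE]
  suffix <- rev(cumsum(rev(pairs[, 3])))
  best <- 0
  n <- nrow(pairs)
  rec <- function(k, ui, uj, cur) {
    if (cur > best) best <<- cur
    if (k > n || cur + suffix[k] <= best) return(invisible())
    if (!(pairs[k, 1] %in% ui) && !(pairs[k, 2] %in% uj))
      rec(k + 1, c(ui, pairs[k, 1]), c(uj, pairs[k, 2]), cur + pairs[k, 3])
    rec(k + 1, ui, uj, cur)
  }
  rec(1L, numeric(0), numeric(0), 0)
  best
}

oracle_cosine <- function(a, b, tol, shift = 0) {
  denom <- sqrt(sum(a$intensity^2)) * sqrt(sum(b$intensity^2))
  if (denom == 0) return(0)
  oracle_best_weight(oracle_pairs(a, b, tol, shift)) / denom
}

# O(n^2) per-peak window-rank survival oracle for the top-k filter
oracle_window_filter <- function(s, k, hw) {
  n <- length(s$mz)
  keep <- logical(n)
  for (i in seq_len(n)) {
    win <- which(abs(s$mz - s$mz[i]) <= hw)
    ord <- win[order(-s$intensity[win], s$mz[win], win)]
    keep[i] <- i %in% ord[seq_len(min(k, length(ord)))]
  }
  spectrum(s$spectrum_id, s$precursor_mz, s$mz[keep], s$intensity[keep],
           allow_empty = TRUE)
}

# brute-force transitive closure of a child->parent edge list
oracle_ancestors <- function(child, parent, term) {
  terms <- unique(c(child, parent))
  reach <- matrix(FALSE, length(terms), length(terms),
                  dimnames = list(terms, terms))
  for (e in seq_along(child)) reach[child[e], parent[e]] <- TRUE
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  sort(terms[reach[term, ]])
}

# random generators --------------------------------------------------------

# spectra whose peaks cluster enough that eligibility conflicts are common
random_dense_spectrum <- function(id, n_peaks, mz_lo = 100, mz_span = 4,
                                  precursor = 400) {
  spectrum(id, precursor,
           mz = mz_lo + runif(n_peaks, 0, mz_span),
           intensity = rlnorm(n_peaks, 0, 1))
}

random_test_spectrum <- function(id, n_peaks = sample(5:30, 1),
                                 mz_range = c(100, 400)) {
  spectrum(id, runif(1, mz_range[1], mz_range[2]),
           mz = runif(n_peaks, mz_range[1], mz_range[2]),
           intensity = rlnorm(n_peaks, 2, 1.5))
}

# random DAG on n terms: node i > 1 draws 1-2 parents among 1..i-1
random_dag_edges <- function(n) {
  child <- character(0); parent <- character(0)
  terms <- sprintf("t%02d", seq_len(n))
  for (i in 2:n) {
    np <- sample(1:min(2, i - 1), 1)
    for (p in sample(seq_len(i - 1), np)) {
      child <- c(child, terms[i]); parent <- c(parent, terms[p])
    }
  }
  list(child = child, parent = parent, terms = terms)
}

# small ready-made chain ontology and samples used by several files
chain_ontology <- function() {
  ontology(c("cherry_tomato", "tomato", "fruit"),
           c("tomato", "fruit", "plant"))
}

chain_samples <- function() {
  data.frame(sample_id = paste0("s", 1:4),
             filename = paste0("s", 1:4, ".mzML"),
             terminal_term = c("cherry_tomato", "tomato", "tomato", "fruit"),
             stringsAsFactors = FALSE)
}
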