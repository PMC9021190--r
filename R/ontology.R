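#' @name ontology
#' @title Food ontology and prevalence aggregation
#'
#' @description
#' Reference samples are labeled with their most specific (terminal) food
#' ontology term; the ontology is a DAG (a term may have several parents,
#' e.g. a berry that is also a fleshy fruit). For reporting, every sample
#' inherits all ancestor terms of its terminal label, and the prevalence of
#' a molecule at a term is the number of samples carrying that term with a
#' spectral match divided by the total number of samples carrying the term.
NULL

new_ontology <- function(terms, parents) {
  o <- structure(list(terms = terms, parents = parents,
                      cache = new.env(parent = emptyenv())),
                 class = "food_ontology")
  o
}

#' Construct a food ontology from an edge list
#'
#' @param child,parent equal-length character vectors; each position is one
#'   child-to-parent edge. Multiple parents per term are allowed (DAG).
#' @param roots optional character vector of terms declared as roots (terms
#'   appearing only as parents are roots automatically).
#' @return an object of class `"food_ontology"`. Cycles are an error (one
#'   cycle is named); so is an ontology without any root.
#' @export
ontology <- function(child, parent, roots = character(0)) {
  stopifnot(length(child) == length(parent))
  child <- as.character(child); parent <- as.character(parent)
  if (any(!nzchar(child)) || any(!nzchar(parent)))
    stop("empty term name in ontology edge")
  terms <- unique(c(child, parent, as.character(roots)))
  parents <- split(parent, factor(child, levels = terms))
  parents <- lapply(parents, unique)
  # cycle check: DFS with colors
  color <- stats::setNames(rep(0L, length(terms)), terms)  # 0 white 1 grey 2 black
  cycle <- NULL
  visit <- function(t, path) {
    if (color[[t]] == 1L) {
      cycle <<- c(path[which(path == t)[1]:length(path)], t)
      return(TRUE)
    }
    if (color[[t]] == 2L) return(FALSE)
    color[[t]] <<- 1L
    for (p in parents[[t]]) if (visit(p, c(path, t))) return(TRUE)
    color[[t]] <<- 2L
    FALSE
  }
  for (t in terms) if (color[[t]] == 0L && visit(t, character(0)))
    stop("ontology contains a cycle: ", paste(cycle, collapse = " -> "))
  o <- new_ontology(terms, parents)
  if (length(ontology_roots(o)) == 0L)
    stop("ontology has no root term")
  o
}

#' Terms with no parent
#' @param o a `"food_ontology"`.
#' @return character vector of root terms.
#' @export
ontology_roots <- function(o) {
  stopifnot(inherits(o, "food_ontology"))
  o$terms[vapply(o$terms, function(t) length(o$parents[[t]]) == 0L, logical(1))]
}

#' Children of each term (inverse edge map)
#' @param o a `"food_ontology"`.
#' @return named list: term -> character vector of direct children, sorted.
#' @export
ontology_children <- function(o) {
  stopifnot(inherits(o, "food_ontology"))
  ch <- stats::setNames(vector("list", length(o$terms)), o$terms)
  for (t in o$terms) ch[[t]] <- character(0)
  for (t in o$terms) for (p in o$parents[[t]]) ch[[p]] <- c(ch[[p]], t)
  lapply(ch, sort)
}

#' @export
print.food_ontology <- function(x, ...) {
  cat(sprintf("<food_ontology> %d terms, %d edges, root(s): %s\n",
              length(x$terms), sum(lengths(x$parents)),
              paste(ontology_roots(x), collapse = ", ")))
  invisible(x)
}

#' Read an ontology from a child-parent edge list file
#'
#' Format: UTF-8 text, one `child<TAB>parent` edge per line. Lines of the
#' form `#root<TAB>name` declare roots explicitly (useful for a
#' single-term ontology); other `#` lines are comments. A literal
#' `child<TAB>parent` header line is permitted and skipped.
#'
#' @param path file path.
#' @return a `"food_ontology"`.
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines)]
  roots <- character(0)
  edges_c <- character(0); edges_p <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (startsWith(line, "#root\t")) {
      roots <- c(roots, trimws(sub("^#root\t", "", line)))
      next
    }
    if (startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (i == 1L && identical(tolower(f), c("child", "parent"))) next
    if (length(f) != 2L)
      stop("ontology parse error at line ", i, ": expected 'child<TAB>parent', got '", line, "'")
    edges_c <- c(edges_c, trimws(f[1])); edges_p <- c(edges_p, trimws(f[2]))
  }
  ontology(edges_c, edges_p, roots = roots)
}

#' All ancestors of a term
#'
#' Every term reachable by following parent links, excluding the term
#' itself. Results are cached per ontology.
#'
#' @param o a `"food_ontology"`.
#' @param term a term identifier present in `o`.
#' @return character vector of ancestor terms (sorted, possibly empty).
#' @export
ancestors <- function(o, term) {
  stopifnot(inherits(o, "food_ontology"))
  if (!term %in% o$terms) stop("unknown ontology term: ", term)
  if (!is.null(o$cache[[term]])) return(o$cache[[term]])
  seen <- character(0)
  frontier <- o$parents[[term]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(o$parents[new], use.names = FALSE))
  }
  res <- sort(seen)
  o$cache[[term]] <- res
  res
}

#' Expand a sample's terminal label to its full term set
#'
#' A sample labeled with a terminal term carries that term plus all of its
#' ancestors (e.g. a red cherry tomato is also a cherry tomato, a tomato, a
#' fruit and a plant).
#'
#' @param o a `"food_ontology"`.
#' @param terminal_term the sample's most specific label.
#' @param sample_id optional identifier used in the error message for an
#'   unknown term.
#' @return character vector: the terminal term plus its ancestors.
#' @export
expand_labels <- function(o, terminal_term, sample_id = NULL) {
  if (!terminal_term %in% o$terms)
    stop("terminal term '", terminal_term, "' not in ontology",
         if (!is.null(sample_id)) paste0(" (sample '", sample_id, "')") else "")
  c(terminal_term, ancestors(o, terminal_term))
}

#' Per-term match prevalence
#'
#' For every ontology term carried by at least one sample (after ancestor
#' inheritance), counts the samples carrying it, the subset of those with a
#' spectral match, and the exact fraction matched. A sample is counted at
#' most once per term even when several parent paths reach the same
#' ancestor.
#'
#' @param matched_sample_ids character vector of sample ids with at least
#'   one spectral match (must be a subset of `samples$sample_id`).
#' @param samples sample metadata `data.frame` with `sample_id` and
#'   `terminal_term` columns.
#' @param o a `"food_ontology"` containing every terminal term.
#' @return a `data.frame` with columns `term`, `n_matched`, `n_total`,
#'   `fraction`, sorted by fraction descending then term name. Fractions
#'   are exact ratios; render to percentages only at presentation.
#' @export
prevalence_table <- function(matched_sample_ids, samples, o) {
  stopifnot(inherits(o, "food_ontology"), is.data.frame(samples))
  matched_sample_ids <- unique(as.character(matched_sample_ids))
  unknown <- setdiff(matched_sample_ids, samples$sample_id)
  if (length(unknown))
    stop("matched sample id(s) not among samples: ", paste(unknown, collapse = ", "))
  expansions <- lapply(seq_len(nrow(samples)), function(r)
    expand_labels(o, samples$terminal_term[r], samples$sample_id[r]))
  term <- unlist(expansions, use.names = FALSE)
  sid <- rep(samples$sample_id, lengths(expansions))
  matched <- sid %in% matched_sample_ids
  n_total <- tapply(sid, term, length)            # expansions are sets: no dup per sample
  n_matched <- tapply(matched, term, sum)
  df <- data.frame(term = names(n_total),
                   n_matched = as.integer(n_matched[names(n_total)]),
                   n_total = as.integer(n_total),
                   stringsAsFactors = FALSE)
  df$fraction <- df$n_matched / df$n_total
  df <- df[order(-df$fraction, df$term), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Render a fraction as a whole-number percentage
#'
#' Rounds half away from zero (0.315 -> 32%), the convention used for
#' on-screen prevalence percentages; stored fractions stay exact.
#'
#' @param fraction numeric vector in \[0, 1\].
#' @return integer vector of percentages.
#' @export
percent_round <- function(fraction) {
  as.integer(floor(fraction * 100 + 0.5))
}
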