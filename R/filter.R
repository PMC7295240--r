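#' Relative position of a substring within a CDR3
#'
#' The 0-based start index of the first occurrence of `sub` in `c`, divided
#' by the number of length-`|sub|` windows in `c` (`|c| - |sub| + 1`). The
#' normalisation makes positions comparable across CDR3s of different
#' lengths; values lie in `[0, 1)`, with 0 for a prefix.
#'
#' @param sub Substring (must occur in `c`).
#' @param c CDR3 sequence.
#' @return A number in `[0, 1)`.
#' @export
relative_position <- function(sub, c) {
  pos <- unname(stringi::stri_locate_first_fixed(c, sub)[, 1])
  if (is.na(pos)) {
    abort("`sub` does not occur in `c`.", class = "dminer_contract_error")
  }
  (pos - 1) / (nchar(c) - nchar(sub) + 1)
}

#' Mean relative positions of extensions across a CDR3 set
#'
#' For each extension, the mean of [relative_position()] over all distinct
#' CDR3s containing it. Because V-gene fragments sit at the start of CDR3s, D
#' genes in the middle, and J-gene fragments at the end, these means separate
#' the three segment classes.
#'
#' @param extensions Character vector of extension sequences, or a tibble
#'   with a `sequence` column.
#' @param cdr3s A CDR3 set.
#' @return The input as a tibble with columns `mean_rp` and `n_cdr3s` added;
#'   extensions absent from every CDR3 get `NA` and `n_cdr3s = 0`.
#' @export
mean_relative_positions <- function(extensions, cdr3s) {
  tbl <- if (is.data.frame(extensions)) as_tibble(extensions)
         else tibble(sequence = extensions)
  seqs <- cdr3s$sequence
  lens <- nchar(seqs)
  stats <- purrr::map(unique(tbl$sequence), function(e) {
    pos <- stringi::stri_locate_first_fixed(seqs, e)[, 1]
    hit <- !is.na(pos)
    n <- sum(hit)
    mean_rp <- if (n == 0) NA_real_ else
      mean((pos[hit] - 1) / (lens[hit] - nchar(e) + 1))
    tibble(sequence = e, mean_rp = mean_rp, n_cdr3s = n)
  }) |> bind_rows()
  left_join(tbl, stats, by = "sequence")
}

# deterministic 1-D Lloyd k-means; empty clusters keep their centroid
lloyd_1d <- function(x, centers, iters = 100) {
  k <- length(centers)
  cl <- integer(length(x))
  for (it in seq_len(iters)) {
    d2 <- outer(x, centers, function(a, b) (a - b)^2)
    cl <- max.col(-d2, ties.method = "first")
    new_c <- centers
    for (j in seq_len(k)) {
      if (any(cl == j)) new_c[j] <- mean(x[cl == j])
    }
    if (isTRUE(all.equal(new_c, centers, tolerance = 1e-12))) break
    centers <- new_c
  }
  list(cluster = cl, centers = centers)
}

#' Classify extensions as V-, D-, or J-derived by relative position
#'
#' One-dimensional k-means (k = 3, fixed initial centroids 0.1 / 0.5 / 0.9,
#' Lloyd iterations, deterministic) on the mean relative positions. The
#' cluster with the middle centroid is labelled `D`, the smallest-centroid
#' cluster `V`, the largest `J`. Fewer than 3 extensions, or all-identical
#' positions, degenerate to a single effective cluster: everything is
#' labelled `D` with a warning.
#'
#' @param extensions A tibble with a `mean_rp` column (see
#'   [mean_relative_positions()]).
#' @param centers Initial centroids (default `c(0.1, 0.5, 0.9)`).
#' @return The input with a `segment_class` column (`"V"`, `"D"`, `"J"`).
#' @export
classify_by_position <- function(extensions, centers = c(0.1, 0.5, 0.9)) {
  x <- extensions$mean_rp
  if (anyNA(x)) {
    abort("`mean_rp` contains NA; compute it on the CDR3 set first.",
          class = "dminer_contract_error")
  }
  if (length(x) < 3 || length(unique(x)) < 2) {
    warn("Too few distinct relative positions to separate V/D/J; labelling all as D.")
    extensions$segment_class <- rep("D", length(x))
    return(extensions)
  }
  fit <- lloyd_1d(x, centers)
  lab <- c("V", "D", "J")[rank(fit$centers, ties.method = "first")]
  extensions$segment_class <- lab[fit$cluster]
  extensions
}

#' Remove unidirectional extensions
#'
#' Extensions that grew in only one direction (zero extension steps on the
#' left or on the right) mostly originate from V-gene suffixes and J-gene
#' prefixes, which abut the CDR3 boundary on one side and therefore cannot be
#' extended past it. Genuine D genes, flanked by random insertions on both
#' sides, extend in both directions.
#'
#' @param extensions A tibble with `left_steps` and `right_steps` columns.
#' @param keep Set `TRUE` to disable the filter.
#' @return The filtered tibble.
#' @export
filter_unidirectional <- function(extensions, keep = FALSE) {
  if (keep) return(extensions)
  filter(extensions, .data$left_steps > 0, .data$right_steps > 0)
}

# longest common substring length of two strings (dynamic programming)
lcs_length <- function(a, b) {
  A <- utf8ToInt(a)
  B <- utf8ToInt(b)
  prev <- integer(length(B))
  best <- 0L
  for (i in seq_along(A)) {
    eq <- B == A[i]
    shifted <- c(0L, prev[-length(prev)])
    cur <- integer(length(B))
    cur[eq] <- shifted[eq] + 1L
    m <- max(cur)
    if (m > best) best <- m
    prev <- cur
  }
  best
}

#' Edge distance between two extensions
#'
#' `min(|e1|, |e2|) - |LCS(e1, e2)|`, where LCS is the longest common
#' substring: the number of nucleotides at the edges of the shorter extension
#' that must be changed or deleted to turn it into a substring of the other.
#' Symmetric, non-negative, and 0 exactly when one string is a substring of
#' the other.
#'
#' @param e1,e2 Non-empty nucleotide strings.
#' @return A non-negative integer.
#' @examples
#' similarity_distance("ACGTACGT", "TTACGTAA") # 3
#' @export
similarity_distance <- function(e1, e2) {
  stopifnot(nzchar(e1), nzchar(e2))
  min(nchar(e1), nchar(e2)) - lcs_length(e1, e2)
}

#' Longest common substring of a set of strings
#'
#' Enumerates substrings of the shortest member from longest to shortest and
#' returns the first (lexicographically smallest at each length) present in
#' every string. Returns `""` when the strings share no substring.
#'
#' @param strings Character vector (length >= 1).
#' @return A single string.
#' @export
longest_common_substring <- function(strings) {
  strings <- unique(strings)
  if (length(strings) == 1L) return(strings)
  pivot <- strings[which.min(nchar(strings))]
  others <- setdiff(strings, pivot)
  n <- nchar(pivot)
  for (len in n:1) {
    starts <- seq_len(n - len + 1L)
    cands <- sort(unique(stringi::stri_sub(pivot, starts, length = len)))
    for (cand in cands) {
      if (all(stringi::stri_detect_fixed(others, cand))) return(cand)
    }
  }
  ""
}

#' Build the similarity graph on extensions
#'
#' Nodes are distinct extension sequences; two nodes are adjacent when their
#' [similarity_distance()] does not exceed `max_dist`.
#'
#' @param sequences Character vector of extension sequences (duplicates are
#'   collapsed).
#' @param max_dist Edge threshold (default 2).
#' @return An undirected [igraph][igraph::graph_from_adjacency_matrix] graph
#'   whose vertex names are the sequences.
#' @export
similarity_graph <- function(sequences, max_dist = 2) {
  sequences <- unique(sequences)
  n <- length(sequences)
  adj <- matrix(0L, n, n, dimnames = list(sequences, sequences))
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (similarity_distance(sequences[i], sequences[j]) <= max_dist) {
          adj[i, j] <- adj[j, i] <- 1L
        }
      }
    }
  }
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

# maximal cliques ordered by decreasing size, ties by lexicographically
# smallest member; returns a list of character vectors of vertex names
ordered_cliques <- function(graph) {
  cl <- igraph::max_cliques(graph)
  members <- lapply(cl, function(v) sort(igraph::V(graph)$name[v]))
  ord <- order(-lengths(members),
               vapply(members, `[`, character(1), 1L))
  members[ord]
}

#' Merge cliques of similar extensions into candidate genes
#'
#' Multiple seeds of one D gene produce overlapping, truncated and slightly
#' shifted extensions. A similarity graph (edges at
#' [similarity_distance()] `<= max_dist`) is built on the distinct
#' extensions; maximal cliques are processed in decreasing size (ties by
#' lexicographically smallest member), each node consumed by at most one
#' clique. Each clique is replaced by the longest common substring of its
#' members, re-extended on the dataset with the stopping rule of
#' [extend_kmer()] (without branching). Cliques whose common substring is
#' shorter than `min_core` are passed through unmerged with a warning, and
#' singleton nodes pass through unchanged.
#'
#' @param sequences Character vector of extension sequences.
#' @param cdr3s The CDR3 set used for re-extension.
#' @param max_dist Similarity-graph edge threshold (default 2).
#' @param alpha Stopping-rule threshold for re-extension (default 1e-30).
#' @param min_core Minimum common-substring length for a merge (default 6 nt).
#' @param max_len Length cap for re-extension (default 50).
#' @param re_extend Set `FALSE` to keep the bare common substrings.
#' @return A character vector of distinct candidate sequences.
#' @export
merge_cliques <- function(sequences, cdr3s, max_dist = 2, alpha = 1e-30,
                          min_core = 6, max_len = 50, re_extend = TRUE) {
  sequences <- unique(sequences)
  if (length(sequences) <= 1L) return(sequences)
  g <- similarity_graph(sequences, max_dist = max_dist)
  cliques <- ordered_cliques(g)
  consumed <- setNames(rep(FALSE, length(sequences)), sequences)
  out <- character()
  for (cl in cliques) {
    avail <- cl[!consumed[cl]]
    if (length(avail) < 2L) next
    core <- longest_common_substring(avail)
    if (nchar(core) < min_core) {
      warn(sprintf(
        "Clique of %d extensions shares only a %d nt substring (< %d); left unmerged.",
        length(avail), nchar(core), min_core))
      next
    }
    consumed[avail] <- TRUE
    merged <- if (re_extend) {
      extend_kmer(cdr3s, core, alpha = alpha, max_len = max_len,
                  branch = FALSE)$sequence[1L]
    } else {
      core
    }
    out <- c(out, merged)
  }
  unique(c(out, sequences[!consumed]))
}

#' Consolidate candidate genes across datasets
#'
#' Takes the union of per-dataset candidate sets, drops candidates that are
#' proper substrings of another candidate, and merges remaining candidates
#' within [similarity_distance()] `<= max_dist` by the clique procedure
#' (longest common substring, no re-extension).
#'
#' @param candidate_lists A list of character vectors (or a single vector).
#' @param max_dist Similarity threshold (default 2).
#' @param min_core Minimum common-substring length for a merge (default 6).
#' @return A character vector of consolidated candidates.
#' @export
merge_across_datasets <- function(candidate_lists, max_dist = 2,
                                  min_core = 6) {
  cands <- unique(unlist(candidate_lists, use.names = FALSE))
  if (length(cands) <= 1L) return(cands)
  is_sub <- vapply(seq_along(cands), function(i) {
    any(stringi::stri_detect_fixed(cands[-i], cands[i]) &
          nchar(cands[-i]) > nchar(cands[i]))
  }, logical(1))
  cands <- cands[!is_sub]
  if (length(cands) <= 1L) return(cands)
  g <- similarity_graph(cands, max_dist = max_dist)
  cliques <- ordered_cliques(g)
  consumed <- setNames(rep(FALSE, length(cands)), cands)
  out <- character()
  for (cl in cliques) {
    avail <- cl[!consumed[cl]]
    if (length(avail) < 2L) next
    core <- longest_common_substring(avail)
    if (nchar(core) < min_core) next
    consumed[avail] <- TRUE
    out <- c(out, core)
  }
  unique(c(out, cands[!consumed]))
}
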