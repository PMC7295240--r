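#' Full generative model of CDR3 formation by V(D)J recombination
#'
#' Each CDR3 is assembled as `v_l + e_l + trimmed(s) + e_r + j_r`: a D gene
#' `s` is drawn from a weighted set of seed strings, trimmed by `p` symbols on
#' the left and `q` on the right (`p + q <= |s|`), flanked by untemplated
#' insertions `e_l`, `e_r` of random lengths with uniform random symbols, and
#' finally framed by a V-gene suffix `v_l` and a J-gene prefix `j_r` drawn
#' from weighted sets.
#'
#' Trimming lengths follow a truncated geometric-like law `P(t) ~ rate^t` on
#' `0..bound` (first `p` with bound `|s|`, then `q` with bound `|s| - p`),
#' mimicking the short exonuclease chews seen in real junctions. Insertion
#' lengths are uniform on `0..max_insertion`.
#'
#' @param genes Named character vector of D-gene sequences (names default to
#'   `gene1..geneM`), or a tibble with columns `gene`, `sequence` and
#'   optionally `weight`.
#' @param gene_weights Selection weights (default uniform).
#' @param trim_rate Geometric decay rate of the trimming law (default 0.7).
#' @param max_insertion Maximum insertion length per side (default 6).
#' @param v_suffixes,j_prefixes Character vectors of V-gene suffixes /
#'   J-gene prefixes appearing inside CDR3s (defaults: four short fixed
#'   fragments each, lengths 3-8).
#' @param v_weights,j_weights Selection weights (default uniform).
#' @return An object of class `generative_model`.
#' @seealso [simulate_cdr3s()]
#' @export
generative_model <- function(genes,
                             gene_weights = NULL,
                             trim_rate = 0.7,
                             max_insertion = 6,
                             v_suffixes = c("GCGAGAGA", "GCGAGA", "GCAAGAC",
                                            "TGTACC"),
                             j_prefixes = c("CTTTGACT", "TTGACTAC", "ACTTCC",
                                            "GACTAC"),
                             v_weights = NULL,
                             j_weights = NULL) {
  if (is.data.frame(genes)) {
    gene_weights <- gene_weights %||%
      (if ("weight" %in% names(genes)) genes$weight else NULL)
    genes <- setNames(genes$sequence, genes$gene)
  }
  genes <- stringi::stri_trans_toupper(genes)
  if (is.null(names(genes)) || any(!nzchar(names(genes)))) {
    names(genes) <- paste0("gene", seq_along(genes))
  }
  norm_w <- function(w, n, what) {
    w <- w %||% rep(1, n)
    if (length(w) != n || any(w < 0) || sum(w) <= 0) {
      abort(sprintf("Invalid %s weights.", what))
    }
    w / sum(w)
  }
  stopifnot(trim_rate > 0, trim_rate <= 1, max_insertion >= 0,
            length(v_suffixes) >= 1, length(j_prefixes) >= 1)
  structure(list(
    genes = genes,
    gene_weights = norm_w(gene_weights, length(genes), "gene"),
    trim_rate = trim_rate,
    max_insertion = as.integer(max_insertion),
    v_suffixes = stringi::stri_trans_toupper(v_suffixes),
    j_prefixes = stringi::stri_trans_toupper(j_prefixes),
    v_weights = norm_w(v_weights, length(v_suffixes), "V suffix"),
    j_weights = norm_w(j_weights, length(j_prefixes), "J prefix")
  ), class = "generative_model")
}

#' @export
print.generative_model <- function(x, ...) {
  cat(sprintf(paste0("<generative_model> %d D genes (lengths %d-%d), ",
                     "trim rate %.2f, insertions 0-%d, %d V suffixes, ",
                     "%d J prefixes\n"),
              length(x$genes), min(nchar(x$genes)), max(nchar(x$genes)),
              x$trim_rate, x$max_insertion,
              length(x$v_suffixes), length(x$j_prefixes)))
  invisible(x)
}

# truncated geometric draw: for each i, t_i in 0..bound_i with P(t) ~ rate^t
rtrunc_geom <- function(bounds, rate) {
  out <- integer(length(bounds))
  for (b in unique(bounds)) {
    sel <- bounds == b
    p <- rate^(0:b)
    out[sel] <- sample.int(b + 1L, sum(sel), replace = TRUE,
                           prob = p / sum(p)) - 1L
  }
  out
}

#' Simulate CDR3s with per-read truth labels
#'
#' Draws `n` CDR3s from a [generative_model()]. The returned tibble keeps the
#' full provenance of every read (which gene, trims, insertion lengths, which
#' V suffix and J prefix) so that parameter- and gene-recovery experiments can
#' compare inferences against ground truth.
#'
#' @param model A [generative_model()].
#' @param n Number of CDR3s.
#' @param rng_seed Optional integer seed; a single seed fully determines the
#'   output.
#' @return A tibble with columns `read_id`, `sequence`, `gene`, `p`, `q`,
#'   `l_l`, `l_r`, `v_id`, `j_id`. Aggregate with [cdr3_set()] for inference.
#' @export
simulate_cdr3s <- function(model, n, rng_seed = NULL) {
  stopifnot(n >= 1)
  run <- function() {
    gi <- sample.int(length(model$genes), n, replace = TRUE,
                     prob = model$gene_weights)
    L <- nchar(model$genes)[gi]
    p <- rtrunc_geom(L, model$trim_rate)
    q <- rtrunc_geom(L - p, model$trim_rate)
    core <- stringi::stri_sub(model$genes[gi], p + 1L, L - q)
    l_l <- sample.int(model$max_insertion + 1L, n, replace = TRUE) - 1L
    l_r <- sample.int(model$max_insertion + 1L, n, replace = TRUE) - 1L
    e_l <- random_strings(l_l)
    e_r <- random_strings(l_r)
    vi <- sample.int(length(model$v_suffixes), n, replace = TRUE,
                     prob = model$v_weights)
    ji <- sample.int(length(model$j_prefixes), n, replace = TRUE,
                     prob = model$j_weights)
    tibble(
      read_id = paste0("read_", seq_len(n)),
      sequence = paste0(model$v_suffixes[vi], e_l, core, e_r,
                        model$j_prefixes[ji]),
      gene = names(model$genes)[gi],
      p = p, q = q, l_l = l_l, l_r = l_r,
      v_id = vi, j_id = ji
    )
  }
  if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
}

#' Generate random D-gene sequences
#'
#' Utility for planted-gene simulations: `n` uniform random nucleotide
#' sequences with lengths sampled uniformly from `len_range`, named
#' `gene1..geneN`.
#'
#' @param n Number of genes.
#' @param len_range Length range (default 12-35, the span of known D-gene
#'   lengths across well-annotated species).
#' @param rng_seed Optional integer seed.
#' @return A named character vector.
#' @export
random_d_genes <- function(n, len_range = c(12, 35), rng_seed = NULL) {
  run <- function() {
    rng <- len_range[1]:len_range[2]
    lens <- rng[sample.int(length(rng), n, replace = TRUE)]
    setNames(random_strings(lens), paste0("gene", seq_len(n)))
  }
  if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
}

#' Apply uniform point mutations to sequences
#'
#' Post-hoc substitution noise used for robustness experiments (e.g. the
#' decoy-allele analysis of hypermutation-driven allele misassignment). Each
#' base is substituted independently with probability `rate`, to one of the
#' three other bases chosen uniformly. This is deliberately a standalone
#' utility: somatic hypermutation is treated as a confounder of germline
#' inference, not as a component of the generative model.
#'
#' @param sequences Character vector of nucleotide sequences.
#' @param rate Per-base substitution probability.
#' @param rng_seed Optional integer seed.
#' @return A character vector of mutated sequences.
#' @export
mutate_sequences <- function(sequences, rate, rng_seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(sequences)
  run <- function() {
    lens <- nchar(sequences)
    idx <- rep.int(seq_along(sequences), lens)
    pos <- sequence(lens)
    hit <- stats::runif(length(pos)) < rate
    if (!any(hit)) return(sequences)
    out <- sequences
    for (i in unique(idx[hit])) {
      sel <- hit & idx == i
      ch <- stringi::stri_sub(out[i], pos[sel], length = 1L)
      repl <- vapply(ch, function(b) sample(setdiff(DNA_BASES, b), 1L),
                     character(1))
      for (k in seq_along(repl)) {
        stringi::stri_sub(out[i], pos[sel][k], length = 1L) <- repl[k]
      }
    }
    out
  }
  if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
}
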