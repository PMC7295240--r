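#' One-sided trimming model of CDR3 generation
#'
#' The simple generative model behind the string-reconstruction view of D-gene
#' inference: a seed string `s` over an alphabet `A` is trimmed by an integer
#' `k` drawn uniformly from `0..|s|` (the last `k` symbols are removed) and
#' then re-extended on the right by `k` symbols drawn uniformly from `A`.
#' Modified strings therefore always have length `|s|`, and the probability of
#' observing a given modified string depends only on the length of its longest
#' shared prefix with the seed.
#'
#' @param seed Seed string (non-empty).
#' @param alphabet Ordered symbol set (default A, C, G, T; at least 2 symbols).
#' @return An object of class `simple_model`.
#' @examples
#' m <- simple_model("ATGA")
#' prob_modified_given_seed(m, "ATCC")
#' @export
simple_model <- function(seed, alphabet = DNA_BASES) {
  seed <- as.character(seed)
  stopifnot(nzchar(seed), length(alphabet) >= 2)
  chars <- stringi::stri_sub(seed, seq_len(nchar(seed)), length = 1L)
  if (!all(chars %in% alphabet)) {
    abort("Seed contains symbols outside the alphabet.")
  }
  structure(list(seed = seed, alphabet = alphabet),
            class = "simple_model")
}

#' @export
print.simple_model <- function(x, ...) {
  cat(sprintf("<simple_model> seed %s (length %d), alphabet {%s}\n",
              x$seed, nchar(x$seed), paste(x$alphabet, collapse = ",")))
  invisible(x)
}

# coerce character vectors / data frames to a (sequence, count) tibble
# without the DNA-alphabet validation of cdr3_set(); the reconstruction
# layer works over arbitrary alphabets
as_seq_tbl <- function(x) {
  if (is.data.frame(x)) {
    out <- as_tibble(x)
    if (!"count" %in% names(out)) out$count <- 1
    return(out)
  }
  tibble(sequence = as.character(x), count = 1)
}

# length of the longest shared prefix of two equal-length strings
shared_prefix_len <- function(s, c) {
  eq <- utf8ToInt(s) == utf8ToInt(c)
  mism <- match(FALSE, eq)
  if (is.na(mism)) length(eq) else mism - 1L
}

#' Probability of one trimming value generating a modified string
#'
#' Probability that the seed, trimmed by exactly `trim` symbols and
#' re-extended at random, yields `c`: `1/(|s|+1) * |A|^(-trim)` when the
#' retained prefix of the seed matches the corresponding prefix of `c`,
#' otherwise 0.
#'
#' @param model A [simple_model()].
#' @param c Modified string of the same length as the seed.
#' @param trim Trimming integer in `0..|s|`.
#' @return A probability.
#' @examples
#' trim_extend_probability(simple_model("ATGA"), "ATCC", trim = 2) # 1/80
#' @export
trim_extend_probability <- function(model, c, trim) {
  s <- model$seed
  n <- nchar(s)
  if (nchar(c) != n) {
    abort("`c` must have the same length as the seed.",
          class = "dminer_contract_error")
  }
  stopifnot(trim >= 0, trim <= n)
  a <- length(model$alphabet)
  keep <- n - trim
  if (keep > 0 &&
      stringi::stri_sub(s, 1, keep) != stringi::stri_sub(c, 1, keep)) {
    return(0)
  }
  (1 / (n + 1)) * a^(-trim)
}

#' Likelihood of a modified string under the one-sided trimming model
#'
#' Marginalises [trim_extend_probability()] over all trimming values. The sum
#' has the closed form `K(|s|,|A|) * (|A|^(m+1) - 1)` where `m` is the length
#' of the longest shared prefix of seed and modified string and
#' `K = 1 / ((|s|+1) * |A|^|s| * (|A|-1))`.
#'
#' @inheritParams trim_extend_probability
#' @param method `"closed_form"` (default) or `"sum"` (explicit sum over
#'   trimming values; used to cross-check the algebra).
#' @return A probability. Summed over all `|A|^|s|` modified strings it is 1.
#' @export
prob_modified_given_seed <- function(model, c, method = c("closed_form", "sum")) {
  method <- match.arg(method)
  s <- model$seed
  n <- nchar(s)
  if (nchar(c) != n) {
    abort("`c` must have the same length as the seed.",
          class = "dminer_contract_error")
  }
  a <- length(model$alphabet)
  if (method == "sum") {
    return(sum(vapply(0:n, function(k) trim_extend_probability(model, c, k),
                      numeric(1))))
  }
  m <- shared_prefix_len(s, c)
  (a^(m + 1) - 1) / ((n + 1) * a^n * (a - 1))
}

#' Log-likelihood score of a seed string for a set of modified strings
#'
#' For equal-length modified strings `c_i` with multiplicities `w_i`, returns
#' `sum_i w_i * log(|A|^(m_i+1) - 1)` (natural log), where `m_i` is the longest
#' shared prefix of `s` and `c_i`. Maximising this score over seed strings is
#' equivalent to maximising the model likelihood, since the two differ by the
#' constant `N * log((|s|+1) * |A|^|s| * (|A|-1))`.
#'
#' @param cdr3s A CDR3 set whose sequences all have length `nchar(s)`.
#' @param s Candidate seed string.
#' @param alphabet Symbol set (default A/C/G/T).
#' @return The score (0 for an empty set).
#' @export
score_set <- function(cdr3s, s, alphabet = DNA_BASES) {
  cdr3s <- as_seq_tbl(cdr3s)
  if (nrow(cdr3s) == 0) return(0)
  if (any(nchar(cdr3s$sequence) != nchar(s))) {
    abort("All sequences must have the same length as `s`.",
          class = "dminer_contract_error")
  }
  a <- length(alphabet)
  m <- vapply(cdr3s$sequence, shared_prefix_len, integer(1), s = s,
              USE.NAMES = FALSE)
  sum(cdr3s$count * log(a^(m + 1) - 1))
}

#' Greedy seed reconstruction from modified strings
#'
#' Builds the seed left to right: at each position the multiplicity-weighted
#' most abundant symbol among currently retained strings is appended (ties
#' broken alphabetically) and strings whose symbol at that position differs
#' are discarded. The retained set never empties because the chosen symbol is
#' observed in at least one retained string.
#'
#' @param cdr3s A CDR3 set whose sequences all have length >= `target_len`.
#' @param target_len Length of the seed to reconstruct.
#' @return The reconstructed string.
#' @export
reconstruct_seed_greedy <- function(cdr3s, target_len) {
  cdr3s <- as_seq_tbl(cdr3s)
  stopifnot(target_len >= 1, all(nchar(cdr3s$sequence) >= target_len))
  seqs <- cdr3s$sequence
  w <- cdr3s$count
  keep <- rep(TRUE, length(seqs))
  out <- character(target_len)
  for (j in seq_len(target_len)) {
    sym <- stringi::stri_sub(seqs[keep], j, j)
    tallies <- rowsum(w[keep], sym)
    top <- rownames(tallies)[tallies[, 1] == max(tallies[, 1])]
    out[j] <- sort(top)[1L]
    keep[keep] <- sym == out[j]
  }
  paste(out, collapse = "")
}

#' Exhaustive seed reconstruction (testing oracle)
#'
#' Enumerates every string of length `target_len` over the alphabet and
#' returns the one maximising [score_set()], breaking ties lexicographically.
#' Exponential in `target_len`; refuses search spaces above `10^7` candidates.
#' Intended as a small-instance oracle against which the greedy and
#' extension-based reconstructions are compared.
#'
#' @inheritParams score_set
#' @param target_len Seed length.
#' @return The maximising string.
#' @export
brute_force_reconstruct <- function(cdr3s, target_len, alphabet = DNA_BASES) {
  cdr3s <- as_seq_tbl(cdr3s)
  a <- length(alphabet)
  if (a^target_len > 1e7) {
    abort("Search space exceeds 10^7 candidates.",
          class = "dminer_refusal_error")
  }
  stopifnot(all(nchar(cdr3s$sequence) == target_len))
  # candidate matrix in lexicographic row order
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), target_len),
                    list(stringsAsFactors = FALSE)))[, target_len:1, drop = FALSE]
  ord <- do.call(order, as.list(grid))
  grid <- as.matrix(grid)[ord, , drop = FALSE]

  cmat <- matrix(stringi::stri_sub(rep(cdr3s$sequence, each = target_len),
                                   rep(seq_len(target_len), nrow(cdr3s)),
                                   length = 1L),
                 nrow = nrow(cdr3s), ncol = target_len, byrow = TRUE)
  w <- cdr3s$count
  loga <- function(m) log(a^(m + 1) - 1)
  best <- -Inf
  best_s <- NULL
  for (i in seq_len(nrow(grid))) {
    v <- grid[i, ]
    m <- integer(nrow(cmat))
    alive <- rep(TRUE, nrow(cmat))
    for (j in seq_len(target_len)) {
      alive <- alive & (cmat[, j] == v[j])
      if (!any(alive)) break
      m[alive] <- j
    }
    sc <- sum(w * loga(m))
    if (sc > best + 1e-12) { # strict improvement keeps lexicographic ties
      best <- sc
      best_s <- paste(v, collapse = "")
    }
  }
  best_s
}

#' Simulate modified strings from the one-sided trimming model
#'
#' @param model A [simple_model()].
#' @param n Number of draws.
#' @param rng_seed Optional integer seed; a single seed fully determines the
#'   output.
#' @return A tibble with one row per draw, columns `sequence` and `trim`.
#'   Aggregate with [cdr3_set()] for downstream use.
#' @export
simulate_simple <- function(model, n, rng_seed = NULL) {
  stopifnot(n >= 1)
  run <- function() {
    s <- model$seed
    L <- nchar(s)
    k <- sample.int(L + 1L, n, replace = TRUE) - 1L
    prefix <- stringi::stri_sub(s, 1, L - k)
    tails <- random_strings(k, model$alphabet)
    tibble(sequence = paste0(prefix, tails), trim = k)
  }
  if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
}

# n random strings with given lengths (vector), uniform over alphabet
random_strings <- function(lengths, alphabet = DNA_BASES) {
  total <- sum(lengths)
  if (total == 0) return(rep("", length(lengths)))
  chars <- sample(alphabet, total, replace = TRUE)
  f <- factor(rep.int(seq_along(lengths), lengths),
              levels = seq_along(lengths))
  vapply(split(chars, f), paste, character(1), collapse = "")
}
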