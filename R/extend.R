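#' Select seed k-mers
#'
#' The `m` most abundant k-mers of the dataset, ties at the cut broken
#' lexicographically. Fewer than `m` k-mers returns all of them.
#'
#' @param kmers A k-mer table from [count_kmers()].
#' @param m Number of seeds. Defaults depend on the species (600 works well
#'   for human-sized repertoires, 300 for mouse).
#' @return A tibble with columns `kmer` and `count`.
#' @export
select_seeds <- function(kmers, m = 600) {
  stopifnot(m >= 1)
  if (nrow(kmers) == 0) {
    warn("Empty k-mer table; no seeds selected.")
    return(kmers)
  }
  kmers |>
    arrange(desc(.data$count), .data$kmer) |>
    slice_head(n = m)
}

# chi-square goodness-of-fit against a uniform multinomial.
# Returns the statistic and the log upper-tail probability (df = cells - 1),
# worked in log space so that astronomically small p-values stay comparable.
chisq_uniform <- function(counts) {
  total <- sum(counts)
  df <- length(counts) - 1L
  if (total == 0) {
    return(list(statistic = 0, df = df, log_p = 0))
  }
  e <- total / length(counts)
  s <- sum((counts - e)^2 / e)
  list(statistic = s, df = df,
       log_p = pchisq(s, df = df, lower.tail = FALSE, log.p = TRUE))
}

#' Test nucleotide extension counts against a uniform null
#'
#' Given the observed abundances of the four single-nucleotide extensions of a
#' string (in A, C, G, T order), tests the null hypothesis that the flanking
#' nucleotide is a uniformly random insertion. Under the null the expected
#' abundances are equal (`E_i = total/4`) and the statistic
#' `S = sum_i (N_i - E_i)^2 / E_i` is approximately chi-square with 3 degrees
#' of freedom. All-zero counts are a "no data" outcome: the null is accepted.
#'
#' @param counts Four non-negative counts (A, C, G, T).
#' @param alpha Significance threshold; the null is rejected when the p-value
#'   falls below it. The default 1e-30 rejects only for extreme departures
#'   from uniformity, i.e. when one extension vastly dominates.
#' @return A one-row tibble with columns `statistic`, `df`, `p_value`,
#'   `log_p`, `reject`.
#' @examples
#' extension_test(c(30, 0, 0, 0), alpha = 1e-6)
#' @export
extension_test <- function(counts, alpha = 1e-30) {
  stopifnot(length(counts) == 4, all(counts >= 0), alpha > 0, alpha < 1)
  res <- chisq_uniform(counts)
  tibble(statistic = res$statistic, df = res$df,
         p_value = exp(res$log_p), log_p = res$log_p,
         reject = res$log_p < log(alpha))
}

# weighted tally of flanking characters into A/C/G/T cells; characters
# outside the alphabet (including "" at a sequence boundary) are dropped,
# so boundary occurrences contribute to no extension on that side
tally_bases <- function(chars, wt) {
  out <- setNames(numeric(4), DNA_BASES)
  keep <- chars %in% DNA_BASES
  if (any(keep)) {
    obs <- rowsum(wt[keep], chars[keep])
    out[rownames(obs)] <- obs[, 1]
  }
  out
}

# all occurrences of `x` across `seqs` as parallel vectors (sequence index,
# 1-based start position)
locate_occurrences <- function(seqs, x) {
  loc <- stringi::stri_locate_all_fixed(seqs, x, omit_no_match = TRUE)
  n_occ <- vapply(loc, nrow, integer(1))
  list(idx = rep.int(seq_along(seqs), n_occ),
       start = unlist(lapply(loc, function(m) m[, 1]), use.names = FALSE))
}

#' Extend a seed k-mer into candidate D genes
#'
#' Iteratively grows the seed on both sides. At each state the occurrence
#' abundances of the four left and four right single-nucleotide extensions are
#' gathered from the CDR3s containing the current string and each side is
#' tested with [extension_test()]. If exactly one side rejects the uniform
#' null, the string is extended on that side by its most abundant symbol; if
#' both sides reject, the side with the smaller p-value is extended (ties go
#' left); if both accept, the branch terminates. After every extension step
#' the remaining three extensions of the extended side are tested against a
#' uniform null (expected `total/3`, chi-square df 2, threshold
#' `branch_alpha`); rejection forks an independent continuation from the
#' runner-up extension, which is how a k-mer shared by two D genes yields both
#' genes. Branches are pursued depth-first until all terminate.
#'
#' The procedure involves no randomness: reruns on the same dataset return
#' identical results.
#'
#' @param cdr3s A CDR3 set.
#' @param seed A k-mer occurring in at least one CDR3.
#' @param alpha Significance threshold of the stopping rule (default 1e-30).
#' @param branch_alpha Threshold of the runner-up test (default `alpha`).
#' @param max_len Hard cap on extension length (default 50 nt, comfortably
#'   above the longest known D genes).
#' @param max_branches Cap on simultaneously live branches per seed
#'   (default 8); forks beyond the cap are skipped, keeping the
#'   higher-support main path, and `"branch_cap_hit"` is set on the result.
#' @param branch Set `FALSE` to disable forking (single maximal extension).
#' @param .occ Precomputed seed occurrences (internal; used by
#'   [extend_seeds()] to avoid rescanning the dataset per seed).
#' @return A tibble of distinct terminal extensions with columns `sequence`,
#'   `seed`, `left_steps`, `right_steps`, `support` (multiplicity-weighted
#'   number of CDR3s containing the extension), `n_cdr3s` (distinct CDR3s),
#'   and `stopped` (`"both_accept"` or `"max_len"`).
#' @export
extend_kmer <- function(cdr3s, seed, alpha = 1e-30, branch_alpha = alpha,
                        max_len = 50, max_branches = 8, branch = TRUE,
                        .occ = NULL) {
  seqs <- cdr3s$sequence
  w <- cdr3s$count
  occ0 <- .occ %||% locate_occurrences(seqs, seed)
  if (length(occ0$idx) == 0) {
    abort("`seed` does not occur in the CDR3 set.",
          class = "dminer_contract_error")
  }
  log_alpha <- log(alpha)
  log_branch_alpha <- log(branch_alpha)
  cap_hit <- FALSE

  # each state tracks every occurrence of its current string as parallel
  # (sequence index, start) vectors, updated incrementally: extending by a
  # symbol keeps exactly the occurrences flanked by that symbol
  stack <- list(list(seq = seed, idx = occ0$idx, start = occ0$start,
                     l = 0L, r = 0L))
  done <- list()
  while (length(stack) > 0) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL

    repeat {
      L <- nchar(st$seq)
      if (L >= max_len) {
        st$stopped <- "max_len"
        done[[length(done) + 1L]] <- st
        break
      }
      sseq <- seqs[st$idx]
      wt <- w[st$idx]
      lch <- stringi::stri_sub(sseq, st$start - 1L, st$start - 1L)
      rch <- stringi::stri_sub(sseq, st$start + L, st$start + L)
      tl <- chisq_uniform(tally_bases(lch, wt))
      tr <- chisq_uniform(tally_bases(rch, wt))
      rej_l <- tl$log_p < log_alpha
      rej_r <- tr$log_p < log_alpha
      if (!rej_l && !rej_r) {
        st$stopped <- "both_accept"
        done[[length(done) + 1L]] <- st
        break
      }
      side <- if (rej_l && rej_r) {
        if (tl$log_p <= tr$log_p) "left" else "right"
      } else if (rej_l) "left" else "right"
      ch <- if (side == "left") lch else rch
      cnt <- tally_bases(ch, wt)
      ord <- order(-cnt, names(cnt)) # most abundant, alphabetic ties
      top <- names(cnt)[ord[1L]]
      grow <- function(sym) {
        if (side == "left") paste0(sym, st$seq) else paste0(st$seq, sym)
      }

      if (branch) {
        rest <- cnt[ord[-1L]]
        bt <- chisq_uniform(rest)
        if (bt$log_p < log_branch_alpha && rest[1L] > 0) {
          if (length(stack) + 1L < max_branches) {
            alt_keep <- ch == names(rest)[1L]
            alt <- st
            alt$seq <- grow(names(rest)[1L])
            alt$idx <- st$idx[alt_keep]
            alt$start <- if (side == "left") st$start[alt_keep] - 1L
                         else st$start[alt_keep]
            if (side == "left") alt$l <- alt$l + 1L else alt$r <- alt$r + 1L
            stack[[length(stack) + 1L]] <- alt
          } else {
            cap_hit <- TRUE
          }
        }
      }

      keep <- ch == top
      st$seq <- grow(top)
      st$idx <- st$idx[keep]
      st$start <- if (side == "left") st$start[keep] - 1L else st$start[keep]
      if (side == "left") st$l <- st$l + 1L else st$r <- st$r + 1L
    }
  }

  out <- tibble(
    sequence = vapply(done, `[[`, character(1), "seq"),
    seed = seed,
    left_steps = vapply(done, `[[`, integer(1), "l"),
    right_steps = vapply(done, `[[`, integer(1), "r"),
    support = vapply(done, function(d) sum(w[unique(d$idx)]), numeric(1)),
    n_cdr3s = vapply(done, function(d) length(unique(d$idx)), integer(1)),
    stopped = vapply(done, `[[`, character(1), "stopped")
  ) |>
    distinct(.data$sequence, .keep_all = TRUE) |>
    arrange(desc(.data$support), .data$sequence)
  attr(out, "branch_cap_hit") <- cap_hit
  out
}

#' Extend every selected seed of a dataset
#'
#' Convenience wrapper running [extend_kmer()] over the seeds chosen by
#' [select_seeds()] from the dataset's k-mer counts.
#'
#' @param cdr3s A CDR3 set.
#' @param k Seed k-mer length (default 10; short enough not to exceed the
#'   length of known D genes).
#' @param num_seeds Number of seeds `m` (default 600).
#' @inheritParams extend_kmer
#' @return A tibble of extensions (one row per seed x terminal branch), with
#'   the same columns as [extend_kmer()].
#' @export
extend_seeds <- function(cdr3s, k = 10, num_seeds = 600, alpha = 1e-30,
                         branch_alpha = alpha, max_len = 50,
                         max_branches = 8) {
  seeds <- select_seeds(count_kmers(cdr3s, k), m = num_seeds)
  if (nrow(seeds) == 0) {
    return(tibble(sequence = character(), seed = character(),
                  left_steps = integer(), right_steps = integer(),
                  support = numeric(), n_cdr3s = integer(),
                  stopped = character()))
  }
  occs <- seed_occurrences(cdr3s, seeds$kmer, k)
  purrr::map2(seeds$kmer, occs, function(s, occ) {
    extend_kmer(cdr3s, s, alpha = alpha, branch_alpha = branch_alpha,
                max_len = max_len, max_branches = max_branches, .occ = occ)
  }) |>
    bind_rows()
}

# one windowed pass locating every occurrence of every seed k-mer
seed_occurrences <- function(cdr3s, seeds, k) {
  lens <- nchar(cdr3s$sequence)
  keep <- which(lens >= k)
  n_win <- lens[keep] - k + 1L
  idx <- rep.int(keep, n_win)
  start <- sequence(n_win)
  km <- stringi::stri_sub(cdr3s$sequence[idx], start, start + k - 1L)
  hit <- match(km, seeds)
  ok <- !is.na(hit)
  f <- factor(hit[ok], levels = seq_along(seeds))
  purrr::map2(split(idx[ok], f), split(start[ok], f),
              function(i, s) list(idx = i, start = s))
}
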