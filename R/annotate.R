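# best ungapped overlap alignment over all relative offsets:
# returns matches, overlap length and identity (= matches / min length * 100).
best_ungapped_overlap <- function(a, b) {
  A <- utf8ToInt(a)
  B <- utf8ToInt(b)
  na <- length(A)
  nb <- length(B)
  best <- list(matches = 0L, overlap = 0L)
  for (shift in (-(nb - 1L)):(na - 1L)) {
    ia <- max(1L, 1L + shift):min(na, nb + shift)
    ib <- ia - shift
    m <- sum(A[ia] == B[ib])
    if (m > best$matches ||
        (m == best$matches && length(ia) > best$overlap)) {
      best <- list(matches = m, overlap = length(ia), shift = shift)
    }
  }
  best$identity <- 100 * best$matches / min(na, nb)
  best
}

#' Percent identity between two nucleotide sequences
#'
#' Best ungapped overlap alignment over all relative offsets;
#' identity = matches / min(length) * 100. D-gene variants differ by
#' substitutions and end truncations, so no internal gaps are modelled; the
#' min-length denominator penalises neither direction of truncation.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Percent identity in `[0, 100]`. Symmetric in its arguments.
#' @export
percent_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  best_ungapped_overlap(a, b)$identity
}

#' Classify a candidate gene against a germline database
#'
#' A candidate is
#' \describe{
#'   \item{`in_db`}{equal to a database sequence, a substring of one, or a
#'     substring of one extended by at most `extension` extra nucleotides at
#'     the start and/or end (default 3) -- the core substring must occur in
#'     the database entry;}
#'   \item{`novel_variation`}{otherwise, if its best [percent_identity()]
#'     against the database exceeds `identity_threshold` (default 75);}
#'   \item{`novel_gene`}{otherwise (identity at or below the threshold
#'     against every entry).}
#' }
#' The closest entry is chosen by identity, then longest overlap, then
#' lexicographic name. Labels are exhaustive and mutually exclusive, and
#' adding database entries can only move a candidate towards
#' `in_db`/`novel_variation`, never towards `novel_gene`.
#'
#' @param candidate Candidate nucleotide sequence.
#' @param db A germline database tibble (see [germline_db()]).
#' @param extension Maximum extra nucleotides per end for the `in_db` rule
#'   (default 3).
#' @param identity_threshold Percent identity boundary between
#'   `novel_variation` and `novel_gene` (default 75).
#' @return A one-row tibble: `sequence`, `classification`, `closest_gene`,
#'   `closest_allele`, `closest_name`, `identity`.
#' @export
classify_candidate <- function(candidate, db, extension = 3,
                               identity_threshold = 75) {
  stopifnot(extension >= 0, identity_threshold > 0, identity_threshold < 100)
  row <- function(class, gene = NA_character_, allele = NA_character_,
                  name = NA_character_, identity = NA_real_) {
    tibble(sequence = candidate, classification = class,
           closest_gene = gene, closest_allele = allele,
           closest_name = name, identity = identity)
  }
  if (nrow(db) == 0) {
    warn("Empty germline database; candidate labelled novel_gene.")
    return(row("novel_gene"))
  }
  n <- nchar(candidate)
  # in_db: strip up to `extension` nt from each end and look for the core
  for (l in 0:min(extension, n - 1L)) {
    for (r in 0:min(extension, n - l - 1L)) {
      core <- stringi::stri_sub(candidate, l + 1L, n - r)
      hit <- stringi::stri_detect_fixed(db$sequence, core)
      if (any(hit)) {
        i <- which(hit)[order(db$name[hit])][1L]
        return(row("in_db", db$gene[i], db$allele[i], db$name[i],
                   percent_identity(candidate, db$sequence[i])))
      }
    }
  }
  aligns <- lapply(db$sequence, best_ungapped_overlap, a = candidate)
  ident <- vapply(aligns, `[[`, numeric(1), "identity")
  overlap <- vapply(aligns, `[[`, integer(1), "overlap")
  best <- order(-ident, -overlap, db$name)[1L]
  class <- if (ident[best] > identity_threshold) "novel_variation"
           else "novel_gene"
  row(class, db$gene[best], db$allele[best], db$name[best], ident[best])
}

#' Classify many candidates against a germline database
#'
#' @param candidates Character vector of candidate sequences, or a tibble
#'   with a `sequence` column.
#' @inheritParams classify_candidate
#' @return A tibble with one row per candidate (see [classify_candidate()]).
#' @export
annotate_candidates <- function(candidates, db, extension = 3,
                                identity_threshold = 75) {
  seqs <- if (is.data.frame(candidates)) candidates$sequence else candidates
  purrr::map(seqs, classify_candidate, db = db, extension = extension,
             identity_threshold = identity_threshold) |>
    bind_rows()
}
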