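#' Build a CDR3 set from nucleotide sequences
#'
#' A CDR3 set is a tibble with one row per distinct CDR3 nucleotide sequence
#' and columns `sequence` (uppercase, alphabet A/C/G/T) and `count` (positive
#' integer multiplicity). All repertoire functions in the package consume and
#' produce this shape. Sequences are upper-cased, records containing symbols
#' outside A/C/G/T are dropped (with a message reporting how many), and
#' duplicate sequences have their counts aggregated.
#'
#' @param x A character vector of sequences, or a data frame with a
#'   `sequence` column and an optional `count` column.
#' @param count Optional multiplicities, recycled against `x` when `x` is a
#'   character vector. Records without an abundance count 1.
#' @param label Optional free-text dataset identifier, stored as the
#'   `"label"` attribute.
#' @return A tibble with columns `sequence` and `count`, sorted by decreasing
#'   count then sequence.
#' @examples
#' cdr3_set(c("ACGT", "acgt", "AATT", "ACGN"))
#' @export
cdr3_set <- function(x, count = NULL, label = NULL) {
  if (is.data.frame(x)) {
    if (!"sequence" %in% names(x)) {
      abort("`x` must have a `sequence` column.")
    }
    count <- if ("count" %in% names(x)) x$count else NULL
    x <- x$sequence
  }
  x <- stringi::stri_trans_toupper(as.character(x))
  if (is.null(count)) count <- 1L
  count <- vctrs_recycle(as.numeric(count), length(x))
  if (any(count < 1, na.rm = TRUE)) {
    abort("multiplicities must be >= 1.")
  }
  valid <- !is.na(x) & nchar(x) > 0 &
    !stringi::stri_detect_regex(x, "[^ACGT]")
  n_dropped <- sum(!valid)
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d sequence(s) with symbols outside A/C/G/T.",
                   n_dropped))
  }
  if (!any(valid)) {
    abort("No valid A/C/G/T sequences remain.", class = "dminer_empty_dataset")
  }
  out <- tibble(sequence = x[valid], count = count[valid])
  out <- out |>
    group_by(.data$sequence) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(desc(.data$count), .data$sequence)
  attr(out, "label") <- label
  attr(out, "n_dropped") <- n_dropped
  out
}

# minimal recycling helper (avoid pulling in vctrs)
vctrs_recycle <- function(x, n) {
  if (length(x) == n) return(x)
  if (length(x) == 1L) return(rep(x, n))
  abort("`count` must have length 1 or length(x).")
}

#' Read a CDR3 dataset from disk
#'
#' Supported formats: FASTA (`fasta`), plain text with one sequence per line
#' (`lines`), and TSV with a header containing a `sequence` column and an
#' optional `count` column (`tsv`). FASTA descriptions may carry an abundance
#' as `count=<n>`; otherwise every record counts 1.
#'
#' @param path Path to the input file.
#' @param format One of `"auto"`, `"fasta"`, `"lines"`, `"tsv"`. `"auto"`
#'   guesses from the file extension.
#' @param min_size Warn when the number of distinct sequences falls below this
#'   floor (default 15000, the size below which repertoires are considered too
#'   small for reliable gene inference).
#' @param label Dataset label; defaults to the file name.
#' @return A CDR3 set (see [cdr3_set()]); the `"below_min_size"` attribute
#'   records whether the warning fired.
#' @export
read_cdr3_dataset <- function(path, format = c("auto", "fasta", "lines", "tsv"),
                              min_size = 15000, label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "dminer_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "fna")) "fasta"
      else if (ext %in% c("tsv", "txt2", "tab")) "tsv"
      else "lines"
  }
  label <- label %||% basename(path)
  if (format == "fasta") {
    recs <- Biostrings::readBStringSet(path)
    seqs <- as.character(recs)
    cnt <- stringi::stri_match_first_regex(names(recs), "count=(\\d+)")[, 2]
    cnt <- suppressWarnings(as.numeric(cnt))
    cnt[is.na(cnt)] <- 1
    out <- cdr3_set(seqs, count = cnt, label = label)
  } else if (format == "lines") {
    seqs <- readLines(path, warn = FALSE)
    seqs <- seqs[nzchar(trimws(seqs))]
    out <- cdr3_set(trimws(seqs), label = label)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (!"sequence" %in% names(tab)) {
      abort("TSV input must have a `sequence` column.",
            class = "dminer_io_error")
    }
    cnt <- if ("count" %in% names(tab)) tab$count else NULL
    out <- cdr3_set(tab$sequence, count = cnt, label = label)
  }
  below <- nrow(out) < min_size
  if (below) {
    warn(sprintf("Dataset '%s' has %d distinct CDR3s (< %d).",
                 label, nrow(out), min_size),
         class = "dminer_small_dataset")
  }
  attr(out, "below_min_size") <- below
  out
}

#' Write a CDR3 set to FASTA
#'
#' Multiplicities are preserved in the description line as `count=<n>` so that
#' a read/write round trip is lossless.
#'
#' @param cdr3s A CDR3 set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cdr3_fasta <- function(cdr3s, path) {
  seqs <- Biostrings::DNAStringSet(cdr3s$sequence)
  names(seqs) <- sprintf("cdr3_%d count=%d",
                         seq_len(nrow(cdr3s)), as.integer(cdr3s$count))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Count k-mers in a CDR3 set
#'
#' Every k-length substring of every CDR3 contributes that CDR3's multiplicity;
#' a k-mer occurring twice in one CDR3 contributes twice. Total mass therefore
#' equals `sum(count * pmax(0, nchar(sequence) - k + 1))`.
#'
#' @param cdr3s A CDR3 set.
#' @param k k-mer length (default 10).
#' @return A tibble with columns `kmer` and `count`, sorted by decreasing
#'   count then k-mer; the `"k"` attribute records `k`.
#' @examples
#' count_kmers(cdr3_set("AAAA"), k = 2)
#' @export
count_kmers <- function(cdr3s, k = 10) {
  stopifnot(k >= 1)
  k <- as.integer(k)
  lens <- nchar(cdr3s$sequence)
  keep <- lens >= k
  empty <- tibble(kmer = character(), count = numeric())
  if (!any(keep)) {
    attr(empty, "k") <- k
    return(empty)
  }
  seqs <- cdr3s$sequence[keep]
  mult <- cdr3s$count[keep]
  n_win <- lens[keep] - k + 1L
  idx <- rep.int(seq_along(seqs), n_win)
  start <- sequence(n_win)
  km <- stringi::stri_sub(seqs[idx], start, start + k - 1L)
  wt <- mult[idx]
  # radix sort + run-length aggregation; much faster than a grouped
  # summarise on millions of k-mer rows
  o <- order(km, method = "radix")
  runs <- rle(km[o])
  ends <- cumsum(runs$lengths)
  csum <- cumsum(wt[o])
  out <- tibble(kmer = runs$values,
                count = diff(c(0, csum[ends]))) |>
    arrange(desc(.data$count), .data$kmer)
  attr(out, "k") <- k
  out
}

#' Collapse near-duplicate CDR3s into consensus sequences
#'
#' Sample-preparation errors produce clouds of CDR3s differing by a few
#' mismatches. Sequences are processed in decreasing multiplicity (ties broken
#' lexicographically); each sequence joins the first group whose founding
#' sequence has equal length and Hamming distance at most `max_mismatches`,
#' otherwise it founds a new group. The consensus of a group is the
#' multiplicity-weighted per-position majority (position ties resolved in
#' favour of the founding sequence's nucleotide, then alphabetically) and its
#' multiplicity is the group total.
#'
#' @param cdr3s A CDR3 set.
#' @param max_mismatches Maximum Hamming distance to a group's founder
#'   (default 3). `0` returns the input unchanged.
#' @return A CDR3 set of consensus sequences. Total multiplicity is conserved
#'   and the number of distinct sequences never increases.
#' @export
build_consensus_cdr3s <- function(cdr3s, max_mismatches = 3) {
  stopifnot(max_mismatches >= 0)
  if (max_mismatches == 0 || nrow(cdr3s) < 2) {
    return(cdr3_set(cdr3s$sequence, cdr3s$count,
                    label = attr(cdr3s, "label")))
  }
  ord <- order(-cdr3s$count, cdr3s$sequence)
  seqs <- cdr3s$sequence[ord]
  mult <- cdr3s$count[ord]
  lens <- nchar(seqs)

  out_seq <- character()
  out_cnt <- numeric()
  for (L in unique(lens)) {
    sel <- which(lens == L)
    s <- seqs[sel]
    w <- mult[sel]
    mat <- matrix(stringi::stri_sub(rep(s, each = L),
                                    rep(seq_len(L), length(s)),
                                    length = 1L),
                  nrow = length(s), ncol = L, byrow = TRUE)
    assigned <- rep(FALSE, length(s))
    while (!all(assigned)) {
      founder <- which(!assigned)[1L]
      fvec <- mat[founder, ]
      cand <- which(!assigned)
      hd <- rowSums(mat[cand, , drop = FALSE] !=
                      matrix(fvec, nrow = length(cand), ncol = L,
                             byrow = TRUE))
      members <- cand[hd <= max_mismatches]
      assigned[members] <- TRUE
      out_seq <- c(out_seq, consensus_of(mat[members, , drop = FALSE],
                                         w[members], fvec))
      out_cnt <- c(out_cnt, sum(w[members]))
    }
  }
  cdr3_set(out_seq, out_cnt, label = attr(cdr3s, "label"))
}

# weighted per-position majority; ties prefer the founder's symbol, then A<C<G<T
consensus_of <- function(mat, w, founder) {
  L <- ncol(mat)
  cons <- character(L)
  for (j in seq_len(L)) {
    tallies <- setNames(numeric(4), DNA_BASES)
    obs <- rowsum(w, mat[, j])
    tallies[rownames(obs)] <- obs[, 1]
    top <- names(tallies)[tallies == max(tallies)]
    cons[j] <- if (founder[j] %in% top) founder[j] else top[1L]
  }
  paste(cons, collapse = "")
}

#' Read a germline gene database from FASTA
#'
#' Headers are parsed in the IMGT dialect `<gene>*<allele>`: everything after
#' the first `*` is the allele name; headers without a `*` get allele `"01"`.
#' Duplicate sequences are allowed under different names, but (gene, allele)
#' pairs must be unique.
#'
#' @param path Path to a FASTA file.
#' @param species Optional free-text species tag, stored as an attribute.
#' @return A tibble with columns `gene`, `allele`, `name` (`gene*allele`), and
#'   `sequence`.
#' @export
read_germline_db <- function(path, species = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "dminer_io_error")
  }
  recs <- Biostrings::readBStringSet(path)
  ids <- stringi::stri_extract_first_regex(names(recs), "^\\S+")
  germline_db(ids, as.character(recs), species = species)
}

#' Build a germline database tibble
#'
#' @param name Entry names, `<gene>` or `<gene>*<allele>`.
#' @param sequence Nucleotide sequences.
#' @param species Optional species tag.
#' @return See [read_germline_db()].
#' @export
germline_db <- function(name, sequence, species = NULL) {
  sequence <- stringi::stri_trans_toupper(as.character(sequence))
  if (any(!nzchar(sequence))) abort("Germline sequences must be non-empty.")
  star <- stringi::stri_locate_first_fixed(name, "*")[, 1]
  gene <- ifelse(is.na(star), name, stringi::stri_sub(name, 1, star - 1L))
  allele <- ifelse(is.na(star), "01", stringi::stri_sub(name, star + 1L))
  out <- tibble(gene = gene, allele = allele,
                name = paste(gene, allele, sep = "*"),
                sequence = sequence)
  if (anyDuplicated(out$name)) {
    abort("Duplicated (gene, allele) pairs in the germline database.")
  }
  attr(out, "species") <- species
  out
}

#' Write a germline database to FASTA
#'
#' @param db A germline database tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(db, path) {
  seqs <- Biostrings::DNAStringSet(db$sequence)
  names(seqs) <- db$name
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
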