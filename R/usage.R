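#' Unique substrings of germline genes
#'
#' A substring (of length at least `k_min`) is unique to a gene when it
#' occurs in at least one sequence of that gene (any allele) and in no
#' sequence of any other gene. These unique substrings are the basis of
#' CDR3-to-gene assignment.
#'
#' @param db A germline database tibble.
#' @param k_min Minimum substring length (default 8).
#' @param by `"gene"` (unique across genes, the default) or `"name"`
#'   (unique across alleles, used for allele-level assignment).
#' @return A tibble with columns `kmer`, `length`, `unit` (the owning gene or
#'   allele name).
#' @export
find_unique_kmers <- function(db, k_min = 8, by = c("gene", "name")) {
  by <- match.arg(by)
  stopifnot(k_min >= 1)
  unit <- db[[by]]
  pieces <- purrr::map2(db$sequence, unit, function(s, u) {
    L <- nchar(s)
    if (L < k_min) return(NULL)
    lens <- k_min:L
    n_win <- L - lens + 1L
    start <- sequence(n_win)
    len <- rep.int(lens, n_win)
    tibble(kmer = stringi::stri_sub(s, start, length = len), unit = u)
  })
  tab <- bind_rows(pieces) |> distinct()
  if (nrow(tab) == 0) {
    return(tibble(kmer = character(), length = integer(), unit = character()))
  }
  tab |>
    group_by(.data$kmer) |>
    filter(dplyr::n_distinct(.data$unit) == 1) |>
    ungroup() |>
    distinct(.data$kmer, .data$unit) |>
    mutate(length = nchar(.data$kmer)) |>
    select("kmer", "length", "unit") |>
    arrange(desc(.data$length), .data$kmer)
}

#' Assign CDR3s to germline genes via unique substrings
#'
#' A CDR3 is formed by gene `g` when it contains a unique substring of `g`
#' and no equally long or longer unique substring of any other gene.
#' Operationally: let `L(g)` be the length of the longest unique substring of
#' `g` occurring in the CDR3 (0 if none); the CDR3 is assigned to the unique
#' argmax gene when that maximum is positive and unique, and is non-traceable
#' otherwise (tie or no match).
#'
#' @param sequences Character vector of CDR3 sequences.
#' @param index A unique-substring index from [find_unique_kmers()].
#' @return A tibble with columns `sequence`, `unit` (`NA` = non-traceable)
#'   and `match_length`.
#' @export
assign_cdr3s <- function(sequences, index) {
  n <- length(sequences)
  unit <- rep(NA_character_, n)
  match_len <- integer(n)
  if (n == 0 || nrow(index) == 0) {
    return(tibble(sequence = sequences, unit = unit,
                  match_length = match_len))
  }
  subj <- Biostrings::DNAStringSet(sequences)
  undecided <- rep(TRUE, n)
  for (t in sort(unique(index$length), decreasing = TRUE)) {
    und <- which(undecided)
    if (length(und) == 0) break
    pat <- index[index$length == t, ]
    pd <- Biostrings::PDict(pat$kmer)
    hits <- Biostrings::vwhichPDict(pd, subj[und])
    nh <- lengths(hits)
    for (i in which(nh > 0)) {
      us <- unique(pat$unit[hits[[i]]])
      j <- und[i]
      undecided[j] <- FALSE
      match_len[j] <- t
      if (length(us) == 1L) unit[j] <- us # ties stay non-traceable
    }
  }
  tibble(sequence = sequences, unit = unit, match_length = match_len)
}

#' Compute D-gene (and allele) usage of a CDR3 set
#'
#' Usage is defined over distinct CDR3s (multiplicities are ignored): a CDR3
#' is traceable when [assign_cdr3s()] assigns it to a single gene, and the
#' usage of a gene is the proportion of traceable CDR3s formed by it. Allele
#' shares apply the same rule at allele resolution within each assigned
#' gene's CDR3s, using substrings unique among that gene's own alleles.
#'
#' @param cdr3s A CDR3 set (or character vector of sequences).
#' @param db A germline database tibble.
#' @param k_min Minimum unique-substring length (default 8).
#' @return An object of class `usage_profile`: a list with elements
#'   `gene_usage` (tibble `gene`, `n_cdr3s`, `usage`), `allele_shares`
#'   (tibble `gene`, `allele`, `name`, `n_cdr3s`, `share`),
#'   `traceable_fraction`, `n_cdr3s`, `k_min`, and `assignments`.
#' @export
compute_usage <- function(cdr3s, db, k_min = 8) {
  seqs <- if (is.data.frame(cdr3s)) cdr3s$sequence else unique(cdr3s)
  gene_idx <- find_unique_kmers(db, k_min = k_min, by = "gene")
  asg <- assign_cdr3s(seqs, gene_idx)
  traceable <- !is.na(asg$unit)
  n_tr <- sum(traceable)
  if (n_tr == 0) {
    warn("No traceable CDR3s.")
    return(structure(list(
      gene_usage = tibble(gene = character(), n_cdr3s = integer(),
                          usage = numeric()),
      allele_shares = tibble(gene = character(), allele = character(),
                             name = character(), n_cdr3s = integer(),
                             share = numeric()),
      traceable_fraction = 0, n_cdr3s = length(seqs), k_min = k_min,
      assignments = asg), class = "usage_profile"))
  }
  gene_usage <- tibble(gene = asg$unit[traceable]) |>
    count(.data$gene, name = "n_cdr3s") |>
    mutate(usage = .data$n_cdr3s / n_tr) |>
    arrange(desc(.data$usage), .data$gene)

  allele_shares <- purrr::map(gene_usage$gene, function(g) {
    sub_db <- db[db$gene == g, ]
    g_seqs <- asg$sequence[traceable & asg$unit == g]
    if (nrow(sub_db) == 1L) {
      return(tibble(gene = g, allele = sub_db$allele, name = sub_db$name,
                    n_cdr3s = length(g_seqs), share = 1))
    }
    allele_idx <- find_unique_kmers(sub_db, k_min = k_min, by = "name")
    a_asg <- assign_cdr3s(g_seqs, allele_idx)
    ok <- !is.na(a_asg$unit)
    if (!any(ok)) return(NULL)
    tibble(name = a_asg$unit[ok]) |>
      count(.data$name, name = "n_cdr3s") |>
      left_join(select(sub_db, "gene", "allele", "name"), by = "name") |>
      mutate(share = .data$n_cdr3s / sum(.data$n_cdr3s)) |>
      select("gene", "allele", "name", "n_cdr3s", "share")
  }) |> bind_rows()

  structure(list(
    gene_usage = gene_usage,
    allele_shares = allele_shares,
    traceable_fraction = n_tr / length(seqs),
    n_cdr3s = length(seqs),
    k_min = k_min,
    assignments = asg
  ), class = "usage_profile")
}

#' @export
print.usage_profile <- function(x, ...) {
  cat(sprintf("<usage_profile> %d CDR3s, %.1f%% traceable, %d genes used\n",
              x$n_cdr3s, 100 * x$traceable_fraction, nrow(x$gene_usage)))
  print(x$gene_usage, n = 10)
  invisible(x)
}

#' @export
tidy.usage_profile <- function(x, ...) x$gene_usage

#' @export
glance.usage_profile <- function(x, ...) {
  tibble(n_cdr3s = x$n_cdr3s,
         n_traceable = round(x$traceable_fraction * x$n_cdr3s),
         traceable_fraction = x$traceable_fraction,
         n_genes = nrow(x$gene_usage),
         k_min = x$k_min)
}

#' Add decoy (false) alleles to a germline database
#'
#' Generates artificial allelic variants of a gene by substituting, at each
#' given site, every combination of the listed alternative nucleotides (the
#' original nucleotide included). Sequences already present in the database
#' are excluded; the rest are appended as alleles `FA1, FA2, ...` of the
#' gene. Decoys reveal hypermutation-driven allele misassignment: reads that
#' land on decoys were never reliable evidence for real alleles.
#'
#' @param db A germline database tibble.
#' @param gene Gene whose first allele (lexicographically) serves as the
#'   base sequence.
#' @param sites Integer positions within the base sequence.
#' @param alternatives A list (one element per site) of character vectors of
#'   alternative nucleotides, or a single character vector recycled to all
#'   sites.
#' @param cap Maximum number of decoys appended (default 100).
#' @return The database with decoy entries appended.
#' @export
add_decoy_alleles <- function(db, gene, sites, alternatives, cap = 100) {
  stopifnot(cap >= 1)
  if (length(sites) == 0) return(db)
  base_rows <- db[db$gene == gene, ]
  if (nrow(base_rows) == 0) abort(sprintf("Gene '%s' not in database.", gene))
  base <- base_rows$sequence[order(base_rows$allele)][1L]
  if (any(sites < 1 | sites > nchar(base))) {
    abort("Decoy site out of range.", class = "dminer_contract_error")
  }
  if (!is.list(alternatives)) {
    alternatives <- rep(list(alternatives), length(sites))
  }
  stopifnot(length(alternatives) == length(sites))
  opts <- purrr::map2(sites, alternatives, function(p, alt) {
    unique(c(stringi::stri_sub(base, p, length = 1L),
             stringi::stri_trans_toupper(alt)))
  })
  combos <- do.call(expand.grid,
                    c(rev(opts), list(stringsAsFactors = FALSE)))
  combos <- as.matrix(combos)[, rev(seq_along(sites)), drop = FALSE]
  decoys <- apply(combos, 1L, function(repl) {
    s <- base
    for (i in seq_along(sites)) {
      stringi::stri_sub(s, sites[i], length = 1L) <- repl[i]
    }
    s
  })
  decoys <- setdiff(unique(decoys), db$sequence)
  decoys <- head(decoys, cap)
  if (length(decoys) == 0) return(db)
  bind_rows(db, germline_db(paste0(gene, "*FA", seq_along(decoys)), decoys))
}

#' Detect overused genes relative to reference repertoires
#'
#' A gene is overused in the target repertoire when its usage is at least
#' `factor` times the maximum usage of that gene across all reference
#' profiles (default factor 2). Genes absent from every reference are
#' reported separately as `absent_in_reference`. Ratios are scale-free.
#'
#' @param target A `usage_profile` or a tibble with `gene` and `usage`.
#' @param references A list of the same (at least one).
#' @param factor Over-usage threshold (default 2).
#' @return A tibble `gene`, `usage`, `reference_max`, `over_usage`, `status`
#'   (`"overused"`, `"normal"`, or `"absent_in_reference"`).
#' @export
detect_overuse <- function(target, references, factor = 2) {
  stopifnot(factor > 0)
  as_usage_tbl <- function(x) {
    if (inherits(x, "usage_profile")) x$gene_usage else as_tibble(x)
  }
  tgt <- as_usage_tbl(target)
  if (!is.list(references) || is.data.frame(references)) {
    references <- list(references)
  }
  stopifnot(length(references) >= 1)
  ref <- bind_rows(lapply(references, as_usage_tbl)) |>
    group_by(.data$gene) |>
    summarise(reference_max = max(.data$usage), .groups = "drop")
  tgt |>
    select("gene", "usage") |>
    left_join(ref, by = "gene") |>
    mutate(
      reference_max = dplyr::coalesce(.data$reference_max, 0),
      over_usage = ifelse(.data$reference_max > 0,
                          .data$usage / .data$reference_max, NA_real_),
      status = dplyr::case_when(
        .data$reference_max == 0 ~ "absent_in_reference",
        .data$over_usage >= factor ~ "overused",
        TRUE ~ "normal"
      )
    ) |>
    arrange(desc(.data$over_usage))
}

#' Haplotype heterozygous V genes through D-gene linkage
#'
#' V and D segments recombined onto the same chromosome stay physically
#' linked, so the joint usage of V alleles and heterozygous D-gene alleles
#' phases the locus. For each V gene retained as heterozygous (at least two
#' alleles each with at least `min_cdr3s` distinct CDR3s) and each
#' heterozygous D gene, the matrix of distinct-CDR3 counts is built and each
#' row (fixed V allele, fixed D gene) normalised over that D gene's alleles;
#' every V allele pairs with the D allele of maximum share. Haplotypes are
#' formed by transitivity through a reference D gene, and a V gene is flagged
#' inconsistent when its alleles pick the same D allele or when pairings
#' conflict across D genes.
#'
#' @param annotated A tibble with columns `cdr3` (or `junction`/`sequence`)
#'   and `v_call` (IMGT-style `gene*allele`; taken as given, V alleles are
#'   not called here).
#' @param db Germline D-gene database (allele resolution).
#' @param min_cdr3s Minimum distinct CDR3s per V allele (default 1000).
#' @param k_min Minimum unique-substring length for D assignment (default 8).
#' @return An object of class `haplotype_report`: list with `pairings`
#'   (tibble `v_gene`, `v_allele`, `d_gene`, `d_allele`, `share`, `n_cdr3s`,
#'   `haplotype`), `joint` (the normalised support matrix in long form),
#'   `v_genes` (tibble with a `consistent` flag), and `anchor_gene`.
#' @export
haplotype_v_genes <- function(annotated, db, min_cdr3s = 1000, k_min = 8) {
  tab <- as_tibble(annotated)
  seq_col <- intersect(c("cdr3", "junction", "sequence"), names(tab))[1]
  if (is.na(seq_col) || !"v_call" %in% names(tab)) {
    abort("`annotated` needs a CDR3 column (cdr3/junction/sequence) and `v_call`.")
  }
  tab <- tab |>
    select(cdr3 = dplyr::all_of(seq_col), "v_call") |>
    distinct() |>
    mutate(cdr3 = stringi::stri_trans_toupper(.data$cdr3))
  star <- stringi::stri_locate_first_fixed(tab$v_call, "*")[, 1]
  tab$v_gene <- ifelse(is.na(star), tab$v_call,
                       stringi::stri_sub(tab$v_call, 1, star - 1L))
  tab$v_allele <- ifelse(is.na(star), "01",
                         stringi::stri_sub(tab$v_call, star + 1L))

  # retain abundant alleles, then genes with >= 2 retained alleles
  allele_n <- tab |> count(.data$v_gene, .data$v_allele, name = "n")
  kept <- allele_n |> filter(.data$n >= min_cdr3s)
  het_v <- kept |> count(.data$v_gene) |> filter(.data$n >= 2) |> pull(.data$v_gene)
  if (length(het_v) == 0) {
    abort("No heterozygous V gene passes the CDR3-count filter.",
          class = "dminer_contract_error")
  }
  tab <- tab |>
    dplyr::semi_join(kept, by = c("v_gene", "v_allele")) |>
    filter(.data$v_gene %in% het_v)

  # D-gene then D-allele assignment of every distinct CDR3
  gene_asg <- assign_cdr3s(tab$cdr3, find_unique_kmers(db, k_min, by = "gene"))
  tab$d_gene <- gene_asg$unit
  tab$d_allele <- NA_character_
  for (g in unique(stats::na.omit(tab$d_gene))) {
    sub_db <- db[db$gene == g, ]
    if (nrow(sub_db) < 2) next
    rows <- which(!is.na(tab$d_gene) & tab$d_gene == g)
    a <- assign_cdr3s(tab$cdr3[rows],
                      find_unique_kmers(sub_db, k_min, by = "name"))
    tab$d_allele[rows] <- a$unit
  }
  obs <- tab |> filter(!is.na(.data$d_allele))
  het_d <- obs |>
    distinct(.data$d_gene, .data$d_allele) |>
    count(.data$d_gene) |>
    filter(.data$n >= 2) |>
    pull(.data$d_gene)
  if (length(het_d) == 0) {
    warn("No heterozygous D gene observed; empty haplotype report.")
    return(structure(list(pairings = tibble(), joint = tibble(),
                          v_genes = tibble(), anchor_gene = NA_character_),
                     class = "haplotype_report"))
  }
  obs <- obs |> filter(.data$d_gene %in% het_d)

  joint <- obs |>
    count(.data$v_gene, .data$v_allele, .data$d_gene, .data$d_allele,
          name = "n_cdr3s") |>
    group_by(.data$v_gene, .data$v_allele, .data$d_gene) |>
    mutate(share = .data$n_cdr3s / sum(.data$n_cdr3s)) |>
    ungroup()

  pairings <- joint |>
    group_by(.data$v_gene, .data$v_allele, .data$d_gene) |>
    arrange(desc(.data$share), .data$d_allele, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup()

  anchor <- sort(het_d)[1L]
  hap_of <- pairings |>
    filter(.data$d_gene == anchor) |>
    select("v_gene", "v_allele", anchor_allele = "d_allele")
  anchor_alleles <- sort(unique(hap_of$anchor_allele))
  hap_of$haplotype <- match(hap_of$anchor_allele, anchor_alleles)
  pairings <- left_join(pairings,
                        select(hap_of, "v_gene", "v_allele", "haplotype"),
                        by = c("v_gene", "v_allele"))

  v_genes <- pairings |>
    group_by(.data$v_gene) |>
    summarise(
      n_alleles = dplyr::n_distinct(.data$v_allele),
      consistent = all(vapply(split(.data$d_allele, .data$d_gene),
                              anyDuplicated, integer(1)) == 0L) &&
        dplyr::n_distinct(.data$haplotype, na.rm = TRUE) ==
          dplyr::n_distinct(.data$v_allele),
      .groups = "drop"
    )

  structure(list(pairings = pairings, joint = joint, v_genes = v_genes,
                 anchor_gene = anchor),
            class = "haplotype_report")
}

#' @export
print.haplotype_report <- function(x, ...) {
  if (nrow(x$v_genes) == 0) {
    cat("<haplotype_report> empty (no heterozygous D gene)\n")
    return(invisible(x))
  }
  cat(sprintf("<haplotype_report> %d V genes phased via anchor %s (%d consistent)\n",
              nrow(x$v_genes), x$anchor_gene, sum(x$v_genes$consistent)))
  print(x$v_genes)
  invisible(x)
}

#' @export
tidy.haplotype_report <- function(x, ...) x$pairings

#' @export
glance.haplotype_report <- function(x, ...) {
  tibble(n_v_genes = nrow(x$v_genes),
         n_consistent = sum(x$v_genes$consistent),
         anchor_gene = x$anchor_gene)
}
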