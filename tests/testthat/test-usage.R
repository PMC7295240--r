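test_that("unique substrings are unique across genes", {
  db <- germline_db(c("d1*01", "d2*01"),
                    c("ACGTACGTAC", "TTTTGGGGCCAA"))
  idx <- find_unique_kmers(db, k_min = 8)
  expect_true(all(c("ACGTACGT", "TTTTGGGG") %in% idx$kmer))
  expect_equal(unique(idx$unit[idx$kmer == "ACGTACGT"]), "d1")
  expect_equal(unique(idx$unit[idx$kmer == "TTTTGGGG"]), "d2")
  # a substring shared by two genes is unique to neither
  db2 <- germline_db(c("d1*01", "d2*01"),
                     c("AAACGTACGTAC", "CCACGTACGTGG"))
  idx2 <- find_unique_kmers(db2, k_min = 8)
  expect_false("ACGTACGT" %in% idx2$kmer)
  # single-gene database: every long-enough substring is unique to it
  db3 <- germline_db("d1*01", "ACGTACGTAC")
  idx3 <- find_unique_kmers(db3, k_min = 8)
  expect_equal(sort(unique(idx3$unit)), "d1")
  expect_equal(nrow(idx3), 3 + 2 + 1) # lengths 8, 9, 10
})

test_that("CDR3 assignment follows the longest-unique-match rule", {
  d1 <- "ACGTACGTACGT"
  d2 <- "TTGGCCAATTGGC"
  db <- germline_db(c("d1*01", "d2*01"), c(d1, d2))
  idx <- find_unique_kmers(db, k_min = 8)
  # whole gene embedded -> assigned
  a <- assign_cdr3s(paste0("GGG", d1, "AAA"), idx)
  expect_equal(a$unit, "d1")
  # longer unique match of the other gene wins ("T" separator does not
  # extend d1's 8-mer prefix match)
  c2 <- paste0(substr(d1, 1, 8), "T", substr(d2, 1, 9))
  a2 <- assign_cdr3s(c2, idx)
  expect_equal(a2$unit, "d2")
  expect_equal(a2$match_length, 9)
  # equal-length matches of two genes tie -> non-traceable
  c3 <- paste0(substr(d1, 1, 9), "A", substr(d2, 1, 9))
  expect_true(is.na(assign_cdr3s(c3, idx)$unit))
  # no match -> non-traceable
  expect_true(is.na(assign_cdr3s("AAAAAAAA", idx)$unit))
  # permutation invariance of the index
  set.seed(8)
  idx_perm <- idx[sample(nrow(idx)), ]
  expect_equal(assign_cdr3s(c(paste0("GGG", d1), c2, c3), idx)$unit,
               assign_cdr3s(c(paste0("GGG", d1), c2, c3), idx_perm)$unit)
})

test_that("usage arithmetic over traceable CDR3s is exact", {
  d1 <- "ACGTACGTACGT"
  d2 <- "TTGGCCAATTGGC"
  db <- germline_db(c("d1*01", "d2*01"), c(d1, d2))
  cdr3s <- c(paste0(c("GGG", "CCC", "TTT", "AAA", "GAG", "CTC"), d1),
             paste0(c("GGG", "CCC"), d2),
             "AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC")
  u <- compute_usage(cdr3s, db)
  expect_equal(u$traceable_fraction, 0.8)
  expect_equal(u$gene_usage$usage[u$gene_usage$gene == "d1"], 0.75)
  expect_equal(u$gene_usage$usage[u$gene_usage$gene == "d2"], 0.25)
  expect_equal(sum(u$gene_usage$usage), 1)
  # single-allele genes have share 1
  expect_true(all(u$allele_shares$share == 1))
  # glance reports the headline numbers
  g <- glance(u)
  expect_equal(g$n_traceable, 8)
  # no traceable CDR3s -> empty profile with warning
  expect_warning(u0 <- compute_usage("AAAAAAAAAA", db))
  expect_equal(u0$traceable_fraction, 0)
})

test_that("planted gene frequencies are recovered within 0.03", {
  genes <- random_d_genes(4, c(16, 30), rng_seed = 21)
  truth <- c(gene1 = 0.4, gene2 = 0.3, gene3 = 0.2, gene4 = 0.1)
  mod <- generative_model(genes, gene_weights = unname(truth))
  sim <- simulate_cdr3s(mod, 50000, rng_seed = 9)
  u <- compute_usage(unique(sim$sequence), germline_db(names(genes),
                                                       unname(genes)))
  est <- setNames(u$gene_usage$usage, u$gene_usage$gene)[names(truth)]
  expect_lt(max(abs(est - truth)), 0.03)
  expect_equal(sum(u$gene_usage$usage), 1, tolerance = 1e-9)
  # allele shares sum to one within every used gene
  shares <- u$allele_shares |>
    dplyr::group_by(gene) |>
    dplyr::summarise(s = sum(share))
  expect_true(all(abs(shares$s - 1) < 1e-9))
})

test_that("decoy alleles enumerate site combinations", {
  base <- "ACGTACGTACGTACGTACGT"
  db <- germline_db("D1*01", base)
  out <- add_decoy_alleles(db, "D1", sites = c(3, 10),
                           alternatives = list(c("A", "C", "G", "T"),
                                               c("A", "C", "G", "T")))
  expect_equal(nrow(out) - 1, 15) # 4 * 4 - original
  expect_true(all(grepl("^FA", out$allele[-1])))
  expect_identical(add_decoy_alleles(db, "D1", integer(0), list()), db)
  expect_error(add_decoy_alleles(db, "D1", 99, list("A")),
               class = "dminer_contract_error")
})

test_that("hypermutation inflates the decoy-allele share", {
  base <- random_d_genes(1, c(28, 28), rng_seed = 3)[[1]]
  al2 <- base
  stringi::stri_sub(al2, 14, 14) <-
    setdiff(c("A", "C", "G", "T"), stringi::stri_sub(base, 14, 14))[1]
  db <- germline_db(c("D1*01", "D1*02"), c(base, al2))
  db <- add_decoy_alleles(db, "D1", sites = c(5, 10, 20, 24),
                          alternatives = rep(list(c("A", "C", "G", "T")), 4),
                          cap = 60)
  mod <- generative_model(setNames(c(base, al2), c("a1", "a2")))
  sim <- simulate_cdr3s(mod, 20000, rng_seed = 13)
  fa_share <- function(seqs) {
    u <- compute_usage(unique(seqs), db)
    sum(u$allele_shares$share[grepl("^FA", u$allele_shares$allele)])
  }
  clean <- fa_share(sim$sequence)
  mutated <- fa_share(mutate_sequences(sim$sequence, 0.02, rng_seed = 14))
  expect_gt(mutated, clean)
})

test_that("over-usage ratios and statuses follow the definition", {
  tgt <- tibble::tibble(gene = c("d1", "d2", "d3"),
                        usage = c(0.10, 0.07, 0.05))
  refs <- list(tibble::tibble(gene = c("d1", "d2"), usage = c(0.04, 0.03)),
               tibble::tibble(gene = c("d1", "d2"), usage = c(0.02, 0.04)))
  out <- detect_overuse(tgt, refs)
  expect_equal(out$over_usage[out$gene == "d1"], 2.5)
  expect_equal(out$status[out$gene == "d1"], "overused")
  expect_equal(out$over_usage[out$gene == "d2"], 1.75)
  expect_equal(out$status[out$gene == "d2"], "normal")
  expect_equal(out$status[out$gene == "d3"], "absent_in_reference")
  # factor 1 reports every gene with nonzero reference
  out1 <- detect_overuse(tgt, refs, factor = 1)
  expect_true(all(out1$status[out1$gene != "d3"] == "overused"))
  # scale invariance
  scale10 <- detect_overuse(
    dplyr::mutate(tgt, usage = usage * 10),
    lapply(refs, function(r) dplyr::mutate(r, usage = usage * 10)))
  expect_equal(scale10$over_usage, out$over_usage)
})

test_that("V-gene haplotypes are phased through heterozygous D genes", {
  # two D alleles distinguishable by unique substrings
  d1a <- "ACGTACGTACGTACGTACGT"
  d1b <- "ACGTACGTTCGTACGTACGT"
  db <- germline_db(c("D1*01", "D1*02"), c(d1a, d1b))
  mk <- function(core, n, tag) {
    paste0(tag, vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
    }, character(1)), core)
  }
  set.seed(12)
  tab <- tibble::tibble(
    cdr3 = c(mk(d1a, 60, "GG"), mk(d1b, 5, "GG"),
             mk(d1b, 55, "CC"), mk(d1a, 4, "CC")),
    v_call = rep(c("IGHV1-2*02", "IGHV1-2*04"), c(65, 59)))
  rep_report <- haplotype_v_genes(tab, db, min_cdr3s = 20)
  p <- tidy(rep_report)
  expect_equal(p$d_allele[p$v_allele == "02"], "D1*01")
  expect_equal(p$d_allele[p$v_allele == "04"], "D1*02")
  expect_true(all(rep_report$v_genes$consistent))
  # rows of the support matrix sum to one per (V allele, D gene)
  sums <- rep_report$joint |>
    dplyr::group_by(v_gene, v_allele, d_gene) |>
    dplyr::summarise(s = sum(share), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  # single-allele V genes are excluded by the heterozygosity filter
  tab2 <- dplyr::mutate(tab, v_call = "IGHV1-2*02")
  expect_error(haplotype_v_genes(tab2, db, min_cdr3s = 20),
               class = "dminer_contract_error")
})

test_that("planted haplotypes are recovered from linked simulations", {
  # two haplotypes: (V*01, D1*01, D2*01) and (V*03, D1*02, D2*02)
  set.seed(9)
  d <- list(D1 = c("ACGTACGTACGTACGTACGT", "ACGTACGTTCGTACGTACGT"),
            D2 = c("TTGGCCAATTGGCCAATTGG", "TTGGCCAAATGGCCAATTGG"))
  db <- germline_db(c("D1*01", "D1*02", "D2*01", "D2*02"),
                    c(d$D1, d$D2))
  hap <- function(v, d1, d2, n) {
    core <- sample(c(d1, d2), n, replace = TRUE)
    tibble::tibble(
      cdr3 = paste0("GCGA",
                    vapply(seq_len(n), function(i) {
                      paste(sample(c("A", "C", "G", "T"), 5, TRUE),
                            collapse = "")
                    }, character(1)), core),
      v_call = v)
  }
  tab <- dplyr::bind_rows(hap("IGHV3-23*01", d$D1[1], d$D2[1], 400),
                          hap("IGHV3-23*03", d$D1[2], d$D2[2], 400))
  rp <- haplotype_v_genes(tab, db, min_cdr3s = 100)
  p <- tidy(rp)
  expect_equal(sort(unique(p$haplotype[p$v_allele == "01"])), 1)
  expect_equal(sort(unique(p$haplotype[p$v_allele == "03"])), 2)
  expect_true(all(rp$v_genes$consistent))
})
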