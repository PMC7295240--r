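test_that("relative position normalises by window count", {
  expect_equal(relative_position("ACGT", "ACGT"), 0)
  c20 <- paste0("ACGTACGTAC", "GGGGGGGGGG")
  expect_equal(relative_position("ACGTACGTAC", c20), 0)
  c2 <- paste0("GGGGGGGGGG", "ACGTACGTAC")
  expect_equal(relative_position("ACGTACGTAC", c2), 10 / 11)
  expect_error(relative_position("TTTT", "ACGT"),
               class = "dminer_contract_error")
})

test_that("mean relative positions average over containing CDR3s", {
  cs <- cdr3_set(c("ACGTACGTGG", "GGACGTACGT"))
  pos <- mean_relative_positions("ACGTACGT", cs)
  expect_equal(pos$mean_rp, mean(c(0, 2 / 3)))
  expect_equal(pos$n_cdr3s, 2)
})

test_that("position clustering labels the middle cluster as D", {
  tbl <- tibble::tibble(sequence = paste0("e", 1:6),
                        mean_rp = c(0.10, 0.12, 0.48, 0.50, 0.52, 0.90))
  out <- classify_by_position(tbl)
  expect_equal(out$segment_class, c("V", "V", "D", "D", "D", "J"))
  # degenerate input: everything labelled D with a warning
  expect_warning(
    out2 <- classify_by_position(tibble::tibble(mean_rp = rep(0.3, 4))))
  expect_true(all(out2$segment_class == "D"))
  expect_warning(
    out3 <- classify_by_position(tibble::tibble(mean_rp = c(0.2, 0.8))))
  expect_true(all(out3$segment_class == "D"))
})

test_that("V/J-derived extensions are separated from planted genes", {
  # extensions from a planted repertoire, classified before any filtering
  rep <- planted_repertoire(n_genes = 6, n_cdr3s = 20000, rng_seed = 31,
                            len_range = c(18, 30))
  ext <- extend_seeds(rep$cdr3s, k = 10, num_seeds = 80)
  uniq <- dplyr::distinct(ext, sequence, .keep_all = TRUE)
  pos <- classify_by_position(mean_relative_positions(uniq, rep$cdr3s))
  genic <- vapply(pos$sequence, function(e) {
    any(vapply(unname(rep$genes), lcs_oracle, integer(1), a = e) >= 10)
  }, logical(1))
  v_like <- vapply(pos$sequence, function(e) {
    any(stringi::stri_detect_fixed(e, rep$model$v_suffixes))
  }, logical(1)) & !genic
  j_like <- vapply(pos$sequence, function(e) {
    any(stringi::stri_detect_fixed(e, rep$model$j_prefixes))
  }, logical(1)) & !genic
  expect_gte(mean(pos$segment_class[genic] == "D"), 0.9)
  if (any(v_like)) expect_gte(mean(pos$segment_class[v_like] == "V"), 0.8)
  if (any(j_like)) expect_gte(mean(pos$segment_class[j_like] == "J"), 0.8)
})

test_that("unidirectional extensions are filtered unless kept", {
  tbl <- tibble::tibble(sequence = c("A1", "A2", "A3"),
                        left_steps = c(0L, 3L, 2L),
                        right_steps = c(7L, 4L, 0L))
  expect_equal(filter_unidirectional(tbl)$sequence, "A2")
  expect_equal(nrow(filter_unidirectional(tbl, keep = TRUE)), 3)
})

test_that("similarity distance equals min length minus the LCS", {
  expect_equal(similarity_distance("ACGTAC", "ACGTAC"), 0)
  expect_equal(similarity_distance("GTAC", "ACGTACGT"), 0) # substring
  expect_equal(similarity_distance("ACGTACGT", "TTACGTAA"), 3) # LCS ACGTA
  # symmetry and agreement with the enumeration oracle on random pairs
  set.seed(77)
  for (i in 1:30) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(5:20, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(5:20, 1), TRUE),
               collapse = "")
    d_ab <- similarity_distance(a, b)
    expect_identical(d_ab, similarity_distance(b, a))
    expect_identical(d_ab, min(nchar(a), nchar(b)) - lcs_oracle(a, b))
    expect_gte(d_ab, 0)
  }
})

test_that("multi-string LCS picks the longest, then smallest, substring", {
  expect_equal(longest_common_substring(c("ACGTACGTACGT", "CGTACGTACGTA",
                                          "ACGTACGTACG")),
               "CGTACGTACG")
  expect_equal(longest_common_substring("ACGT"), "ACGT")
  expect_equal(longest_common_substring(c("AAAA", "CCCC")), "")
})

test_that("clique merging collapses redundant extensions", {
  exts <- c("ACGTACGTACGT", "CGTACGTACGTA", "ACGTACGTACG")
  # pairwise distances are within the default threshold
  g <- similarity_graph(exts, max_dist = 2)
  expect_equal(igraph::ecount(g), 3)
  dummy <- cdr3_set("TTCGTACGTACGTT") # contains the core
  merged <- merge_cliques(exts, dummy, re_extend = FALSE)
  expect_equal(merged, "CGTACGTACG")
  # graph without edges passes everything through
  far <- c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG")
  expect_setequal(merge_cliques(far, dummy), far)
})

test_that("merging planted duplicates restores one candidate per gene", {
  ok <- 0
  for (r in 1:5) {
    rep <- planted_repertoire(n_genes = 5, n_cdr3s = 15000,
                              rng_seed = 500 + r, len_range = c(16, 28))
    # duplicated/truncated variants of each gene, as left by seed extension
    variants <- unlist(lapply(unname(rep$genes), function(g) {
      unique(c(g, substr(g, 2, nchar(g)), substr(g, 1, nchar(g) - 2)))
    }))
    merged <- merge_cliques(variants, rep$cdr3s)
    ok <- ok + (recovered_count(merged, rep$genes) == 5 &&
                  length(merged) == 5)
  }
  expect_gte(ok, 4)
})

test_that("cross-dataset consolidation removes substrings then merges", {
  expect_equal(merge_across_datasets(list("ACGTACGTAC", "GTACGTAC")),
               "ACGTACGTAC")
  expect_setequal(
    merge_across_datasets(list(c("AAAAAAAAAA"), c("CCCCCCCCCC"))),
    c("AAAAAAAAAA", "CCCCCCCCCC"))
  # same genes found in two datasets consolidate to one entry each
  a <- c("TTCGACATTACTACGGCATGG", "GGCAATCCGGTTAACCGGTT")
  b <- c("TCGACATTACTACGGCATGGA", "GGCAATCCGGTTAACCGGTT")
  cons <- merge_across_datasets(list(a, b))
  expect_equal(length(cons), 2)
})
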