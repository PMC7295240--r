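test_that("per-trim generation probabilities match hand calculation", {
  m <- simple_model("ATGA")
  expect_equal(trim_extend_probability(m, "ATCC", 2), 1 / 5 * 1 / 16)
  expect_equal(trim_extend_probability(m, "ATCC", 3), 1 / 5 * 1 / 64)
  expect_equal(trim_extend_probability(m, "ATCC", 4), 1 / 5 * 1 / 256)
  # retained prefix mismatch has probability zero
  expect_equal(trim_extend_probability(m, "ATCC", 1), 0)
  expect_error(trim_extend_probability(m, "ATC", 1),
               class = "dminer_contract_error")
})

test_that("modified-string likelihood equals the closed form", {
  m <- simple_model("ATGA")
  expect_equal(prob_modified_given_seed(m, "ATCC"), 21 / 1280)
  expect_equal(prob_modified_given_seed(m, "ATGA"), 341 / 1280)
  expect_equal(prob_modified_given_seed(m, "GTGA"), 1 / 1280)
})

test_that("sum and closed forms agree on random pairs", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    cc <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    m <- simple_model(s)
    expect_equal(prob_modified_given_seed(m, cc, method = "sum"),
                 prob_modified_given_seed(m, cc, method = "closed_form"),
                 tolerance = 1e-13)
  }
})

test_that("the likelihood is a proper distribution over modified strings", {
  # enumeration for |s| <= 5, plus the exact integer identity
  # sum_c (|A|^(m(c)+1) - 1) = (|s|+1) * |A|^|s| * (|A|-1) ... / (|s|+1) = norm
  for (n in 2:5) {
    s <- paste(rep(c("A", "C", "G", "T"), length.out = n), collapse = "")
    m <- simple_model(s)
    all_c <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), n)))
    total <- sum(vapply(all_c, function(cc) prob_modified_given_seed(m, cc),
                        numeric(1)))
    expect_equal(total, 1, tolerance = 1e-12)
  }
  # exact combinatorial identity: strings with shared prefix exactly j
  # number 3 * 4^(n-j-1) for j < n and 1 for j = n
  for (n in 2:6) {
    lhs <- sum(3 * 4^(n - (0:(n - 1)) - 1) * (4^((0:(n - 1)) + 1) - 1)) +
      (4^(n + 1) - 1)
    expect_identical(lhs, (n + 1) * 4^n * 3)
  }
})

test_that("score_set matches its definition and links to the likelihood", {
  expect_equal(score_set(character(0), "ACGT"), 0)
  expect_equal(score_set("ATCC", "ATGA"), log(63)) # shared prefix 2
  # score - sum of log-likelihoods is the stated constant
  set.seed(5)
  s <- "ACGTAC"
  m <- simple_model(s)
  d <- cdr3_set(simulate_simple(m, 300, rng_seed = 8)$sequence)
  score <- score_set(d, s)
  ll <- sum(d$count * log(vapply(d$sequence, function(cc) {
    prob_modified_given_seed(m, cc)
  }, numeric(1))))
  n_total <- sum(d$count)
  expect_equal(score - ll, n_total * log((nchar(s) + 1) * 4^nchar(s) * 3))
  # invariant to duplication structure: multiplicities vs repeated rows
  rep_tbl <- tibble::tibble(sequence = rep(d$sequence, d$count), count = 1)
  expect_equal(score_set(rep_tbl, s), score)
})

test_that("greedy reconstruction recovers planted seeds", {
  expect_equal(reconstruct_seed_greedy(cdr3_set("ATGC", count = 5), 4), "ATGC")
  m <- simple_model("ACGTACGTAC")
  d <- simulate_simple(m, 5000, rng_seed = 11)
  expect_equal(reconstruct_seed_greedy(d, 10), "ACGTACGTAC")
})

test_that("exhaustive reconstruction is the score argmax", {
  expect_equal(brute_force_reconstruct(cdr3_set("AAAA", count = 10), 4), "AAAA")
  # tie broken lexicographically
  d <- tibble::tibble(sequence = c("AAB", "AAC"), count = 1)
  expect_equal(brute_force_reconstruct(d, 3, alphabet = c("A", "B", "C")),
               "AAB")
  # argmax property by re-enumeration
  set.seed(42)
  d2 <- cdr3_set(simulate_simple(simple_model("ACGT"), 50, rng_seed = 2)$sequence)
  best <- brute_force_reconstruct(d2, 4)
  all_c <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 4)))
  scores <- vapply(all_c, function(x) score_set(d2, x), numeric(1))
  expect_equal(score_set(d2, best), max(scores))
  expect_error(brute_force_reconstruct(cdr3_set("A"), 30),
               class = "dminer_refusal_error")
})

test_that("exhaustive reconstruction recovers planted seeds at large N", {
  hits <- 0
  for (r in 1:20) {
    g <- random_d_genes(1, c(6, 6), rng_seed = 300 + r)[[1]]
    d <- cdr3_set(simulate_simple(simple_model(g), 2000,
                                  rng_seed = 400 + r)$sequence)
    hits <- hits + (brute_force_reconstruct(d, 6) == g)
  }
  expect_gte(hits, 19)
})

test_that("simulator output is seed-deterministic and matches the model law", {
  m <- simple_model("ACGTAC")
  a <- simulate_simple(m, 100, rng_seed = 3)
  b <- simulate_simple(m, 100, rng_seed = 3)
  expect_identical(a, b)
  expect_true(all(nchar(a$sequence) == 6))

  # empirical shared-prefix distribution vs closed form, 3 MC standard errors
  big <- simulate_simple(m, 100000, rng_seed = 17)
  n <- 6
  mvals <- numeric(nrow(big))
  alive <- rep(TRUE, nrow(big))
  for (j in seq_len(n)) {
    alive <- alive & (stringi::stri_sub(big$sequence, j, j) ==
                        substr("ACGTAC", j, j))
    mvals <- mvals + alive
  }
  p_m <- c(3 * 4^(n - (0:(n - 1)) - 1) * (4^((0:(n - 1)) + 1) - 1),
           4^(n + 1) - 1) / ((n + 1) * 4^n * 3)
  for (j in 0:n) {
    emp <- mean(mvals == j)
    se <- sqrt(p_m[j + 1] * (1 - p_m[j + 1]) / 100000)
    expect_lt(abs(emp - p_m[j + 1]), 3 * se + 1e-12)
  }
  # full trimming occurs at rate ~ 1/(|s|+1)
  full <- mean(big$trim == n)
  expect_lt(abs(full - 1 / (n + 1)), 3 * sqrt(1 / 7 * 6 / 7 / 100000))
})
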