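test_that("hamming_distance matches hand counts and rejects length mismatch", {
  expect_identical(hamming_distance("ACGT", "ACGT"), 0L)
  expect_identical(hamming_distance("ACGT", "AGGA"), 2L)
  expect_error(hamming_distance("ACG", "ACGT"), "equal length")
  expect_error(hamming_distance("ACNT", "ACGT"), "invalid symbol")
})

test_that("hamming_distance equals the brute-force positional oracle", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(2:12, 1)
    v <- random_word(n)
    u <- random_word(n)
    expect_identical(hamming_distance(v, u), oracle_hamming(v, u))
  }
})

test_that("hamming_distance is a metric on equal-length words", {
  set.seed(12)
  for (rep in 1:40) {
    n <- sample(2:10, 1)
    a <- random_word(n); b <- random_word(n); c <- random_word(n)
    expect_identical(hamming_distance(a, a), 0L)
    expect_identical(hamming_distance(a, b), hamming_distance(b, a))
    expect_true(hamming_distance(a, c) <=
                  hamming_distance(a, b) + hamming_distance(b, c))
    if (a != b) expect_gt(hamming_distance(a, b), 0L)
  }
})

test_that("gc_count / gc_content count G and C bases", {
  expect_identical(gc_count("ATGC"), 2L)
  expect_identical(gc_count("AATT"), 0L)
  expect_identical(gc_count("GGCC"), 4L)
  expect_equal(gc_content("ATGC"), 0.5)
  # GC + AT partition every word
  set.seed(13)
  for (rep in 1:20) {
    w <- random_word(sample(1:12, 1))
    at <- sum(strsplit(w, "")[[1]] %in% c("A", "T"))
    expect_identical(gc_count(w) + at, nchar(w))
  }
})

test_that("no-runlength detects homopolymer runs", {
  expect_false(satisfies_no_runlength("TAAAGC"))
  expect_true(satisfies_no_runlength("ACGT"))
  expect_false(satisfies_no_runlength("ACCA"))
  expect_equal(satisfies_no_runlength(c("ACGT", "ACCA")), c(TRUE, FALSE))
})

test_that("non-adjacent subsequence constraint finds tandem K-mers", {
  expect_false(satisfies_non_adjacent_subsequence("GTAGAGAGCTA", lengths = 2))
  expect_false(satisfies_non_adjacent_subsequence("AGTGATGACG", lengths = 3))
  expect_true(satisfies_non_adjacent_subsequence("ACGT", lengths = c(2, 3)))
  # matches the scanning oracle on random words
  set.seed(14)
  for (rep in 1:60) {
    w <- random_word(sample(4:14, 1))
    expect_identical(satisfies_non_adjacent_subsequence(w, c(2L, 3L)),
                     oracle_tandem_free(w, c(2L, 3L)))
  }
})

test_that("NS with K = 1 degenerates to the no-runlength constraint", {
  set.seed(15)
  words <- vapply(1:80, function(i) random_word(sample(2:10, 1)), "")
  expect_identical(satisfies_non_adjacent_subsequence(words, lengths = 1L),
                   satisfies_no_runlength(words))
})

test_that("constraint_profile defaults and validation", {
  p_even <- constraint_profile(8, 5)
  expect_identical(p_even$gc_counts, 4L)
  p_odd <- constraint_profile(9, 5)
  expect_identical(p_odd$gc_counts, c(4L, 5L))
  expect_error(constraint_profile(4, 5), "d <= n")
  expect_error(constraint_profile(4, 2, gc_counts = 7), "0:n")
})

test_that("is_feasible_word combines toggled constraints", {
  expect_true(is_feasible_word("ATGC", constraint_profile(4, 1, gc_counts = 2)))
  expect_false(is_feasible_word("TAAAGC", constraint_profile(6, 1, gc_counts = 3)))
  expect_false(is_feasible_word(
    "AGAGTC", constraint_profile(6, 1, gc_counts = 3, ns = TRUE)))
  expect_error(is_feasible_word("ACG", constraint_profile(4, 1)), "length")
})

test_that("feasibility is invariant under the A<->T, G<->C relabeling", {
  swap <- function(w) chartr("ATGC", "TACG", w)
  set.seed(16)
  p <- constraint_profile(8, 3, ns = TRUE)
  for (rep in 1:60) {
    w <- random_word(8)
    expect_identical(is_feasible_word(w, p), is_feasible_word(swap(w), p))
  }
})

test_that("validate_codeset reports every violation and accepts valid sets", {
  p3 <- constraint_profile(4, 3, gc_counts = 0:4, nl = FALSE)
  expect_true(validate_codeset(character(0), p3)$valid)
  expect_true(validate_codeset(c("ATGC", "GCAT"), p3)$valid)
  bad <- validate_codeset(c("ATGC", "ATGG"), p3)
  expect_false(bad$valid)
  expect_true("distance" %in% bad$violations$type)
  dup <- validate_codeset(c("ATGC", "ATGC"), p3)
  expect_true("duplicate" %in% dup$violations$type)
})

test_that("lowercase input is accepted, non-ACGT symbols are rejected", {
  expect_identical(hamming_distance("acgt", "ACGT"), 0L)
  expect_true(satisfies_no_runlength("acgt"))
  expect_error(gc_count("ACGU"), "invalid symbol")
  expect_error(gc_count("AC-T"), "invalid symbol")
})
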