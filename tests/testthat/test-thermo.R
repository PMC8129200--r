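test_that("Tm agrees with an independent NN calculator on frozen values", {
  # reference values computed with a second, independent implementation of
  # the unified NN table at C_T = 10 nM, 1 M Na+ (agreement well inside 0.5 C)
  m <- thermo_model()
  seqs <- c("ATGAGCTAC", "TAGCTTCAGC", "ACACACAC", "AGCTGGCAT",
            "CGTACGTAGCGG", "TCATCATCA")
  want <- c(19.64975943, 30.72423762, 16.49561443, 29.27256918,
            47.74483563, 16.70302533)
  expect_equal(melting_temperature(seqs, m), want, tolerance = 1e-6)
  # self-complementary duplex (symmetry factor 1 + symmetry entropy)
  expect_equal(melting_temperature("ACGTACGT", m), 21.05524437,
               tolerance = 1e-6)
  # salt correction away from the 1 M reference
  expect_equal(melting_temperature("ATGAGCTAC", thermo_model(na = 0.5)),
               16.87712519, tolerance = 1e-6)
})

test_that("Tm is invariant under reverse complement", {
  set.seed(61)
  for (rep in 1:30) {
    w <- random_word(sample(4:14, 1))
    expect_equal(melting_temperature(w),
                 melting_temperature(reverse_complement(w)),
                 tolerance = 1e-9)
  }
})

test_that("Tm is strictly monotone in log strand concentration", {
  w <- "ATGAGCTAC"
  concs <- 10^seq(-9, -5, by = 1)
  tms <- vapply(concs, function(ct) melting_temperature(w, thermo_model(conc = ct)),
                numeric(1))
  expect_true(all(diff(tms) > 0))
})

test_that("melting_temperature rejects words shorter than a dinucleotide", {
  expect_error(melting_temperature("A"), "at least 2 bases")
})

test_that("tm_variance is the population variance with a closed two-word form", {
  m <- thermo_model()
  expect_equal(as.numeric(tm_variance(rep("ATGAGCTAC", 4), m)), 0)
  pair <- c("ATGAGCTAC", "TCATCATCA")
  t12 <- melting_temperature(pair, m)
  expect_equal(as.numeric(tm_variance(pair, m)), ((t12[1] - t12[2]) / 2)^2)
  # two-pass independent computation
  set.seed(62)
  words <- vapply(1:12, function(i) random_word(8), "")
  tm <- melting_temperature(words, m)
  two_pass <- sum((tm - sum(tm) / length(tm))^2) / length(tm)
  expect_equal(as.numeric(tm_variance(words, m)), two_pass, tolerance = 1e-9)
})

test_that("enabling NS never enlarges the feasible pool", {
  for (n in 6:8) {
    p_no <- constraint_profile(n, 3, ns = FALSE)
    p_ns <- constraint_profile(n, 3, ns = TRUE)
    pool_no <- enumerate_feasible(p_no)
    pool_ns <- enumerate_feasible(p_ns)
    expect_true(all(pool_ns %in% pool_no))
    expect_lte(length(pool_ns), length(pool_no))
  }
})

test_that("ns_effect builds paired sets and reports both variances", {
  ctl <- clgbo_control(pop_size = 20, max_iter = 100, per_coordinate = TRUE)
  eff <- ns_effect(7, d = 4, control = ctl, stall_limit = 5, seed = 63)
  expect_s3_class(eff, "ns_effect")
  sets <- attr(eff, "sets")[[1]]
  expect_true(all(satisfies_non_adjacent_subsequence(sets$with$words)))
  expect_true(validate_codeset(sets$with)$valid)
  expect_true(validate_codeset(sets$without)$valid)
  expect_equal(eff$diff, eff$var_without - eff$var_with)
  # report serialization round-trips
  path <- tempfile(fileext = ".json")
  write_report_json(eff, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$var_with, eff$var_with, tolerance = 1e-12)
  expect_equal(back$var_without, eff$var_without, tolerance = 1e-12)
})

test_that("the bundled reference comparison table has the published shape", {
  tab <- tm_reference_table()
  expect_identical(nrow(tab), 15L)
  expect_identical(sort(unique(tab$n)), c(8L, 9L, 10L))
  expect_identical(sort(unique(tab$d)), 3:7)
})
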