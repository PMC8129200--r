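fast_ctl <- clgbo_control(pop_size = 20L, max_iter = 150L,
                          per_coordinate = TRUE)

test_that("decode_position floors into A/C/G/T cells with clamping", {
  expect_identical(decode_position(c(0.2, 1.7, 2.0, 3.9)), "ACGT")
  expect_identical(decode_position(rep(0, 6)), "AAAAAA")
  expect_identical(decode_position(c(-3, 4.0, 9)), "ATT")
  # constant on each unit cell
  set.seed(51)
  for (rep in 1:20) {
    cell <- sample(0:3, 5, replace = TRUE)
    x1 <- cell + runif(5)
    x2 <- cell + runif(5)
    expect_identical(decode_position(x1), decode_position(x2))
  }
})

test_that("candidate_fitness is zero iff the word extends the set", {
  p <- constraint_profile(4, 3, gc_counts = 2)
  expect_identical(candidate_fitness(c(0.5, 3.5, 1.5, 2.5), character(0), p), 0)
  # duplicate of a member at d = 3: shortfall 3 plus duplicate 1
  expect_gte(candidate_fitness(c(0.5, 3.5, 1.5, 2.5), "ATCG", p), 4)
})

test_that("penalty agrees with an independent constraint-by-constraint oracle", {
  set.seed(52)
  p <- constraint_profile(6, 3, ns = TRUE)
  members <- c("ACGTAG", "TGCATC")
  for (rep in 1:60) {
    x <- runif(6, 0, 4)
    expect_equal(candidate_fitness(x, members, p, engine = "cpp"),
                 oracle_penalty(x, members, p))
    expect_equal(candidate_fitness(x, members, p, engine = "r"),
                 oracle_penalty(x, members, p))
  }
})

test_that("enumerate_feasible produces exactly the feasible words in order", {
  got <- enumerate_feasible(constraint_profile(2, 1, gc_counts = 1))
  expect_identical(got, c("AC", "AG", "CA", "CT", "GA", "GT", "TC", "TG"))
  expect_identical(
    enumerate_feasible(constraint_profile(1, 1, gc_counts = 0, nl = FALSE)),
    c("A", "T"))
  # closed form for no-runlength-only words: 4 * 3^(n-1)
  for (n in 2:6) {
    p <- constraint_profile(n, 1, gc_counts = 0:n)
    expect_identical(length(enumerate_feasible(p)), as.integer(4 * 3^(n - 1)))
  }
  expect_error(enumerate_feasible(constraint_profile(13, 3)), "guard")
})

test_that("exact_max_codeset certifies small instances", {
  s <- exact_max_codeset(constraint_profile(4, 3))
  expect_identical(length(s), 12L)
  expect_true(s$optimal)
  expect_true(validate_codeset(s)$valid)
  # d = 1: the clique is the whole feasible pool
  p1 <- constraint_profile(3, 1)
  s1 <- exact_max_codeset(p1)
  expect_identical(length(s1), length(enumerate_feasible(p1)))
})

test_that("branch-and-bound equals brute-force subset search on tiny instances", {
  for (prof in list(constraint_profile(4, 4, gc_counts = 2),
                    constraint_profile(3, 2, gc_counts = 1),
                    constraint_profile(4, 3, gc_counts = 2, ns = TRUE))) {
    words <- enumerate_feasible(prof)
    H <- clgbo:::.hamming_matrix_cpp(clgbo:::words_to_matrix(words))
    adj <- H >= prof$d
    diag(adj) <- FALSE
    expect_identical(length(exact_max_codeset(prof)),
                     oracle_max_clique_size(adj))
  }
})

test_that("branch-and-bound agrees with igraph's clique number", {
  for (prof in list(constraint_profile(5, 4), constraint_profile(6, 5))) {
    words <- enumerate_feasible(prof)
    H <- clgbo:::.hamming_matrix_cpp(clgbo:::words_to_matrix(words))
    g <- igraph::graph_from_adjacency_matrix(H >= prof$d, mode = "undirected",
                                             diag = FALSE)
    expect_identical(length(exact_max_codeset(prof)),
                     as.integer(igraph::clique_num(g)))
  }
})

test_that("the stochastic builder returns valid sets the oracle dominates", {
  p <- constraint_profile(4, 3)
  ctl <- clgbo_control(pop_size = 20L, max_iter = 100L, per_coordinate = TRUE)
  s <- build_codeset(p, control = ctl, stall_limit = 5, plateaus = 80,
                     seed = 53)
  expect_true(validate_codeset(s)$valid)
  # the plateau-escape walk recovers the certified optimum on this instance
  expect_identical(length(s), 12L)
  expect_lte(length(s), length(exact_max_codeset(p)))
  # reproducibility of the whole construction
  s2 <- build_codeset(p, control = ctl, stall_limit = 5, plateaus = 80,
                      seed = 53)
  expect_identical(s$words, s2$words)
})

test_that("with d = 1 the builder can only stop at the full feasible pool", {
  p <- constraint_profile(3, 1, gc_counts = 1)
  pool <- enumerate_feasible(p)
  s <- build_codeset(p, control = fast_ctl, stall_limit = 10, plateaus = 2,
                     seed = 54)
  expect_setequal(s$words, pool)
})

test_that("coding_rate implements log4(M)/n", {
  expect_equal(coding_rate(199, 9), log(199, 4) / 9)
  expect_equal(round(coding_rate(199, 9), 2), 0.42)
  # 113 words of length 8 also achieve rate 0.42 (0.4263 to full precision)
  expect_equal(floor(coding_rate(113, 8) * 100) / 100, 0.42)
  expect_identical(coding_rate(1, 7), 0)
})

test_that("bounds tables are monotone in d and under adding the NS constraint", {
  # cells chosen sparse enough for the exact search to certify quickly
  tab <- rbind(bounds_table(4, 3:4, mode = "exact"),
               bounds_table(5, 4:5, mode = "exact"),
               bounds_table(6, 5:6, mode = "exact"))
  expect_true(all(tab$optimal))
  for (n in unique(tab$n)) {
    sizes <- tab$size[tab$n == n][order(tab$d[tab$n == n])]
    expect_true(all(diff(sizes) <= 0))
  }
  tab_ns <- rbind(bounds_table(4, 3:4, mode = "exact", ns = TRUE),
                  bounds_table(5, 4:5, mode = "exact", ns = TRUE),
                  bounds_table(6, 5:6, mode = "exact", ns = TRUE))
  merged <- merge(tab, tab_ns, by = c("n", "d"), suffixes = c("", "_ns"))
  expect_true(all(merged$size_ns <= merged$size))
  # single exact cell reproduces exact_max_codeset
  one <- bounds_table(4, 3, mode = "exact")
  expect_identical(one$size, length(exact_max_codeset(constraint_profile(4, 3))))
})
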