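# Independent brute-force oracles used to cross-check the implementation.

# positional character-by-character comparison, no shared code with the package
oracle_hamming <- function(v, u) {
  a <- strsplit(v, "")[[1]]
  b <- strsplit(u, "")[[1]]
  stopifnot(length(a) == length(b))
  n <- 0L
  for (i in seq_along(a)) if (a[i] != b[i]) n <- n + 1L
  n
}

# scan every adjacent K-mer pair explicitly via substring comparison
oracle_tandem_free <- function(w, ks) {
  n <- nchar(w)
  for (k in ks) {
    if (n < 2 * k) next
    for (i in seq_len(n - 2 * k + 1)) {
      if (substr(w, i, i + k - 1) == substr(w, i + k, i + 2 * k - 1))
        return(FALSE)
    }
  }
  TRUE
}

random_word <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

# exhaustive maximum clique by recursion over subsets (tiny graphs only)
oracle_max_clique_size <- function(adj) {
  n <- nrow(adj)
  best <- 0L
  rec <- function(cur_size, cand) {
    if (cur_size + length(cand) <= best) return()
    if (length(cand) == 0L) {
      best <<- max(best, cur_size)
      return()
    }
    v <- cand[1L]
    rest <- cand[-1L]
    rec(cur_size + 1L, rest[adj[v, rest]])
    rec(cur_size, rest)
  }
  rec(0L, seq_len(n))
  best
}

# independent constraint-by-constraint penalty computation
oracle_penalty <- function(x, members, profile) {
  codes <- pmin(pmax(floor(x), 0), 3)
  word <- paste(c("A", "C", "G", "T")[codes + 1], collapse = "")
  chars <- strsplit(word, "")[[1]]
  pen <- min(abs(sum(chars %in% c("G", "C")) - profile$gc_counts))
  if (profile$nl) {
    for (i in seq_len(length(chars) - 1))
      if (chars[i] == chars[i + 1]) pen <- pen + 1
  }
  if (profile$ns) {
    for (k in profile$ns_lengths) {
      if (length(chars) < 2 * k) next
      for (i in seq_len(length(chars) - 2 * k + 1))
        if (substr(word, i, i + k - 1) == substr(word, i + k, i + 2 * k - 1))
          pen <- pen + 1
    }
  }
  for (m in members) {
    h <- oracle_hamming(word, m)
    pen <- pen + max(0, profile$d - h) + (h == 0)
  }
  pen
}
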