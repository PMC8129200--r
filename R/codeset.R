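# Coding-set construction: continuous-to-discrete decoding, penalty fitness,
# incremental CLGBO search, exhaustive enumeration, exact maximum-clique
# oracle, coding rate, and lower-bound tables.

new_dna_codeset <- function(words, profile, provenance,
                            optimal = NA, meta = list()) {
  structure(list(words = as.character(words), profile = profile,
                 provenance = provenance, optimal = optimal, meta = meta),
            class = "dna_codeset")
}

#' @export
print.dna_codeset <- function(x, ...) {
  cat(sprintf("DNA coding set: %d word(s) of length %d (d >= %d)\n",
              length(x$words), x$profile$n, x$profile$d))
  cat("  provenance:", x$provenance,
      if (isTRUE(x$optimal)) "(certified maximum)" else "", "\n")
  if (length(x$words)) {
    show <- utils::head(x$words, 8L)
    cat("  words:", paste(show, collapse = " "),
        if (length(x$words) > 8L) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
summary.dna_codeset <- function(object, ...) {
  print(object)
  if (length(object$words)) {
    gc <- vapply(object$words, gc_count, integer(1))
    cat(sprintf("  GC counts: %s\n",
                paste(names(table(gc)), table(gc), sep = "x", collapse = ", ")))
    cat(sprintf("  coding rate R = log4(M)/n = %.4f\n",
                coding_rate(length(object$words), object$profile$n)))
    v <- validate_codeset(object)
    cat("  validation:", if (v$valid) "passes all constraints" else
      sprintf("INVALID (%d violations)", nrow(v$violations)), "\n")
  }
  invisible(object)
}

#' @export
as.character.dna_codeset <- function(x, ...) x$words

#' @export
length.dna_codeset <- function(x) length(x$words)

#' Decode a continuous optimizer position into a DNA codeword
#'
#' Per-coordinate floor mapping over the box `[0, 4)^n`: values in `[0,1)`
#' give A, `[1,2)` C, `[2,3)` G, `[3,4]` T (the boundary 4.0 maps to T).
#' Coordinates outside the box are clamped first. The map is constant on
#' each unit cell and surjective onto all `4^n` words, so the continuous
#' population search explores the full discrete space.
#'
#' @param x Numeric vector of length `n`.
#' @return A codeword string.
#' @examples
#' decode_position(c(0.2, 1.7, 2.0, 3.9))  # "ACGT"
#' @export
decode_position <- function(x) {
  codes <- pmin(pmax(floor(as.numeric(x)), 0), 3)
  codes_to_word(as.integer(codes))
}

.profile_penalty_data <- function(members_codes, profile) {
  gc_allowed <- integer(profile$n + 1L)
  gc_allowed[profile$gc_counts + 1L] <- 1L
  list(members = members_codes, d = profile$d, gc_allowed = gc_allowed,
       nl = profile$nl,
       ns2 = profile$ns && 2L %in% profile$ns_lengths,
       ns3 = profile$ns && 3L %in% profile$ns_lengths)
}

#' Penalty fitness of a candidate position against a growing coding set
#'
#' The objective minimized when hunting the next codeword. It is 0 exactly
#' when the decoded word is feasible under the profile, distinct from every
#' current member, and at Hamming distance at least `d` from each of them.
#' Otherwise it is the sum of: the GC-count deviation from the nearest
#' allowed count, the number of adjacent identical-base pairs (if NL), the
#' number of tandem-repeated K-mers (if NS), the distance shortfall
#' `max(0, d - H)` summed over members, and 1 if the word duplicates a
#' member.
#'
#' @param x Numeric position in `[0, 4]^n` (decoded via [decode_position()]).
#' @param members Character vector of current set members (possibly empty).
#' @param profile A [constraint_profile()].
#' @param engine `"cpp"` (the compiled version used in the search) or `"r"`
#'   (reference implementation).
#' @return Non-negative penalty; 0 iff the candidate extends the set.
#' @export
candidate_fitness <- function(x, members, profile, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(profile, "constraint_profile"),
            length(x) == profile$n)
  mcodes <- if (length(members)) words_to_matrix(members) else
    matrix(integer(0), 0L, profile$n)
  if (engine == "cpp")
    return(.codeset_penalty_cpp(as.numeric(x), .profile_penalty_data(mcodes, profile)))
  # reference path, scanning constraints one by one
  w <- decode_position(x)
  codes <- word_to_codes(w)
  pen <- min(abs(sum(codes == 1L | codes == 2L) - profile$gc_counts))
  if (profile$nl && profile$n > 1L)
    pen <- pen + sum(codes[-1L] == codes[-profile$n])
  if (profile$ns) {
    for (k in profile$ns_lengths) {
      if (profile$n < 2L * k) next
      for (i in seq_len(profile$n - 2L * k + 1L))
        if (all(codes[i:(i + k - 1L)] == codes[(i + k):(i + 2L * k - 1L)]))
          pen <- pen + 1L
    }
  }
  for (m in members) {
    h <- hamming_distance(w, m)
    pen <- pen + max(0L, profile$d - h) + (h == 0L)
  }
  pen
}

#' Grow a DNA coding set with the CLGBO optimizer
#'
#' Incremental construction: the optimizer repeatedly searches the continuous
#' box `[0, 4]^n` for a zero-penalty position (see [candidate_fitness()]);
#' each success appends the decoded codeword to the set and restarts the
#' search against the enlarged set. When `stall_limit` consecutive restarts
#' fail to find a compatible word the set has reached a maximal plateau: the
#' current set is snapshotted if it is the largest seen, `plateau_drop`
#' random members are removed, and the search continues (a ruin-and-recreate
#' walk across maximal sets, which escapes the small maximal sets that pure
#' greedy accumulation gets stuck on). Construction stops after `plateaus`
#' such escapes (or when `max_words` is reached) and returns the largest
#' snapshot. The returned set always passes [validate_codeset()].
#'
#' @param profile A [constraint_profile()].
#' @param control A [clgbo_control()]; `stop_at` is forced to 0 so each
#'   restart ends as soon as a feasible word is found. The builder default
#'   turns on per-coordinate mutation draws: the decoded penalty landscape
#'   is piecewise constant on unit cells, and coordinate-wise jumps explore
#'   neighbouring cells far more effectively than whole-position rescaling.
#' @param stall_limit Consecutive failed restarts tolerated before a plateau
#'   is declared (default 20).
#' @param plateaus Number of maximal-set plateaus explored before stopping
#'   (default 20). `plateaus = 1` stops at the first stall.
#' @param plateau_drop Members removed at each plateau escape (default 2).
#' @param max_words Optional cap on the set size.
#' @param seed Optional integer seed; restarts consume one shared RNG stream
#'   so the whole construction is reproducible.
#' @param verbose Print progress?
#' @return A `dna_codeset` with provenance `"clgbo"`; `meta` records the
#'   number of restarts and the seed.
#' @examples
#' p <- constraint_profile(4, 3)
#' s <- build_codeset(p, control = clgbo_control(pop_size = 20, max_iter = 100),
#'                    stall_limit = 5, seed = 1)
#' length(s)
#' @export
build_codeset <- function(profile,
                          control = clgbo_control(per_coordinate = TRUE),
                          stall_limit = 20L, plateaus = 20L,
                          plateau_drop = 2L, max_words = Inf, seed = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(profile, "constraint_profile"),
            inherits(control, "clgbo_control"), stall_limit >= 1L,
            plateaus >= 1L, plateau_drop >= 1L)
  if (!is.null(seed)) set.seed(seed)
  control$stop_at <- 0
  n <- profile$n
  members_codes <- matrix(integer(0), 0L, n)
  words <- character(0)
  best_words <- character(0)
  stall <- 0L
  restarts <- 0L
  plateau_count <- 0L
  lower <- rep(0, n)
  upper <- rep(4, n)
  repeat {
    data <- .profile_penalty_data(members_codes, profile)
    res <- .clgbo_run(100L, NULL, data, lower, upper, control)
    restarts <- restarts + 1L
    if (res$value <= 0) {
      w <- decode_position(res$best)
      # postcondition guard; a zero penalty implies feasibility + distance
      stopifnot(is_feasible_word(w, profile), !(w %in% words))
      words <- c(words, w)
      members_codes <- rbind(members_codes, word_to_codes(w))
      stall <- 0L
      if (verbose)
        message(sprintf("restart %d: added %s (set size %d)", restarts, w,
                        length(words)))
      if (length(words) >= max_words) break
    } else {
      stall <- stall + 1L
      if (stall >= stall_limit) {
        # maximal plateau: snapshot, then ruin a few members and regrow
        if (length(words) > length(best_words)) best_words <- words
        plateau_count <- plateau_count + 1L
        if (plateau_count >= plateaus) break
        keep <- sample.int(length(words),
                           max(0L, length(words) - plateau_drop))
        words <- words[keep]
        members_codes <- members_codes[keep, , drop = FALSE]
        stall <- 0L
        if (verbose)
          message(sprintf("plateau %d: kept %d members", plateau_count,
                          length(words)))
      }
    }
  }
  if (length(words) > length(best_words)) best_words <- words
  new_dna_codeset(best_words, profile, "clgbo",
                  meta = list(restarts = restarts, seed = seed,
                              stall_limit = stall_limit,
                              plateaus = plateau_count))
}

#' Enumerate all feasible codewords under a profile
#'
#' Exhaustive generation of the words passing every intra-word constraint of
#' the profile, in lexicographic order (A < C < G < T). Words are grown one
#' base at a time with homopolymer pruning, so the no-runlength case touches
#' only `4 * 3^(n-1)` prefixes rather than `4^n`.
#'
#' @param profile A [constraint_profile()].
#' @param max_n Guard on the word length (default 12); longer words raise an
#'   error advising the stochastic builder.
#' @return Character vector of feasible words.
#' @examples
#' enumerate_feasible(constraint_profile(2, 1, gc_counts = 1))  # 8 words
#' @export
enumerate_feasible <- function(profile, max_n = 12L) {
  stopifnot(inherits(profile, "constraint_profile"))
  n <- profile$n
  if (n > max_n)
    stop("n = ", n, " exceeds the enumeration guard (", max_n,
         "); use build_codeset() for large n", call. = FALSE)
  mat <- matrix(0:3, ncol = 1L)
  if (n > 1L) {
    for (k in 2:n) {
      m <- nrow(mat)
      cand <- rep(0:3, times = m)
      idx <- rep(seq_len(m), each = 4L)
      keep <- if (profile$nl) cand != mat[idx, k - 1L] else rep(TRUE, 4L * m)
      mat <- cbind(mat[idx[keep], , drop = FALSE], cand[keep])
    }
  }
  gc <- rowSums(mat == 1L | mat == 2L)
  mat <- mat[gc %in% profile$gc_counts, , drop = FALSE]
  if (profile$ns && nrow(mat)) {
    ok <- rep(TRUE, nrow(mat))
    for (k in profile$ns_lengths) {
      if (n < 2L * k) next
      for (i in seq_len(n - 2L * k + 1L)) {
        eq <- rep(TRUE, nrow(mat))
        for (j in 0:(k - 1L)) eq <- eq & (mat[, i + j] == mat[, i + k + j])
        ok <- ok & !eq
      }
    }
    mat <- mat[ok, , drop = FALSE]
  }
  matrix_to_words(mat)
}

#' Exact maximum coding set via branch-and-bound clique search
#'
#' Builds the compatibility graph over all feasible words (vertices) with an
#' edge whenever the Hamming distance is at least `d`, then finds a maximum
#' clique by branch and bound with a greedy-coloring upper bound, processing
#' vertices in descending-degree order. The clique is the provably largest
#' coding set for the profile, certifying the heuristic lower bounds on
#' small instances.
#'
#' @param profile A [constraint_profile()].
#' @param max_n Enumeration guard passed to [enumerate_feasible()].
#' @param node_budget Maximum branch-and-bound nodes explored (default 5e7).
#'   If exceeded, the best clique found so far is returned with
#'   `optimal = FALSE`.
#' @return A `dna_codeset` with provenance `"exact"`; its `optimal` field is
#'   `TRUE` iff the search ran to completion.
#' @examples
#' s <- exact_max_codeset(constraint_profile(4, 3))
#' length(s)  # 12
#' @export
exact_max_codeset <- function(profile, max_n = 12L, node_budget = 5e7) {
  words <- enumerate_feasible(profile, max_n = max_n)
  if (length(words) == 0L)
    return(new_dna_codeset(character(0), profile, "exact", optimal = TRUE))
  codes <- words_to_matrix(words)
  res <- .max_clique_cpp(codes, profile$d, node_budget)
  set <- new_dna_codeset(words[res$clique], profile, "exact",
                         optimal = isTRUE(res$complete),
                         meta = list(n_feasible = length(words),
                                     bb_nodes = res$nodes))
  if (!isTRUE(res$complete))
    warning("node budget exceeded; returning best clique found (not certified)",
            call. = FALSE)
  set
}

#' Coding rate of a set of M words of length n
#'
#' `R = log4(M) / n`, the information per base available when addressing
#' with the code. Larger sets at the same length, or equal-size sets at a
#' shorter length, raise the rate.
#'
#' @param M Set size (positive integer).
#' @param n Word length.
#' @return The coding rate.
#' @examples
#' coding_rate(199, 9)  # ~0.42
#' @export
coding_rate <- function(M, n) {
  stopifnot(M >= 1, n >= 1)
  log(M, base = 4) / n
}

#' Lower-bound table of coding-set sizes over an (n, d) grid
#'
#' For each cell, constructs (or certifies) a coding set and records its
#' size with provenance. Sizes are non-increasing in `d` for fixed `n`, and
#' enabling the tandem-repeat constraint can only shrink them, which the
#' generated table can be checked against.
#'
#' @param n_values,d_values Integer vectors spanning the grid; cells with
#'   `d > n` are skipped.
#' @param mode `"exact"` (enumeration + clique oracle) or `"clgbo"`
#'   (stochastic builder).
#' @param ns Apply the non-adjacent subsequence constraint?
#' @param control,stall_limit,seed Passed to [build_codeset()] in clgbo mode.
#' @param node_budget Passed to [exact_max_codeset()] in exact mode.
#' @return A data frame with columns `n`, `d`, `size`, `provenance`,
#'   `optimal`.
#' @export
bounds_table <- function(n_values, d_values, mode = c("exact", "clgbo"),
                         ns = FALSE, control = clgbo_control(),
                         stall_limit = 20L, seed = NULL, node_budget = 5e7) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (n in sort(as.integer(n_values))) {
    for (d in sort(as.integer(d_values))) {
      if (d > n) next
      p <- constraint_profile(n, d, ns = ns)
      set <- if (mode == "exact")
        exact_max_codeset(p, node_budget = node_budget)
      else
        build_codeset(p, control = control, stall_limit = stall_limit)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, d = d, size = length(set$words),
        provenance = set$provenance,
        optimal = isTRUE(set$optimal))
    }
  }
  do.call(rbind, rows)
}
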