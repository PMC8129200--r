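#' @useDynLib clgbo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd wilcox.test runif rnorm var setNames
#' @importFrom utils write.csv modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

# character word -> integer codes 0:3 (A,C,G,T), case-insensitive, strict alphabet
word_to_codes <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  codes <- match(chars, DNA_BASES) - 1L
  if (anyNA(codes)) {
    bad <- which(is.na(codes))
    stop(sprintf("invalid symbol '%s' at position %d (alphabet is A/C/G/T)",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  codes
}

codes_to_word <- function(codes) paste(DNA_BASES[codes + 1L], collapse = "")

# many words -> codes matrix (rows = words); all words must share one length
words_to_matrix <- function(words) {
  n <- unique(nchar(words))
  if (length(n) > 1L)
    stop("all codewords must have the same length", call. = FALSE)
  if (length(words) == 0L) return(matrix(integer(0), 0L, 0L))
  t(vapply(words, word_to_codes, integer(n[1]), USE.NAMES = FALSE))
}

matrix_to_words <- function(codes) {
  if (nrow(codes) == 0L) return(character(0))
  apply(codes, 1L, codes_to_word)
}

#' Hamming distance between two equal-length DNA words
#'
#' Counts the positions at which two codewords differ. A coding set for DNA
#' storage requires every unordered pair of words to be at distance at least
#' `d`, which limits cross-hybridisation between address/primer sequences.
#'
#' @param v,u Codewords (single character strings over A/C/G/T, case
#'   insensitive) of equal length.
#' @return Non-negative integer distance.
#' @examples
#' hamming_distance("ACGT", "AGGA")  # 2
#' @export
hamming_distance <- function(v, u) {
  a <- word_to_codes(v)
  b <- word_to_codes(u)
  if (length(a) != length(b))
    stop("Hamming distance requires words of equal length (got ",
         length(a), " and ", length(b), ")", call. = FALSE)
  sum(a != b)
}

#' GC count and GC fraction of a DNA word
#'
#' @param s A codeword (character string over A/C/G/T).
#' @return `gc_count()` returns the number of G and C bases; `gc_content()`
#'   the fraction in `[0, 1]`. A fraction of 0.5 (count n/2 for even n) is
#'   the thermodynamically balanced target for storage codes.
#' @examples
#' gc_count("ATGC")    # 2
#' gc_content("ATGC")  # 0.5
#' @export
gc_count <- function(s) {
  codes <- word_to_codes(s)
  sum(codes == 1L | codes == 2L)
}

#' @rdname gc_count
#' @export
gc_content <- function(s) gc_count(s) / nchar(s)

#' Homopolymer (no-runlength) constraint
#'
#' TRUE iff no two adjacent bases are identical. Homopolymer runs are a major
#' source of insertion/deletion miscalls in synthesis and sequencing, so
#' storage codewords exclude them entirely.
#'
#' @param s Character vector of codewords.
#' @return Logical vector, one entry per word.
#' @examples
#' satisfies_no_runlength(c("ACGT", "TAAAGC"))  # TRUE FALSE
#' @export
satisfies_no_runlength <- function(s) {
  vapply(s, function(w) {
    codes <- word_to_codes(w)
    n <- length(codes)
    n < 2L || all(codes[-1L] != codes[-n])
  }, logical(1), USE.NAMES = FALSE)
}

#' Non-adjacent subsequence (tandem-repeat) constraint
#'
#' TRUE iff the word contains no immediately tandem-repeated K-mer for any K
#' in `lengths`: no index i such that the K bases starting at i equal the K
#' bases starting at i + K. Adjacent repeated subsequences promote polymerase
#' slippage during synthesis and misalignment during sequencing; excluding
#' them makes coding sets more robust. Words shorter than 2K trivially
#' satisfy the constraint for that K. With `lengths = 1` the constraint
#' degenerates to [satisfies_no_runlength()].
#'
#' @param s Character vector of codewords.
#' @param lengths Integer vector of subsequence lengths K (default `c(2, 3)`).
#' @return Logical vector, one entry per word.
#' @examples
#' satisfies_non_adjacent_subsequence("GTAGAGAGCTA", lengths = 2)  # FALSE (AG.AG)
#' satisfies_non_adjacent_subsequence("AGTGATGACG", lengths = 3)   # FALSE (TGA.TGA)
#' @export
satisfies_non_adjacent_subsequence <- function(s, lengths = c(2L, 3L)) {
  lengths <- as.integer(lengths)
  stopifnot(all(lengths >= 1L))
  vapply(s, function(w) {
    codes <- word_to_codes(w)
    n <- length(codes)
    for (k in lengths) {
      if (n < 2L * k) next
      for (i in seq_len(n - 2L * k + 1L)) {
        if (all(codes[i:(i + k - 1L)] == codes[(i + k):(i + 2L * k - 1L)]))
          return(FALSE)
      }
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Constraint profile for a DNA storage coding set
#'
#' Bundles the parameters that define feasibility of a single codeword and
#' compatibility of a pair: word length `n`, minimum pairwise Hamming
#' distance `d`, the set of admissible G+C counts, and the homopolymer (NL)
#' and tandem-repeat (NS) toggles. The default GC window targets 50% GC:
#' `n/2` for even `n` and `{floor(n/2), ceiling(n/2)}` for odd `n`, the two
#' counts closest to balance.
#'
#' @param n Word length (positive integer).
#' @param d Minimum pairwise Hamming distance, `1 <= d <= n`.
#' @param gc_counts Integer vector of allowed G+C counts (subset of `0:n`).
#'   `NULL` selects the balanced default described above.
#' @param nl Enforce the no-runlength (homopolymer) constraint?
#' @param ns Enforce the non-adjacent subsequence constraint?
#' @param ns_lengths Tandem-repeat lengths for the NS constraint (subset of
#'   `c(2, 3)`), applied simultaneously by default.
#' @return An object of class `constraint_profile`.
#' @examples
#' constraint_profile(9, 5, ns = TRUE)   # gc_counts 4:5
#' @export
constraint_profile <- function(n, d, gc_counts = NULL, nl = TRUE, ns = FALSE,
                               ns_lengths = c(2L, 3L)) {
  n <- as.integer(n)
  d <- as.integer(d)
  stopifnot(length(n) == 1L, n >= 1L, length(d) == 1L)
  if (d < 1L || d > n)
    stop("need 1 <= d <= n (got d = ", d, ", n = ", n, ")", call. = FALSE)
  if (is.null(gc_counts)) {
    gc_counts <- if (n %% 2L == 0L) n %/% 2L else c(n %/% 2L, n %/% 2L + 1L)
  }
  gc_counts <- sort(unique(as.integer(gc_counts)))
  if (any(gc_counts < 0L | gc_counts > n))
    stop("gc_counts must lie in 0:n", call. = FALSE)
  ns_lengths <- sort(unique(as.integer(ns_lengths)))
  if (ns && !all(ns_lengths %in% c(2L, 3L)))
    stop("ns_lengths must be a subset of c(2, 3)", call. = FALSE)
  structure(list(n = n, d = d, gc_counts = gc_counts, nl = isTRUE(nl),
                 ns = isTRUE(ns), ns_lengths = ns_lengths),
            class = "constraint_profile")
}

#' @export
print.constraint_profile <- function(x, ...) {
  cat(sprintf("DNA coding constraint profile: n = %d, d >= %d\n", x$n, x$d))
  cat("  GC counts allowed:", paste(x$gc_counts, collapse = ", "), "\n")
  cat("  no-runlength:", if (x$nl) "yes" else "no", "\n")
  cat("  non-adjacent subsequence:",
      if (x$ns) paste0("yes (K = ", paste(x$ns_lengths, collapse = ","), ")")
      else "no", "\n")
  invisible(x)
}

#' Single-word feasibility under a constraint profile
#'
#' Conjunction of the intra-word constraints enabled in the profile: GC count
#' in the admissible window, no-runlength if required, and the non-adjacent
#' subsequence constraint if required. (Pairwise Hamming distance is a
#' property of a set, checked by [validate_codeset()].)
#'
#' @param s Character vector of codewords of length `profile$n`.
#' @param profile A [constraint_profile()].
#' @return Logical vector.
#' @export
is_feasible_word <- function(s, profile) {
  stopifnot(inherits(profile, "constraint_profile"))
  if (any(nchar(s) != profile$n))
    stop("word length does not match profile n = ", profile$n, call. = FALSE)
  ok <- vapply(s, function(w) gc_count(w) %in% profile$gc_counts, logical(1),
               USE.NAMES = FALSE)
  if (profile$nl) ok <- ok & satisfies_no_runlength(s)
  if (profile$ns) ok <- ok & satisfies_non_adjacent_subsequence(s, profile$ns_lengths)
  ok
}

#' Validate a coding set against its constraint profile
#'
#' Checks all set invariants: distinct words of the profile's length, every
#' word individually feasible, and every unordered pair at Hamming distance
#' at least `d`. Returns a report rather than throwing, so callers can
#' inspect every violation.
#'
#' @param words Character vector of codewords, or a `dna_codeset`.
#' @param profile A [constraint_profile()]; taken from the codeset if omitted.
#' @return A list of class `codeset_validation` with elements `valid`
#'   (logical) and `violations` (data frame with columns `type`, `word`,
#'   `other`, `detail`).
#' @export
validate_codeset <- function(words, profile = NULL) {
  if (inherits(words, "dna_codeset")) {
    if (is.null(profile)) profile <- words$profile
    words <- words$words
  }
  stopifnot(inherits(profile, "constraint_profile"))
  viol <- list()
  add <- function(type, word, other, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      type = type, word = word, other = other, detail = detail,
      stringsAsFactors = FALSE)
  }
  if (length(words)) {
    if (any(nchar(words) != profile$n)) {
      for (w in words[nchar(words) != profile$n])
        add("length", w, NA_character_, sprintf("length %d != n = %d", nchar(w), profile$n))
    } else {
      dup <- unique(words[duplicated(words)])
      for (w in dup) add("duplicate", w, NA_character_, "word appears more than once")
      feas <- is_feasible_word(words, profile)
      for (w in words[!feas])
        add("infeasible", w, NA_character_, "fails an intra-word constraint")
      if (length(words) > 1L) {
        H <- .hamming_matrix_cpp(words_to_matrix(words))
        idx <- which(upper.tri(H) & H < profile$d, arr.ind = TRUE)
        for (r in seq_len(nrow(idx))) {
          a <- idx[r, 1L]; b <- idx[r, 2L]
          if (words[a] != words[b])  # duplicates already reported
            add("distance", words[a], words[b],
                sprintf("Hamming distance %d < d = %d", H[a, b], profile$d))
          else
            add("distance", words[a], words[b], "duplicate pair at distance 0")
        }
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(type = character(0), word = character(0),
               other = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  structure(list(valid = nrow(violations) == 0L, violations = violations,
                 n_words = length(words), profile = profile),
            class = "codeset_validation")
}

#' @export
print.codeset_validation <- function(x, ...) {
  cat(sprintf("Coding set validation: %d word(s), %s\n", x$n_words,
              if (x$valid) "VALID" else "INVALID"))
  if (!x$valid) {
    cat(sprintf("  %d violation(s):\n", nrow(x$violations)))
    print(utils::head(x$violations, 20L), row.names = FALSE)
    if (nrow(x$violations) > 20L) cat("  ...\n")
  }
  invisible(x)
}

#' Reverse complement of a DNA word
#'
#' @param s Character vector of codewords.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(s) {
  vapply(s, function(w) {
    codes <- word_to_codes(w)
    codes_to_word(rev(3L - codes))
  }, character(1), USE.NAMES = FALSE)
}
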