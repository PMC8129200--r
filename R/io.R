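# Reading/writing codeword sets (FASTA + one-word-per-line text), fixture
# generation for testing, and run manifests for reproducibility.

codeset_ids <- function(k) sprintf("cw_%06d", seq_len(k))

#' Write a coding set to FASTA or line-text
#'
#' FASTA records are wrapped at 60 columns with zero-padded ordinal ids
#' (`cw_000001`, ...); the line dialect writes one word per line. An empty
#' set writes an empty file.
#'
#' @param set A `dna_codeset` or character vector of words.
#' @param file Output path.
#' @param format `"fasta"` or `"lines"`.
#' @return `file`, invisibly.
#' @export
write_codeset <- function(set, file, format = c("fasta", "lines")) {
  format <- match.arg(format)
  words <- if (inherits(set, "dna_codeset")) set$words else as.character(set)
  if (format == "lines") {
    writeLines(words, file)
  } else {
    x <- Biostrings::DNAStringSet(words)
    names(x) <- codeset_ids(length(words))
    Biostrings::writeXStringSet(x, file, width = 60L)
  }
  invisible(file)
}

#' Read a coding set from FASTA or line-text
#'
#' Input is parsed case-insensitively; any symbol outside A/C/G/T (including
#' IUPAC ambiguity codes, U and gaps) is rejected with a record/line
#' diagnostic rather than coerced. The two dialects are auto-detected from
#' the first non-empty character (`>` means FASTA).
#'
#' @param file Input path.
#' @param profile Optional [constraint_profile()] to attach (no validation is
#'   performed here; see [validate_codeset()]).
#' @param format `"auto"`, `"fasta"` or `"lines"`.
#' @return A `dna_codeset` with provenance `"file"` (profile may be `NULL`).
#' @export
read_codeset <- function(file, profile = NULL,
                         format = c("auto", "fasta", "lines")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1L)
    format <- if (length(first) && startsWith(trimws(first), ">")) "fasta"
              else "lines"
  }
  if (format == "fasta") {
    x <- tryCatch(Biostrings::readDNAStringSet(file),
                  error = function(e)
                    stop("malformed FASTA in ", file, ": ",
                         conditionMessage(e), call. = FALSE))
    raw_words <- as.character(x)
    labels <- sprintf("record %d (%s)", seq_along(raw_words), names(x))
  } else {
    raw_words <- readLines(file)
    raw_words <- raw_words[nzchar(trimws(raw_words))]
    labels <- sprintf("line %d", seq_along(raw_words))
  }
  words <- character(length(raw_words))
  for (i in seq_along(raw_words)) {
    w <- toupper(trimws(raw_words[i]))
    bad <- setdiff(strsplit(w, "")[[1]], DNA_BASES)
    if (length(bad))
      stop(sprintf("%s of %s: invalid symbol(s) %s (alphabet is A/C/G/T)",
                   labels[i], file, paste(sQuote(bad), collapse = ", ")),
           call. = FALSE)
    words[i] <- w
  }
  new_dna_codeset(words, profile, "file")
}

#' Generate labelled fixture sequences with planted constraint violations
#'
#' Produces `count` words of length `n` of a requested kind, each verified
#' against the constraint predicates before emission: `"valid"` words pass
#' the whole profile, the violation kinds each fail exactly the advertised
#' predicate, and `"mixed"` alternates valid words and violations. Useful
#' for exercising verification tools end to end.
#'
#' @param kind One of `"valid"`, `"nl_violations"`, `"ns2_violations"`,
#'   `"ns3_violations"`, `"gc_off"`, `"mixed"`.
#' @param n Word length.
#' @param count Number of sequences.
#' @param seed Integer seed (same seed, same file bytes).
#' @param file Optional FASTA output path; record ids carry the planted
#'   status (e.g. `fx_000003|nl_violation`).
#' @param profile Profile defining "valid" (default: balanced GC, NL and NS
#'   on, d ignored here since these are single-word properties).
#' @return Character vector of words (named by their planted status),
#'   invisibly if `file` is given.
#' @export
generate_fixtures <- function(kind = c("valid", "nl_violations",
                                       "ns2_violations", "ns3_violations",
                                       "gc_off", "mixed"),
                              n, count, seed = NULL, file = NULL,
                              profile = constraint_profile(n, 1L, ns = TRUE)) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  min_len <- c(valid = 1L, nl_violations = 2L, ns2_violations = 4L,
               ns3_violations = 6L, gc_off = 1L, mixed = 6L)[[kind]]
  if (n < min_len)
    stop("cannot plant '", kind, "' in words of length ", n, call. = FALSE)

  rand_word <- function() codes_to_word(sample(0:3, n, replace = TRUE))
  draw <- function(pred, label, tries = 10000L) {
    for (i in seq_len(tries)) {
      w <- rand_word()
      if (pred(w)) return(setNames(w, label))
    }
    stop("could not generate a '", label, "' fixture word", call. = FALSE)
  }
  gens <- list(
    valid = function() draw(function(w) is_feasible_word(w, profile), "valid"),
    nl_violations = function()
      draw(function(w) !satisfies_no_runlength(w), "nl_violation"),
    ns2_violations = function()
      draw(function(w) satisfies_no_runlength(w) &&
             !satisfies_non_adjacent_subsequence(w, 2L), "ns2_violation"),
    ns3_violations = function()
      draw(function(w) satisfies_no_runlength(w) &&
             satisfies_non_adjacent_subsequence(w, 2L) &&
             !satisfies_non_adjacent_subsequence(w, 3L), "ns3_violation"),
    gc_off = function()
      draw(function(w) !(gc_count(w) %in% profile$gc_counts), "gc_off"))
  words <- character(count)
  labels <- character(count)
  for (i in seq_len(count)) {
    g <- if (kind == "mixed") {
      if (i %% 2L == 1L) gens$valid else gens[[2L + (i %/% 2L - 1L) %% 4L]]
    } else gens[[kind]]
    w <- g()
    words[i] <- w
    labels[i] <- names(w)
  }
  names(words) <- labels
  if (!is.null(file)) {
    x <- Biostrings::DNAStringSet(unname(words))
    names(x) <- sprintf("fx_%06d|%s", seq_along(words), labels)
    Biostrings::writeXStringSet(x, file, width = 60L)
    return(invisible(words))
  }
  words
}

#' Write a run manifest for reproducibility
#'
#' Records the package version, the command/configuration, the master seed,
#' a timestamp, and the md5 checksum of every emitted artifact, as JSON.
#' Re-running the recorded command with the recorded seed reproduces the
#' stochastic outputs bit-identically.
#'
#' @param path Manifest output path (JSON).
#' @param command Name of the operation (e.g. `"build"`).
#' @param config Named list of resolved configuration values.
#' @param seed Master seed used (may be `NULL`).
#' @param files Character vector of emitted artifact paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config, seed = NULL,
                           files = character(0)) {
  checks <- if (length(files)) as.list(tools::md5sum(files)) else list()
  manifest <- list(
    tool = "clgbo",
    version = as.character(utils::packageVersion("clgbo")),
    command = command,
    config = config,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = checks)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(manifest)
}

#' Serialize a validation or Tm report to JSON
#'
#' @param x A `codeset_validation`, `ns_effect` data frame, or any
#'   JSON-representable list/data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  if (inherits(x, "codeset_validation"))
    x <- list(valid = x$valid, n_words = x$n_words, violations = x$violations)
  if (inherits(x, "ns_effect")) {
    attr(x, "sets") <- NULL
    x <- as.data.frame(unclass(x))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Resolve a run configuration from file and overrides
#'
#' Reads an optional YAML or JSON configuration file, applies the study
#' defaults (population 50, 500 iterations, 30 repeats, `pr = 0.5`,
#' `levy_beta = 1.5`), then applies `overrides` (command-line flags win over
#' the file). Unknown keys and out-of-range values are rejected with a
#' message listing every offender.
#'
#' @param file Optional path to a `.yaml`/`.yml` or `.json` configuration.
#' @param overrides Named list of values taking precedence over the file.
#' @return Named list with the resolved configuration.
#' @export
resolve_config <- function(file = NULL, overrides = list()) {
  defaults <- list(pop_size = 50L, max_iter = 500L, repeats = 30L, pr = 0.5,
                   levy_beta = 1.5, mutation = "both", n = NULL, d = NULL,
                   gc_counts = NULL, nl = TRUE, ns = FALSE, seed = NULL,
                   stall_limit = 20L, plateaus = 20L, plateau_drop = 2L)
  cfg <- defaults
  apply_layer <- function(cfg, layer, origin) {
    unknown <- setdiff(names(layer), names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    cfg[names(layer)] <- layer
    cfg
  }
  if (!is.null(file)) {
    parsed <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE))
      yaml::read_yaml(file)
    else
      jsonlite::read_json(file, simplifyVector = TRUE)
    cfg <- apply_layer(cfg, parsed, file)
  }
  cfg <- apply_layer(cfg, overrides, "overrides")
  bad <- character(0)
  chk <- function(cond, what) if (!isTRUE(cond)) bad <<- c(bad, what)
  chk(cfg$pop_size >= 2, "pop_size must be >= 2")
  chk(cfg$max_iter >= 1, "max_iter must be >= 1")
  chk(cfg$repeats >= 1, "repeats must be >= 1")
  chk(cfg$pr >= 0 && cfg$pr <= 1, "pr must lie in [0, 1]")
  chk(cfg$levy_beta > 0 && cfg$levy_beta <= 2, "levy_beta must lie in (0, 2]")
  chk(cfg$mutation %in% c("both", "cauchy", "levy", "none"),
      "mutation must be both/cauchy/levy/none")
  chk(cfg$stall_limit >= 1, "stall_limit must be >= 1")
  chk(cfg$plateaus >= 1, "plateaus must be >= 1")
  if (!is.null(cfg$n)) chk(cfg$n >= 1, "n must be >= 1")
  if (!is.null(cfg$n) && !is.null(cfg$d))
    chk(cfg$d >= 1 && cfg$d <= cfg$n, "need 1 <= d <= n")
  if (length(bad))
    stop("invalid configuration: ", paste(bad, collapse = "; "),
         call. = FALSE)
  cfg
}
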