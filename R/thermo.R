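# Nearest-neighbor melting temperature and the Tm-variance robustness
# analysis of coding sets built with vs without the tandem-repeat constraint.

#' Nearest-neighbor thermodynamic model for duplex melting
#'
#' Bundles a dinucleotide enthalpy/entropy parameter table with the solution
#' conditions used for the two-state melting-temperature calculation. The
#' default table is the unified oligonucleotide NN parameter set (enthalpies
#' in kcal/mol, entropies in cal/mol/K, referenced to 1 M Na+); an alternate
#' table with the same layout can be loaded from file. Default conditions
#' are total strand concentration 10 nM and 1 M monovalent salt, at which
#' the entropic salt correction `0.368 (n-1) ln[Na+]` vanishes.
#'
#' @param conc Total strand concentration C_T in mol/L (default `1e-8`).
#' @param na Monovalent cation concentration in mol/L (default 1).
#' @param table Path to a tab-separated parameter table with columns
#'   `param`, `dH`, `dS` covering the ten unique duplex steps, the two
#'   terminal initiation penalties (`init_AT`, `init_GC`) and the
#'   self-complementary symmetry term (`sym`). `NULL` loads the packaged
#'   unified table.
#' @return An object of class `thermo_model`.
#' @export
thermo_model <- function(conc = 1e-8, na = 1.0, table = NULL) {
  stopifnot(conc > 0, na > 0)
  if (is.null(table))
    table <- system.file("extdata", "nn_unified.tsv", package = "clgbo",
                         mustWork = TRUE)
  tab <- utils::read.delim(table, stringsAsFactors = FALSE)
  stopifnot(all(c("param", "dH", "dS") %in% names(tab)))
  rownames(tab) <- tab$param
  steps <- c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG")
  missing <- setdiff(c(steps, "init_AT", "init_GC", "sym"), tab$param)
  if (length(missing))
    stop("parameter table lacks entries: ", paste(missing, collapse = ", "),
         call. = FALSE)
  # expand the 10 unique duplex steps to all 16 dinucleotides: a step read on
  # the complementary strand (reverse complement of the dimer) is the same
  # duplex stack
  all_dimers <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  dH <- dS <- setNames(numeric(16L), all_dimers)
  for (dm in all_dimers) {
    key <- if (dm %in% steps) dm else reverse_complement(dm)
    dH[dm] <- tab[key, "dH"]
    dS[dm] <- tab[key, "dS"]
  }
  structure(list(dH = dH, dS = dS,
                 init_AT = unlist(tab["init_AT", c("dH", "dS")]),
                 init_GC = unlist(tab["init_GC", c("dH", "dS")]),
                 sym = unlist(tab["sym", c("dH", "dS")]),
                 conc = conc, na = na, source = table),
            class = "thermo_model")
}

#' @export
print.thermo_model <- function(x, ...) {
  cat("Nearest-neighbor thermodynamic model\n")
  cat(sprintf("  strand concentration: %.3g M, monovalent salt: %.3g M\n",
              x$conc, x$na))
  cat(sprintf("  10 duplex steps, dH range [%.1f, %.1f] kcal/mol\n",
              min(x$dH), max(x$dH)))
  invisible(x)
}

#' Two-state nearest-neighbor melting temperature
#'
#' Tm (in degrees Celsius) of the perfect duplex of each word with its
#' complement: `Tm = 1000 dH / (dS + R ln(C_T / x)) - 273.15`, where dH and
#' dS accumulate the NN stack terms plus terminal initiation penalties, `R =
#' 1.987` cal/mol/K, and the symmetry factor `x` is 4 for
#' non-self-complementary and 1 for self-complementary sequences (whose
#' entropy also receives the symmetry correction). The entropic salt
#' correction `0.368 (n-1) ln[Na+]` is applied, vanishing at the reference
#' 1 M. Tm of a set of address/primer words should be as uniform as possible
#' so one PCR condition melts all duplexes together.
#'
#' @param words Character vector of DNA words (length >= 2 each).
#' @param model A [thermo_model()].
#' @return Numeric vector of melting temperatures in degrees C.
#' @export
melting_temperature <- function(words, model = thermo_model()) {
  stopifnot(inherits(model, "thermo_model"))
  R <- 1.987  # cal/mol/K
  vapply(words, function(w) {
    codes <- word_to_codes(w)
    n <- length(codes)
    if (n < 2L)
      stop("melting temperature needs at least 2 bases (got '", w, "')",
           call. = FALSE)
    w <- codes_to_word(codes)  # normalized to upper case
    dimers <- substring(w, 1:(n - 1L), 2:n)
    dh <- sum(model$dH[dimers])
    ds <- sum(model$dS[dimers])
    for (end in c(substr(w, 1L, 1L), substr(w, n, n))) {
      term <- if (end %in% c("G", "C")) model$init_GC else model$init_AT
      dh <- dh + term[["dH"]]
      ds <- ds + term[["dS"]]
    }
    selfcomp <- identical(w, reverse_complement(w))
    x_sym <- 4
    if (selfcomp) {
      dh <- dh + model$sym[["dH"]]
      ds <- ds + model$sym[["dS"]]
      x_sym <- 1
    }
    ds_corr <- ds + 0.368 * (n - 1L) * log(model$na)
    1000 * dh / (ds_corr + R * log(model$conc / x_sym)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Population variance of melting temperatures across a coding set
#'
#' The dispersion statistic used to score the thermal uniformity of a set:
#' smaller variance means the members denature over a narrower temperature
#' range, reducing non-specific hybridisation during PCR access.
#'
#' @param words Character vector of words, or a `dna_codeset`.
#' @param model A [thermo_model()].
#' @return Population variance (divisor M) of the per-word Tm values, with
#'   the Tm vector in attribute `"tm"`.
#' @export
tm_variance <- function(words, model = thermo_model()) {
  if (inherits(words, "dna_codeset")) words <- words$words
  stopifnot(length(words) >= 1L)
  tm <- melting_temperature(words, model)
  v <- mean((tm - mean(tm))^2)
  attr(v, "tm") <- tm
  v
}

#' Published reference Tm-variance comparison table
#'
#' Reference values from the CLGBO DNA-storage literature: the Tm variance of
#' coding sets constructed with and without the non-adjacent subsequence
#' constraint over a grid of word lengths n = 8..10 and minimum distances
#' d = 3..7 (15 cells). In 14 of the 15 cells the constraint reduces the
#' variance.
#'
#' @return A data frame with columns `n`, `d`, `variance_without_ns`,
#'   `variance_with_ns`.
#' @export
tm_reference_table <- function() {
  utils::read.delim(system.file("extdata", "tm_variance_reference.tsv",
                                package = "clgbo", mustWork = TRUE))
}

#' Effect of the tandem-repeat constraint on Tm uniformity
#'
#' Builds, for each requested minimum distance, one coding set with the
#' non-adjacent subsequence constraint and one without (same seed discipline
#' and budget), computes each set's Tm variance, and reports the paired
#' comparison. A variance drop under the constraint indicates a thermally
#' more uniform, hence more robust, library.
#'
#' @param n Word length.
#' @param d Integer vector of minimum Hamming distances to compare.
#' @param control,stall_limit Passed to [build_codeset()].
#' @param seed Master seed; each (d, constraint) cell derives its own seed
#'   so the paired sets are built under identical conditions.
#' @param model A [thermo_model()].
#' @return An object of class `ns_effect`: a data frame with columns `n`,
#'   `d`, `size_without`, `size_with`, `var_without`, `var_with`, `diff`,
#'   `ratio`, plus the built sets in attribute `"sets"`.
#' @export
ns_effect <- function(n, d, control = clgbo_control(), stall_limit = 20L,
                      seed = NULL, model = thermo_model()) {
  if (!is.null(seed)) set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, length(d))
  rows <- list()
  sets <- list()
  for (i in seq_along(d)) {
    p_no <- constraint_profile(n, d[i], ns = FALSE)
    p_ns <- constraint_profile(n, d[i], ns = TRUE)
    s_no <- build_codeset(p_no, control = control, stall_limit = stall_limit,
                          seed = cell_seeds[i])
    s_ns <- build_codeset(p_ns, control = control, stall_limit = stall_limit,
                          seed = cell_seeds[i])
    v_no <- tm_variance(s_no, model)
    v_ns <- tm_variance(s_ns, model)
    rows[[i]] <- data.frame(
      n = n, d = d[i],
      size_without = length(s_no$words), size_with = length(s_ns$words),
      var_without = as.numeric(v_no), var_with = as.numeric(v_ns),
      diff = as.numeric(v_no) - as.numeric(v_ns),
      ratio = as.numeric(v_ns) / as.numeric(v_no))
    sets[[i]] <- list(without = s_no, with = s_ns)
  }
  out <- do.call(rbind, rows)
  attr(out, "sets") <- sets
  class(out) <- c("ns_effect", class(out))
  out
}

#' @export
print.ns_effect <- function(x, ...) {
  cat("Tm-variance effect of the non-adjacent subsequence constraint\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Bar comparison of Tm variances with and without the constraint
#'
#' @param x An `ns_effect` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.ns_effect <- function(x, ...) {
  m <- t(as.matrix(x[, c("var_without", "var_with")]))
  graphics::barplot(m, beside = TRUE, names.arg = paste0("d=", x$d),
                    legend.text = c("without NS", "with NS"),
                    ylab = "Tm variance", xlab = "minimum Hamming distance",
                    main = sprintf("Tm variance, n = %d", x$n[1]), ...)
  invisible(x)
}
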