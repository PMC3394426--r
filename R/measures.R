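#' @useDynLib abbrsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Recycle two character vectors to a common length, lower-casing both.
# All measures operate on case-normalized strings.
prep_pair <- function(s1, s2) {
  if (anyNA(s1) || anyNA(s2)) stop("string inputs must not contain NA")
  s1 <- tolower(as.character(s1))
  s2 <- tolower(as.character(s2))
  n <- max(length(s1), length(s2))
  if (n > 0 && (n %% length(s1) != 0 || n %% length(s2) != 0))
    stop("s1 and s2 must have compatible lengths")
  list(s1 = rep_len(s1, n), s2 = rep_len(s2, n))
}

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and substitutions
#' needed to transform one string into the other, computed by dynamic
#' programming in O(n1 n2). Inputs are lower-cased before comparison.
#'
#' @param s1,s2 character vectors, recycled to a common length.
#' @return Integer vector of distances.
#' @examples
#' edit_distance("diethylene glycol monoethyl ether",
#'               "diethylene glycol monomethyl ether")  # 1
#' @export
edit_distance <- function(s1, s2) {
  p <- prep_pair(s1, s2)
  edit_distance_cpp(p$s1, p$s2)
}

#' Length-normalized edit distance
#'
#' Levenshtein distance divided by the length of the longer string, mapping
#' into `[0, 1]` so full forms of different lengths are comparable. Two empty
#' strings are identical and get distance 0.
#'
#' @inheritParams edit_distance
#' @return Numeric vector in `[0, 1]`.
#' @export
normalized_edit_distance <- function(s1, s2) {
  p <- prep_pair(s1, s2)
  m <- pmax(nchar(p$s1), nchar(p$s2))
  d <- as.numeric(edit_distance_cpp(p$s1, p$s2))
  ifelse(m == 0, 0, d / m)
}

#' Per-character insertion/deletion weight vector
#'
#' A named numeric vector of 26 non-negative costs, one per letter 'a'..'z',
#' used by [weighted_edit_distance()]. Costs default to 1 (the unweighted
#' case); named arguments override individual letters.
#'
#' @param ... named scalar overrides, e.g. `weight_vector(e = 0.4, h = 0.1)`.
#' @param default cost assigned to letters not overridden.
#' @return Named numeric vector of length 26 with class `"weight_vector"`.
#' @examples
#' w <- weight_vector(e = 0.4)
#' w["e"]
#' @export
weight_vector <- function(..., default = 1) {
  stopifnot(is.numeric(default), length(default) == 1, default >= 0)
  w <- rep(default, 26)
  names(w) <- letters
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!names(over) %in% letters))
      stop("weight overrides must be named with single letters 'a'..'z'")
    vals <- unlist(over)
    if (any(!is.finite(vals)) || any(vals < 0))
      stop("weights must be finite and >= 0")
    w[names(over)] <- vals
  }
  structure(w, class = "weight_vector")
}

as_weight_vector <- function(w) {
  if (inherits(w, "weight_vector")) return(w)
  if (is.numeric(w) && length(w) == 26) {
    if (is.null(names(w))) names(w) <- letters
    stopifnot(identical(names(w), letters), all(is.finite(w)), all(w >= 0))
    return(structure(as.numeric(`names<-`(w, letters)), names = letters,
                     class = "weight_vector"))
  }
  stop("w must be a weight_vector or a numeric vector of 26 letter costs")
}

#' Weighted length-normalized edit distance
#'
#' Like [normalized_edit_distance()], but inserting or deleting a letter `c`
#' in 'a'..'z' costs `w[c]` instead of 1. Substitutions always cost 1 and
#' characters outside 'a'..'z' (spaces, hyphens, digits) always cost 1, since
#' the learned weight vector is defined over the 26 letters only. With all
#' weights equal to 1 the result equals [normalized_edit_distance()] exactly.
#'
#' @inheritParams edit_distance
#' @param w a [weight_vector()] (or named numeric vector of 26 costs).
#' @return Numeric vector of normalized weighted distances.
#' @seealso [optimize_weights()] to learn `w` from labeled candidate pairs.
#' @export
weighted_edit_distance <- function(s1, s2, w = weight_vector()) {
  w <- as_weight_vector(w)
  p <- prep_pair(s1, s2)
  weighted_edit_cpp(p$s1, p$s2, as.numeric(w))
}

#' Parameters of the Monge-Elkan alignment score
#'
#' Character-level score matrix, equivalence classes and affine gap penalty
#' for [monge_elkan()]. The default matrix is \{5, 3, -3\}: 5 for identical
#' characters, 3 for distinct characters in the same equivalence class, -3
#' otherwise, with gap penalty g(k) = alpha + beta * k. The alternative
#' historical matrix \{5, 2, -5\} can be requested via the arguments.
#'
#' @param match_score score for identical characters.
#' @param class_score score for two distinct characters in one equivalence class.
#' @param mismatch_score score for all other character pairs.
#' @param gap_open_alpha,gap_extend_beta affine gap penalty parameters; a gap
#'   of length k costs `gap_open_alpha + gap_extend_beta * k`.
#' @param equivalence_classes list of character vectors of interchangeable
#'   characters; classes must be disjoint.
#' @return A list with class `"monge_elkan_params"`.
#' @export
monge_elkan_params <- function(match_score = 5, class_score = 3,
                               mismatch_score = -3,
                               gap_open_alpha = 5, gap_extend_beta = 1,
                               equivalence_classes = list(
                                 c("d", "t"), c("g", "j"), c("l", "r"),
                                 c("m", "n"), c("b", "p", "v"),
                                 c("a", "e", "i", "o", "u"))) {
  stopifnot(match_score > class_score, class_score > mismatch_score,
            gap_open_alpha >= 0, gap_extend_beta >= 0)
  all_chars <- unlist(equivalence_classes)
  if (anyDuplicated(all_chars))
    stop("equivalence classes must be disjoint")
  structure(list(match_score = match_score, class_score = class_score,
                 mismatch_score = mismatch_score,
                 gap_open_alpha = gap_open_alpha,
                 gap_extend_beta = gap_extend_beta,
                 equivalence_classes = equivalence_classes),
            class = "monge_elkan_params")
}

# byte -> equivalence class id (0 = none), for the C++ kernel
class_lookup <- function(params) {
  lut <- integer(256)
  for (k in seq_along(params$equivalence_classes)) {
    for (ch in params$equivalence_classes[[k]]) {
      lut[utf8ToInt(ch) + 1L] <- k
    }
  }
  lut
}

#' Monge-Elkan alignment similarity
#'
#' Best local (Smith-Waterman style) alignment score of the two strings under
#' a character score matrix with equivalence classes and an affine gap penalty
#' g(k) = alpha + beta k, scaled to `[0, 1]` by dividing by
#' `match_score * min(n1, n2)` and clipping at 0. Identical strings score 1.
#'
#' @inheritParams edit_distance
#' @param params a [monge_elkan_params()] object.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' monge_elkan("dime", "time")  # d~t are in one equivalence class
#' @export
monge_elkan <- function(s1, s2, params = monge_elkan_params()) {
  stopifnot(inherits(params, "monge_elkan_params"))
  p <- prep_pair(s1, s2)
  if (any(nchar(p$s1) == 0) || any(nchar(p$s2) == 0))
    stop("monge_elkan() is undefined for empty strings (scaling denominator)")
  monge_elkan_cpp(p$s1, p$s2, params$match_score, params$class_score,
                  params$mismatch_score, params$gap_open_alpha,
                  params$gap_extend_beta, class_lookup(params))
}

#' Jaro similarity
#'
#' One third of `m/n1 + m/n2 + (m - T)/m`, where `m` counts characters of one
#' string that also occur in the other no farther than `min(n1, n2)/2`
#' positions away, and `T` is half the number of matched characters appearing
#' in a different order. Returns 0 when no characters match.
#'
#' @inheritParams edit_distance
#' @return Numeric vector in `[0, 1]`.
#' @export
jaro <- function(s1, s2) {
  p <- prep_pair(s1, s2)
  jaro_cpp(p$s1, p$s2)
}

#' Jaro-Winkler similarity
#'
#' [jaro()] boosted by the length of the common prefix:
#' `jaro + min(p, 4)/10 * (1 - jaro)` with `p` the number of leading
#' characters the strings share. Always at least the Jaro score and at most 1.
#'
#' @inheritParams edit_distance
#' @return Numeric vector in `[0, 1]`.
#' @export
jaro_winkler <- function(s1, s2) {
  p <- prep_pair(s1, s2)
  jaro_winkler_cpp(p$s1, p$s2)
}

#' Token document frequencies for SoftTFIDF
#'
#' Tokenizes every string on whitespace and records, for each token, the
#' number of strings that contain it (document frequency, not occurrence
#' count), plus the corpus size. These statistics define the IDF term of
#' [soft_tfidf()].
#'
#' @param strings non-empty character vector; the string set S.
#' @return A list with class `"corpus_stats"`: `corpus_size` and a named
#'   integer vector `doc_freq`.
#' @export
build_corpus_stats <- function(strings) {
  if (length(strings) == 0) stop("corpus must contain at least one string")
  if (anyNA(strings)) stop("corpus strings must not be NA")
  strings <- tolower(as.character(strings))
  toks <- strsplit(trimws(strings), "[[:space:]]+")
  tab <- table(unlist(lapply(toks, unique)))
  doc_freq <- as.integer(tab)
  names(doc_freq) <- names(tab)
  structure(list(corpus_size = length(strings), doc_freq = doc_freq),
            class = "corpus_stats")
}

tokenize <- function(s) {
  t <- strsplit(trimws(tolower(s)), "[[:space:]]+")[[1]]
  t[nzchar(t)]
}

# L2-normalized log-TF * log-IDF weights for the distinct tokens of one string.
# Unseen tokens fall back to doc_freq = 1; tokens present in every corpus
# string have IDF = 1, hence log IDF = 0 and zero weight.
v_weights <- function(tokens, stats) {
  tab <- table(tokens)
  tf <- as.numeric(tab)
  dfq <- stats$doc_freq[names(tab)]
  dfq[is.na(dfq)] <- 1L
  idf <- stats$corpus_size / as.numeric(dfq)
  raw <- log(tf + 1) * log(idf)
  nrm <- sqrt(sum(raw^2))
  v <- if (nrm > 0) raw / nrm else raw
  names(v) <- names(tab)
  v
}

#' SoftTFIDF similarity
#'
#' Token-level TF-IDF cosine similarity in which tokens of the two strings are
#' matched approximately: a token w of `s1` contributes when some token of
#' `s2` has Jaro-Winkler similarity at least `a` to it, and the contribution
#' is `V(w, s1) * V(w*, s2) * max_jw`, where `w*` is the most similar token of
#' `s2` and V is the L2-normalized `log(TF + 1) * log(IDF)` weight under the
#' corpus statistics `stats` (natural logarithms). Self-similarity is 1
#' whenever some token of the string has positive IDF weight.
#'
#' @inheritParams edit_distance
#' @param stats a [build_corpus_stats()] object over the string set S.
#' @param a secondary-similarity cutoff in (0, 1]; tokens closer than `a`
#'   under Jaro-Winkler are considered matching. Default 0.9.
#' @return Numeric vector of non-negative similarities.
#' @export
soft_tfidf <- function(s1, s2, stats, a = 0.9) {
  stopifnot(inherits(stats, "corpus_stats"), is.numeric(a), length(a) == 1,
            a > 0, a <= 1)
  p <- prep_pair(s1, s2)
  vapply(seq_along(p$s1), function(i) {
    t1 <- tokenize(p$s1[i])
    t2 <- tokenize(p$s2[i])
    if (length(t1) == 0 || length(t2) == 0)
      stop("soft_tfidf() requires at least one token per string")
    v1 <- v_weights(t1, stats)
    v2 <- v_weights(t2, stats)
    u2 <- names(v2)
    total <- 0
    for (w in names(v1)) {
      sims <- jaro_winkler_cpp(rep(w, length(u2)), u2)
      k <- which.max(sims)
      if (sims[k] >= a)
        total <- total + v1[[w]] * v2[[u2[k]]] * sims[k]
    }
    total
  }, numeric(1))
}

#' Character n-gram Dice coefficient
#'
#' `2 * c_n / (n1 + n2)`, where `c_n` is the multiset intersection count of
#' length-`n` substrings of the two strings (each occurrence can match at most
#' once) and `n1`, `n2` are the character lengths. Bigrams (`n = 2`) are the
#' default. Because the denominator uses character lengths rather than n-gram
#' counts, identical strings of length L score `2(L - n + 1) / (2L) < 1`; the
#' conventional n-gram-count denominator is available via
#' `denominator = "ngram"`.
#'
#' @inheritParams edit_distance
#' @param n n-gram length, a positive integer (default 2).
#' @param denominator `"length"` for `n1 + n2` (default) or `"ngram"` for the
#'   standard count of n-grams in both strings.
#' @return Numeric vector in `[0, 1]`; 0 when either string is shorter than `n`.
#' @examples
#' ngram_dice("night", "nacht")  # only "ht" shared: 2/10
#' @export
ngram_dice <- function(s1, s2, n = 2, denominator = c("length", "ngram")) {
  denominator <- match.arg(denominator)
  if (!is.numeric(n) || length(n) != 1 || n != as.integer(n) || n <= 0)
    stop("n must be a positive integer")
  p <- prep_pair(s1, s2)
  ngram_dice_cpp(p$s1, p$s2, as.integer(n), denominator == "length")
}
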