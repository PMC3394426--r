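# Independent direct-definition oracles. These deliberately avoid the
# package's dynamic-programming kernels: edit distances come from memoized
# recursion over edit scripts, alignment scores from explicit enumeration of
# all alignment column sets, and the token measures from naive definitional
# recomputation.

chars_of <- function(s) if (nchar(s) == 0) character(0) else strsplit(s, "")[[1]]

# recursive Levenshtein (memoized); unit costs
oracle_edit <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  ca <- chars_of(a); cb <- chars_of(b)
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- min(rec(i - 1, j) + 1,
             rec(i, j - 1) + 1,
             rec(i - 1, j - 1) + (ca[i] != cb[j]))
    memo[[key]] <- v
    v
  }
  as.integer(rec(length(ca), length(cb)))
}

# recursive minimum-cost edit script with per-letter insertion/deletion costs
oracle_weighted_edit <- function(a, b, w) {
  memo <- new.env(parent = emptyenv())
  ca <- chars_of(a); cb <- chars_of(b)
  cost <- function(ch) if (ch %in% letters) w[[ch]] else 1
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- Inf
    if (i > 0) v <- min(v, rec(i - 1, j) + cost(ca[i]))
    if (j > 0) v <- min(v, rec(i, j - 1) + cost(cb[j]))
    if (i > 0 && j > 0) v <- min(v, rec(i - 1, j - 1) + (ca[i] != cb[j]))
    memo[[key]] <- v
    v
  }
  raw <- rec(length(ca), length(cb))
  m <- max(length(ca), length(cb))
  if (m == 0) 0 else raw / m
}

# exhaustive local alignment: enumerate every increasing set of aligned
# column pairs, charge affine penalties for internal gaps, take the maximum
oracle_monge_elkan <- function(a, b, params = monge_elkan_params()) {
  ca <- chars_of(a); cb <- chars_of(b)
  n1 <- length(ca); n2 <- length(cb)
  stopifnot(n1 > 0, n2 > 0)
  cls <- function(ch) {
    for (k in seq_along(params$equivalence_classes))
      if (ch %in% params$equivalence_classes[[k]]) return(k)
    0L
  }
  char_score <- function(x, y) {
    if (x == y) return(params$match_score)
    kx <- cls(x)
    if (kx != 0L && kx == cls(y)) params$class_score else params$mismatch_score
  }
  gap <- function(len) {
    len <- len[len > 0]
    if (length(len) == 0) 0
    else sum(params$gap_open_alpha + params$gap_extend_beta * len)
  }
  best <- 0
  for (k in seq_len(min(n1, n2))) {
    I_sets <- utils::combn(n1, k, simplify = FALSE)
    J_sets <- utils::combn(n2, k, simplify = FALSE)
    for (I in I_sets) for (J in J_sets) {
      s <- sum(mapply(char_score, ca[I], cb[J]))
      s <- s - gap(diff(I) - 1) - gap(diff(J) - 1)
      if (s > best) best <- s
    }
  }
  min(1, best / (params$match_score * min(n1, n2)))
}

# naive Jaro: window scan per the definition, transpositions from matched
# subsequences
oracle_jaro <- function(a, b) {
  ca <- chars_of(a); cb <- chars_of(b)
  n1 <- length(ca); n2 <- length(cb)
  if (n1 == 0 || n2 == 0) return(0)
  win <- floor(min(n1, n2) / 2)
  used <- rep(FALSE, n2)
  ma <- character(0)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      if (!used[j] && abs(i - j) <= win && ca[i] == cb[j]) {
        used[j] <- TRUE
        ma <- c(ma, ca[i])
        break
      }
    }
  }
  m <- length(ma)
  if (m == 0) return(0)
  mb <- cb[used]
  t_half <- sum(ma != mb) / 2
  (m / n1 + m / n2 + (m - t_half) / m) / 3
}

oracle_jaro_winkler <- function(a, b) {
  jr <- oracle_jaro(a, b)
  ca <- chars_of(a); cb <- chars_of(b)
  p <- 0
  for (i in seq_len(min(length(ca), length(cb)))) {
    if (ca[i] != cb[i]) break
    p <- p + 1
  }
  jr + (min(p, 4) / 10) * (1 - jr)
}

# naive SoftTFIDF: TF, IDF, L2-normalized V and the max-similarity pairing
# recomputed by direct enumeration, with oracle_jaro_winkler as the
# secondary similarity
oracle_soft_tfidf <- function(a, b, corpus, cutoff = 0.9) {
  toks <- function(s) {
    t <- strsplit(trimws(tolower(s)), "[[:space:]]+")[[1]]
    t[nzchar(t)]
  }
  corpus_toks <- lapply(corpus, toks)
  doc_freq <- function(w) {
    n <- sum(vapply(corpus_toks, function(tt) w %in% tt, logical(1)))
    max(n, 1)
  }
  vfun <- function(tt) {
    u <- unique(tt)
    raw <- vapply(u, function(w) {
      tf <- sum(tt == w)
      idf <- length(corpus) / doc_freq(w)
      log(tf + 1) * log(idf)
    }, numeric(1))
    nrm <- sqrt(sum(raw^2))
    v <- if (nrm > 0) raw / nrm else raw
    names(v) <- u
    v
  }
  t1 <- toks(a); t2 <- toks(b)
  v1 <- vfun(t1); v2 <- vfun(t2)
  total <- 0
  for (w in names(v1)) {
    sims <- vapply(names(v2), function(w2) oracle_jaro_winkler(w, w2),
                   numeric(1))
    k <- which.max(sims)
    if (sims[k] >= cutoff)
      total <- total + v1[[w]] * v2[[names(v2)[k]]] * sims[[k]]
  }
  unname(total)
}

# naive n-gram Dice: explicit substring lists, greedy capped matching
oracle_ngram_dice <- function(a, b, n = 2, length_denominator = TRUE) {
  grams <- function(s) {
    if (nchar(s) < n) return(character(0))
    vapply(seq_len(nchar(s) - n + 1), function(i) substr(s, i, i + n - 1),
           character(1))
  }
  g1 <- grams(a); g2 <- grams(b)
  if (length(g1) == 0 || length(g2) == 0) return(0)
  used <- rep(FALSE, length(g2))
  c_n <- 0
  for (x in g1) {
    hit <- which(!used & g2 == x)
    if (length(hit) > 0) {
      used[hit[1]] <- TRUE
      c_n <- c_n + 1
    }
  }
  denom <- if (length_denominator) nchar(a) + nchar(b)
           else length(g1) + length(g2)
  2 * c_n / denom
}

# all strings over an alphabet up to a maximum length
enumerate_strings <- function(alphabet, max_len, include_empty = TRUE) {
  out <- if (include_empty) "" else character(0)
  cur <- ""
  for (len in seq_len(max_len)) {
    cur <- as.vector(outer(cur, alphabet, paste0))
    out <- c(out, cur)
  }
  out
}

random_strings <- function(n, alphabet, max_len = 8, min_len = 0) {
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# brute-force evaluation-layer oracles -------------------------------------

# best F over all distinct thresholds (plus the all-predicted set) by direct
# confusion-matrix recomputation
oracle_best_f <- function(scores, gold, direction) {
  thr <- if (direction == "distance") c(sort(unique(scores)), max(scores) + 1)
         else c(min(scores) - 1, sort(unique(scores)))
  rows <- lapply(thr, function(t) {
    pred <- if (direction == "distance") scores < t else scores > t
    tp <- sum(pred & gold)
    p <- if (sum(pred) > 0) tp / sum(pred) else 0
    r <- if (sum(gold) > 0) tp / sum(gold) else 0
    f <- if (p > 0 && r > 0) 2 * p * r / (p + r) else 0
    c(threshold = t, precision = p, recall = r, f_measure = f,
      n_predicted = sum(pred))
  })
  m <- do.call(rbind, rows)
  best <- which(m[, "f_measure"] == max(m[, "f_measure"]))
  pick <- if (direction == "distance") best[which.min(m[best, "threshold"])]
          else best[which.max(m[best, "threshold"])]
  m[pick, ]
}

# prefix-scan PR points, tie-grouped by score
oracle_pr_curve <- function(scores, gold, direction) {
  ord <- order(if (direction == "distance") scores else -scores)
  s <- scores[ord]; g <- gold[ord]
  pts <- list()
  for (i in seq_along(s)) {
    if (i < length(s) && s[i + 1] == s[i]) next
    tp <- sum(g[1:i])
    pts[[length(pts) + 1]] <- c(recall = tp / sum(gold), precision = tp / i,
                                n_selected = i)
  }
  do.call(rbind, pts)
}

# all-prefix scan for the fixed-recall rule (ties -> smaller prefix)
oracle_threshold_at_recall <- function(scores, gold, direction, target) {
  ord <- order(if (direction == "distance") scores else -scores)
  s <- scores[ord]; g <- gold[ord]
  n_pos <- sum(g)
  rec <- c(0, cumsum(g) / n_pos)
  i <- which.min(abs(rec - target)) - 1
  tp <- if (i > 0) sum(g[1:i]) else 0
  c(threshold = if (i > 0) s[i] else NA_real_,
    precision = if (i > 0) tp / i else 0,
    recall = tp / n_pos, n_selected = i)
}

# small deterministic candidate-pair fixture with controllable scores
make_scored_pairs <- function(scores, gold, direction = "distance") {
  d <- data.frame(abbreviation = "ab",
                  full_form_1 = sprintf("left %03d", seq_along(scores)),
                  full_form_2 = sprintf("right %03d", seq_along(scores)),
                  concept_id_1 = "c1",
                  concept_id_2 = ifelse(gold, "c1", "c2"),
                  is_chemical = FALSE,
                  gold = gold, score = scores,
                  stringsAsFactors = FALSE)
  attr(d, "direction") <- direction
  d
}
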