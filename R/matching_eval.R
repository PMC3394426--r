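#' Candidate pairs from A-pair records
#'
#' Every two A-pairs (abbreviation, full form) sharing the same abbreviation
#' are candidates for denoting the same concept: an abbreviation group of size
#' k yields k(k-1)/2 unordered candidate pairs. The gold label is concept-ID
#' equality of the two full forms. Output order is deterministic: rows are
#' sorted by abbreviation, then by the two full forms.
#'
#' @param apairs data frame with columns `abbreviation`, `full_form`,
#'   `concept_id` and (optionally) `is_chemical`, as returned by
#'   [generate_dataset()] or [read_apairs()].
#' @return Data frame of candidate pairs with columns `abbreviation`,
#'   `full_form_1`, `full_form_2`, `concept_id_1`, `concept_id_2`,
#'   `is_chemical` (NA when the two sides disagree), `gold` (logical) and
#'   `score` (NA until filled by [score_pairs()]).
#' @export
generate_candidates <- function(apairs) {
  stopifnot(is.data.frame(apairs),
            all(c("abbreviation", "full_form", "concept_id") %in% names(apairs)))
  if (nrow(apairs) == 0) return(empty_candidates())
  has_chem <- "is_chemical" %in% names(apairs)
  ap <- apairs[order(apairs$abbreviation, apairs$full_form, apairs$concept_id), ,
               drop = FALSE]
  groups <- split(seq_len(nrow(ap)), ap$abbreviation)
  out <- lapply(groups, function(idx) {
    k <- length(idx)
    if (k < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    i <- cmb[1, ]; j <- cmb[2, ]
    chem <- if (has_chem) {
      ifelse(ap$is_chemical[i] == ap$is_chemical[j], ap$is_chemical[i], NA)
    } else NA
    data.frame(abbreviation = ap$abbreviation[i],
               full_form_1 = ap$full_form[i],
               full_form_2 = ap$full_form[j],
               concept_id_1 = ap$concept_id[i],
               concept_id_2 = ap$concept_id[j],
               is_chemical = as.logical(chem),
               gold = ap$concept_id[i] == ap$concept_id[j],
               score = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(empty_candidates())))
  out <- out[order(out$abbreviation, out$full_form_1, out$full_form_2), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(abbreviation = character(), full_form_1 = character(),
             full_form_2 = character(), concept_id_1 = character(),
             concept_id_2 = character(), is_chemical = logical(),
             gold = logical(), score = numeric(), stringsAsFactors = FALSE)
}

#' Available similarity measures
#'
#' @return Character vector of measure identifiers accepted by
#'   [score_pairs()].
#' @export
measure_names <- function() {
  c("edit", "weighted_edit", "monge_elkan", "soft_tfidf", "bigram_dice")
}

#' Direction of a measure's scale
#'
#' Edit distances predict a match below a threshold; the other measures above
#' one.
#'
#' @param measure a measure identifier from [measure_names()].
#' @return `"distance"` or `"similarity"`.
#' @export
measure_direction <- function(measure) {
  measure <- match.arg(measure, measure_names())
  if (measure %in% c("edit", "weighted_edit")) "distance" else "similarity"
}

#' Score candidate pairs with one similarity measure
#'
#' Fills the `score` column by applying the chosen measure to the two full
#' forms of every candidate pair; input order is preserved. For
#' `"soft_tfidf"` the corpus statistics default to the set union of all full
#' forms appearing in `pairs`.
#'
#' @param pairs candidate-pair data frame from [generate_candidates()].
#' @param measure one of [measure_names()].
#' @param w weight vector for `"weighted_edit"` (default unit weights).
#' @param params [monge_elkan_params()] for `"monge_elkan"`.
#' @param stats [build_corpus_stats()] object for `"soft_tfidf"`; built from
#'   the pairs' full forms when NULL.
#' @param a SoftTFIDF secondary-similarity cutoff.
#' @param n n-gram length for `"bigram_dice"`.
#' @param denominator Dice denominator convention, see [ngram_dice()].
#' @return `pairs` with `score` filled, plus attributes `measure` and
#'   `direction`.
#' @export
score_pairs <- function(pairs, measure = measure_names(),
                        w = weight_vector(), params = monge_elkan_params(),
                        stats = NULL, a = 0.9, n = 2,
                        denominator = "length") {
  measure <- match.arg(measure)
  stopifnot(is.data.frame(pairs),
            all(c("full_form_1", "full_form_2") %in% names(pairs)))
  f1 <- pairs$full_form_1
  f2 <- pairs$full_form_2
  pairs$score <- if (nrow(pairs) == 0) numeric(0) else switch(measure,
    edit = normalized_edit_distance(f1, f2),
    weighted_edit = weighted_edit_distance(f1, f2, w),
    monge_elkan = monge_elkan(f1, f2, params),
    soft_tfidf = {
      if (is.null(stats)) stats <- build_corpus_stats(unique(c(f1, f2)))
      soft_tfidf(f1, f2, stats, a)
    },
    bigram_dice = ngram_dice(f1, f2, n, denominator))
  attr(pairs, "measure") <- measure
  attr(pairs, "direction") <- measure_direction(measure)
  pairs
}

direction_of <- function(pairs, direction = NULL) {
  if (!is.null(direction)) return(match.arg(direction, c("distance", "similarity")))
  d <- attr(pairs, "direction")
  if (is.null(d)) stop("direction not given and pairs carry no direction attribute")
  d
}

check_scored <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("gold", "score") %in% names(pairs)))
  if (nrow(pairs) > 0 && anyNA(pairs$score))
    stop("all candidate pairs must be scored; run score_pairs() first")
}

#' Precision, recall and F-measure at one threshold
#'
#' Predicts a match for `score < threshold` (distance measures) or
#' `score > threshold` (similarity measures) -- strict inequalities -- and
#' compares against the gold labels. Precision is 0 when nothing is
#' predicted; recall is 0 when there are no gold positives; F is the harmonic
#' mean, or 0 when either component is 0.
#'
#' @param pairs scored candidate pairs.
#' @param threshold numeric cutoff.
#' @param direction `"distance"` or `"similarity"`; taken from the `pairs`
#'   attribute set by [score_pairs()] when omitted.
#' @return One-row data frame: `threshold`, `precision`, `recall`,
#'   `f_measure`, `n_predicted`.
#' @export
evaluate_at <- function(pairs, threshold, direction = NULL) {
  check_scored(pairs)
  direction <- direction_of(pairs, direction)
  pred <- if (direction == "distance") pairs$score < threshold
          else pairs$score > threshold
  tp <- sum(pred & pairs$gold)
  prf(threshold, tp, n_pred = sum(pred), n_pos = sum(pairs$gold))
}

prf <- function(threshold, tp, n_pred, n_pos) {
  precision <- if (n_pred > 0) tp / n_pred else 0
  recall <- if (n_pos > 0) tp / n_pos else 0
  f <- if (precision > 0 && recall > 0)
    2 * precision * recall / (precision + recall) else 0
  data.frame(threshold = threshold, precision = precision, recall = recall,
             f_measure = f, n_predicted = n_pred)
}

#' Threshold grids
#'
#' `"coarse"` is 0 to 1 in steps of 0.05; `"fine"` is 0.900 to 0.995 in steps
#' of 0.005 (used for SoftTFIDF, whose informative range is compressed near
#' 1); `"observed"` uses every distinct score in the data as a candidate
#' cutoff, plus one sentinel beyond the loosest score so that the
#' all-predicted operating point is reachable under the strict inequality.
#'
#' @param pairs scored candidate pairs (needed for `"observed"`).
#' @param grid `"coarse"`, `"fine"`, `"observed"`, or a numeric vector of
#'   thresholds.
#' @param direction `"distance"` or `"similarity"` (for the sentinel side).
#' @return Sorted numeric vector of thresholds.
#' @export
threshold_grid <- function(grid = "coarse", pairs = NULL, direction = NULL) {
  if (is.numeric(grid)) {
    if (length(grid) == 0) stop("threshold grid must be non-empty")
    return(sort(grid))
  }
  grid <- match.arg(grid, c("coarse", "fine", "observed"))
  if (grid == "coarse") return(seq(0, 1, by = 0.05))
  if (grid == "fine") return(seq(0.900, 0.995, by = 0.005))
  check_scored(pairs)
  direction <- direction_of(pairs, direction)
  s <- sort(unique(pairs$score))
  if (length(s) == 0) stop("observed grid requires scored pairs")
  if (direction == "distance") c(s, max(s) + 1) else c(min(s) - 1, s)
}

#' Threshold sweep
#'
#' Evaluates precision, recall and F-measure at every threshold of a grid.
#'
#' @inheritParams evaluate_at
#' @param grid see [threshold_grid()].
#' @return Data frame with one [evaluate_at()] row per threshold, ascending.
#' @export
sweep_thresholds <- function(pairs, direction = NULL, grid = "coarse") {
  check_scored(pairs)
  direction <- direction_of(pairs, direction)
  thr <- threshold_grid(grid, pairs, direction)
  s_all <- sort(pairs$score)
  s_pos <- sort(pairs$score[pairs$gold])
  n <- length(s_all)
  n_pos <- length(s_pos)
  if (direction == "distance") {
    # strict '<': number of elements strictly below each threshold
    n_pred <- findInterval(thr, s_all, left.open = TRUE)
    tp <- findInterval(thr, s_pos, left.open = TRUE)
  } else {
    # strict '>': total minus number of elements <= threshold
    n_pred <- n - findInterval(thr, s_all)
    tp <- n_pos - findInterval(thr, s_pos)
  }
  precision <- ifelse(n_pred > 0, tp / n_pred, 0)
  recall <- if (n_pos > 0) tp / n_pos else rep(0, length(thr))
  f <- ifelse(precision > 0 & recall > 0,
              2 * precision * recall / (precision + recall), 0)
  data.frame(threshold = thr, precision = precision, recall = recall,
             f_measure = f, n_predicted = n_pred)
}

#' Best-F point of a sweep
#'
#' Returns the sweep row with the highest F-measure. Ties are broken toward
#' the stricter threshold: the smaller one for distance measures, the larger
#' one for similarity measures.
#'
#' @param sweep data frame from [sweep_thresholds()].
#' @param direction `"distance"` or `"similarity"`.
#' @return One-row data frame.
#' @export
best_threshold <- function(sweep, direction) {
  direction <- match.arg(direction, c("distance", "similarity"))
  stopifnot(is.data.frame(sweep), nrow(sweep) > 0)
  best <- which(sweep$f_measure == max(sweep$f_measure))
  pick <- if (direction == "distance") best[which.min(sweep$threshold[best])]
          else best[which.max(sweep$threshold[best])]
  out <- sweep[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-F point over the observed-score grid
#'
#' Convenience wrapper: sweeps every distinct score value as a threshold and
#' returns the maximizing point.
#'
#' @inheritParams evaluate_at
#' @return One-row data frame as in [best_threshold()].
#' @export
best_f_point <- function(pairs, direction = NULL) {
  direction <- direction_of(pairs, direction)
  best_threshold(sweep_thresholds(pairs, direction, "observed"), direction)
}

# Deterministic best-score-first ordering used by pr_curve() and
# threshold_at_recall(): by score (ascending for distance, descending for
# similarity), ties by abbreviation and the two full forms.
rank_pairs <- function(pairs, direction) {
  key <- if (direction == "distance") pairs$score else -pairs$score
  aux1 <- if ("abbreviation" %in% names(pairs)) pairs$abbreviation else ""
  aux2 <- if ("full_form_1" %in% names(pairs)) pairs$full_form_1 else ""
  aux3 <- if ("full_form_2" %in% names(pairs)) pairs$full_form_2 else ""
  order(key, aux1, aux2, aux3)
}

#' Precision-recall curve
#'
#' Sorts pairs best-score-first and emits one (recall, precision) point per
#' prefix. Pairs with tied scores are grouped into one point so that every
#' point on the curve corresponds to a realizable threshold.
#'
#' @inheritParams evaluate_at
#' @return Data frame with columns `score`, `recall`, `precision`,
#'   `n_selected`.
#' @export
pr_curve <- function(pairs, direction = NULL) {
  check_scored(pairs)
  direction <- direction_of(pairs, direction)
  n_pos <- sum(pairs$gold)
  if (n_pos == 0) stop("pr_curve() requires at least one gold-positive pair")
  ord <- rank_pairs(pairs, direction)
  s <- pairs$score[ord]
  g <- pairs$gold[ord]
  cum_tp <- cumsum(g)
  idx <- seq_along(s)
  last_of_tier <- idx[!duplicated(s, fromLast = TRUE)]
  data.frame(score = s[last_of_tier],
             recall = cum_tp[last_of_tier] / n_pos,
             precision = cum_tp[last_of_tier] / last_of_tier,
             n_selected = last_of_tier)
}

# prefix-selection scan shared by threshold_at_recall() and
# compare_split_vs_mixed(); returns the chosen prefix size and its counts
prefix_at_recall <- function(pairs, direction, target_recall) {
  check_scored(pairs)
  n_pos <- sum(pairs$gold)
  if (n_pos == 0) stop("fixed-recall selection requires gold-positive pairs")
  stopifnot(target_recall > 0, target_recall <= 1)
  ord <- rank_pairs(pairs, direction)
  g <- pairs$gold[ord]
  recall_i <- c(0, cumsum(g) / n_pos)          # prefixes i = 0 .. N
  i <- which.min(abs(recall_i - target_recall)) - 1L
  tp <- if (i > 0) sum(g[seq_len(i)]) else 0L
  list(i = i, tp = tp, n_pos = n_pos,
       threshold = if (i > 0) pairs$score[ord][i] else NA_real_,
       selected = ord[seq_len(i)])
}

#' Threshold achieving a target recall
#'
#' Sorts pairs best-score-first and, over all prefixes i = 0..N, picks the one
#' whose recall is closest to `target_recall` (ties go to the smaller
#' prefix). The reported threshold is the score of the last selected pair.
#'
#' @inheritParams evaluate_at
#' @param target_recall desired recall in (0, 1].
#' @return One-row data frame: `threshold`, `precision`, `recall`,
#'   `n_selected`.
#' @export
threshold_at_recall <- function(pairs, target_recall, direction = NULL) {
  direction <- direction_of(pairs, direction)
  sel <- prefix_at_recall(pairs, direction, target_recall)
  data.frame(threshold = sel$threshold,
             precision = if (sel$i > 0) sel$tp / sel$i else 0,
             recall = sel$tp / sel$n_pos,
             n_selected = sel$i)
}

#' Split versus single-threshold matching at a fixed recall
#'
#' Compares two matching strategies for a corpus divided into chemical and
#' non-chemical full forms: (a) selecting a separate fixed-recall threshold
#' for each subset and pooling the two prediction sets ("split"), versus (b)
#' one threshold chosen on the concatenated set ("mixed"). Both use the
#' prefix-selection rule of [threshold_at_recall()]. The pooled ("all") row
#' evaluates the union of the two per-subset selections against the pooled
#' gold labels.
#'
#' @param chemical_pairs,other_pairs candidate pairs scored with the same
#'   measure.
#' @param target_recall recall to fix, default 0.8.
#' @param direction `"distance"` or `"similarity"`; taken from the pairs'
#'   attributes when omitted.
#' @return Data frame with rows `chemical`, `other`, `all`, `mixed` and
#'   columns `subset`, `threshold`, `precision`, `recall`, `n_selected`.
#' @export
compare_split_vs_mixed <- function(chemical_pairs, other_pairs,
                                   target_recall = 0.8, direction = NULL) {
  direction <- direction_of(chemical_pairs, direction)
  if (nrow(chemical_pairs) == 0 || sum(chemical_pairs$gold) == 0)
    stop("chemical subset has no gold-positive pairs")
  if (nrow(other_pairs) == 0 || sum(other_pairs$gold) == 0)
    stop("non-chemical subset has no gold-positive pairs")
  chem <- prefix_at_recall(chemical_pairs, direction, target_recall)
  oth <- prefix_at_recall(other_pairs, direction, target_recall)
  pool_tp <- chem$tp + oth$tp
  pool_n <- chem$i + oth$i
  pool_pos <- chem$n_pos + oth$n_pos
  mixed_pairs <- rbind(chemical_pairs[names(other_pairs)], other_pairs)
  mix <- prefix_at_recall(mixed_pairs, direction, target_recall)
  row <- function(subset, sel) {
    data.frame(subset = subset, threshold = sel$threshold,
               precision = if (sel$i > 0) sel$tp / sel$i else 0,
               recall = sel$tp / sel$n_pos, n_selected = sel$i)
  }
  out <- rbind(
    row("chemical", chem),
    row("other", oth),
    data.frame(subset = "all", threshold = NA_real_,
               precision = if (pool_n > 0) pool_tp / pool_n else 0,
               recall = pool_tp / pool_pos, n_selected = pool_n),
    row("mixed", mix))
  rownames(out) <- NULL
  out
}
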