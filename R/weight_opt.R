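#' Coordinate-descent learning of insertion/deletion weights
#'
#' Learns the 26 per-letter insertion/deletion costs of
#' [weighted_edit_distance()] on a labeled candidate-pair set. Starting from
#' all weights 1, the letters 'a'..'z' are visited once in alphabetical
#' order; for each letter, every candidate value on the grid
#' `seq(value_range[1], value_range[2], by = grid_step)` (plus the incumbent
#' value) is tried while all other weights stay fixed, each candidate is
#' scored by rescoring every pair and taking the best F-measure over the
#' observed-threshold sweep, and the best candidate is fixed before moving
#' on. Ties go to the value closest to 1 (then to the larger value), so the
#' optimizer does not drift on flat regions. Because the incumbent value is
#' always among the candidates, the best F-measure is non-decreasing along
#' the trace.
#'
#' @param pairs candidate pairs with gold labels (scores are recomputed
#'   internally); must contain at least one gold-positive pair.
#' @param grid_step spacing of candidate weight values, default 0.1.
#' @param value_range lower and upper bounds of the search, default `c(0, 1)`.
#' @return A list with class `"weight_opt"`: `weights` (a [weight_vector()]),
#'   `trace` (data frame with one row per letter: `character`, `best_weight`,
#'   `best_f`, `threshold`) and `candidates` (per-letter data frames of every
#'   value examined with its F-measure).
#' @export
optimize_weights <- function(pairs, grid_step = 0.1, value_range = c(0, 1)) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0,
            all(c("full_form_1", "full_form_2", "gold") %in% names(pairs)),
            is.numeric(grid_step), grid_step > 0,
            length(value_range) == 2, value_range[1] >= 0,
            value_range[2] >= value_range[1])
  if (sum(pairs$gold) == 0)
    stop("weight optimization requires at least one gold-positive pair")
  f1 <- tolower(pairs$full_form_1)
  f2 <- tolower(pairs$full_form_2)
  gold <- pairs$gold
  w <- weight_vector()
  grid_vals <- seq(value_range[1], value_range[2], by = grid_step)

  eval_w <- function(wv) {
    sc <- weighted_edit_cpp(f1, f2, as.numeric(wv))
    scored <- data.frame(gold = gold, score = sc)
    best_threshold(sweep_thresholds(scored, "distance", "observed"), "distance")
  }

  trace <- vector("list", 26)
  cand_log <- vector("list", 26)
  for (k in seq_along(letters)) {
    ch <- letters[k]
    vals <- sort(unique(c(grid_vals, w[[ch]])))
    fs <- numeric(length(vals))
    thr <- numeric(length(vals))
    for (v in seq_along(vals)) {
      wv <- w
      wv[[ch]] <- vals[v]
      pt <- eval_w(wv)
      fs[v] <- pt$f_measure
      thr[v] <- pt$threshold
    }
    top <- which(fs == max(fs))
    # ties: closest to 1.0, then the larger value
    top <- top[order(abs(vals[top] - 1), -vals[top])][1]
    w[[ch]] <- vals[top]
    trace[[k]] <- data.frame(character = ch, best_weight = vals[top],
                             best_f = fs[top], threshold = thr[top])
    cand_log[[k]] <- data.frame(character = ch, value = vals, f_measure = fs)
  }
  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL
  structure(list(weights = w, trace = trace, candidates = cand_log),
            class = "weight_opt")
}

#' Best-F operating point of a weight vector
#'
#' Rescores all candidate pairs with [weighted_edit_distance()] under `w` and
#' returns the best-F point of the observed-threshold sweep.
#'
#' @param pairs candidate pairs with gold labels.
#' @param w a [weight_vector()].
#' @return One-row data frame as in [best_threshold()].
#' @export
evaluate_weight_vector <- function(pairs, w = weight_vector()) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0)
  scored <- score_pairs(pairs, "weighted_edit", w = w)
  best_f_point(scored, "distance")
}

#' Write / read a weight vector as two-column TSV
#'
#' The on-disk format is 26 lines of `character<TAB>weight` plus a header.
#'
#' @param w a [weight_vector()].
#' @param path file path.
#' @return `write_weight_vector()` returns `path` invisibly;
#'   `read_weight_vector()` returns a [weight_vector()].
#' @export
write_weight_vector <- function(w, path) {
  w <- as_weight_vector(w)
  utils::write.table(data.frame(character = names(w), weight = as.numeric(w)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_vector
#' @export
read_weight_vector <- function(path) {
  d <- utils::read.delim(path, colClasses = c("character", "numeric"))
  stopifnot(identical(sort(d$character), letters))
  w <- d$weight[match(letters, d$character)]
  names(w) <- letters
  as_weight_vector(w)
}
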