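#' Best log-odds motif match score per sequence
#'
#' Scores every window of every sequence, on both strands, with the
#' log-odds `sum_j log(pwm[b_j, j] / M1(b_j))` and returns each sequence's
#' maximum. PWM entries are floored at a small positive value before the
#' log so indicator columns stay finite.
#'
#' @param seqs A `DNAStringSet`.
#' @param motif A `motif_result`.
#' @param model A `markov_background` supplying the `M1` base frequencies.
#' @param floor Minimum PWM entry (default 1e-4).
#' @return Numeric vector of per-sequence best scores (named after the
#'   sequences); `-Inf` for sequences shorter than the motif.
#' @export
scan_best_score <- function(seqs, motif, model, floor = 1e-4) {
  pwm <- pmax(motif$pwm, floor)
  L <- ncol(pwm)
  lodds <- log(pwm / as.numeric(model$M1[rownames(pwm)]))
  strands <- sequence_strands(seqs)
  score_string <- function(s, l) {
    if (l < L) return(-Inf)
    code <- match(strsplit(s, "", fixed = TRUE)[[1]], BASES)  # N -> NA
    n_win <- l - L + 1L
    total <- numeric(n_win)
    for (j in seq_len(L)) {
      col <- lodds[code[j:(j + n_win - 1L)], j]
      col[is.na(col)] <- -Inf                     # windows containing N
      total <- total + col
    }
    max(total)
  }
  best <- vapply(seq_along(strands$fwd), function(i) {
    max(score_string(strands$fwd[i], strands$len[i]),
        score_string(strands$rev[i], strands$len[i]))
  }, numeric(1))
  stats::setNames(best, strands$ids)
}

#' Threshold maximising accuracy
#'
#' Scans all candidate thresholds (the unique scores) and returns the
#' smallest one achieving maximal accuracy of `score >= threshold` against
#' the labels. Deterministic for fixed input.
#'
#' @param labels Logical vector (`TRUE` = positive).
#' @param scores Numeric vector of the same length.
#' @return The selected threshold.
#' @export
choose_threshold_acc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  cand <- sort(unique(scores[is.finite(scores)]))
  if (length(cand) == 0L) return(Inf)
  acc <- vapply(cand, function(th) mean((scores >= th) == labels), numeric(1))
  cand[which.max(acc)]
}

#' Classification metrics for sequence-level motif prediction
#'
#' Computes precision `TP/(TP+FP)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/N` at the given threshold (`score >= threshold` predicts
#' positive), and AUPRC by step-wise (interpolation-free) summation over
#' all score thresholds. When no positive is predicted, precision is
#' returned as 0 with attribute `zero_division = TRUE`. With a single
#' class present AUPRC is undefined: a warning is raised and `NA` returned
#' for it, while the threshold metrics are still computed.
#'
#' @param labels Logical vector (`TRUE` = positive).
#' @param scores Numeric vector of per-sequence scores.
#' @param threshold Decision threshold (e.g. from
#'   [choose_threshold_acc()]).
#' @return List with `precision`, `specificity`, `acc`, `auprc`.
#' @export
classification_metrics <- function(labels, scores, threshold) {
  stopifnot(length(labels) == length(scores), is.logical(labels))
  if (anyNA(scores)) stop("scores must not contain NA")
  pred <- scores >= threshold
  tp <- sum(pred & labels)
  fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels)
  fn <- sum(!pred & labels)
  precision <- if (tp + fp == 0) structure(0, zero_division = TRUE)
               else tp / (tp + fp)
  specificity <- if (tn + fp == 0) structure(0, zero_division = TRUE)
                 else tn / (tn + fp)
  acc <- (tp + tn) / length(labels)
  auprc <- if (all(labels) || all(!labels)) {
    warning("AUPRC undefined: only one class present")
    NA_real_
  } else {
    auprc_step(labels, scores)
  }
  list(precision = precision, specificity = specificity, acc = acc,
       auprc = auprc)
}

# step-wise average precision: sum over descending-score cutpoints of
# (recall increment) * (precision at that cutpoint); ties processed jointly
auprc_step <- function(labels, scores) {
  ord <- order(-scores)
  labels <- labels[ord]
  scores <- scores[ord]
  n_pos <- sum(labels)
  cum_tp <- cumsum(labels)
  cum_pp <- seq_along(labels)
  last_of_tie <- c(scores[-1] != scores[-length(scores)], TRUE)
  tp <- cum_tp[last_of_tie]
  pp <- cum_pp[last_of_tie]
  prec <- tp / pp
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Write a metrics table as TSV
#'
#' @param metrics List from [classification_metrics()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  df <- data.frame(metric = c("precision", "specificity", "acc", "auprc"),
                   value = c(as.numeric(metrics$precision),
                             as.numeric(metrics$specificity),
                             metrics$acc, metrics$auprc))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
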