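# Signal novelty filtration: partition positive disproportionality signals
# into labeled (on the drug label), unlabeled published (only in the
# literature) and potentially new (in neither), with the label taking
# precedence over the literature. Evaluation helpers compute
# precision/recall/F-measure against a gold term set and the two-rater
# Cohen's kappa for manual review agreement.

#' Classify positive signals against label and literature term sets
#'
#' A signal is `labeled` when its code is in the label term set, else
#' `unlabeled_published` when in the literature set, else `new`.
#' Membership is evaluated on the signal's PT code and - because mined
#' term sets legitimately contain SOC-level terms - falls back to any SOC
#' linked to that PT when the PT itself is absent; such assignments are
#' flagged as level-relaxed via `matched_via = "soc"`.
#'
#' @param signals positive signal event codes (vector, [term_set()], or a
#'   [detect_signals()] frame, from which positive rows are taken).
#' @param label_terms [term_set()] mined from drug labels.
#' @param literature_terms [term_set()] mined from the literature.
#' @param h optional hierarchy enabling the SOC fallback.
#' @param relax_level disable the SOC fallback by setting `FALSE`.
#' @return an object of class `signal_classification`: `assignments`
#'   (data frame `event_code`, `category`, `matched_via`), `counts` and
#'   integer `percentages` per category, and `total`.
#' @export
classify_signals <- function(signals, label_terms, literature_terms,
                             h = NULL, relax_level = TRUE) {
  if (inherits(signals, "signal_results")) {
    signals <- signals$event_code[signals$positive]
  }
  codes <- unique(term_codes(signals))
  if (!length(codes)) {
    stop("usage error: empty signal set", call. = FALSE)
  }
  lab <- unique(term_codes(label_terms))
  lit <- unique(term_codes(literature_terms))

  in_set <- function(code, set) {
    if (code %in% set) return("pt")
    if (relax_level && !is.null(h)) {
      lv <- term_level(h, code)
      if (!is.na(lv) && lv == "PT" &&
          any(socs_for_pt(h, code) %in% set)) {
        return("soc")
      }
    }
    NA_character_
  }

  category <- character(length(codes))
  matched_via <- character(length(codes))
  for (k in seq_along(codes)) {
    via <- in_set(codes[k], lab)
    if (!is.na(via)) {
      category[k] <- "labeled"; matched_via[k] <- via
      next
    }
    via <- in_set(codes[k], lit)
    if (!is.na(via)) {
      category[k] <- "unlabeled_published"; matched_via[k] <- via
    } else {
      category[k] <- "new"; matched_via[k] <- ""
    }
  }

  lv <- c("labeled", "unlabeled_published", "new")
  counts <- table(factor(category, levels = lv))
  structure(list(
    assignments = data.frame(event_code = codes, category = category,
                             matched_via = matched_via),
    counts = stats::setNames(as.integer(counts), lv),
    percentages = stats::setNames(
      as.integer(round(100 * as.integer(counts) / length(codes))), lv),
    total = length(codes)
  ), class = "signal_classification")
}

#' @export
print.signal_classification <- function(x, ...) {
  cat("<signal_classification> ", x$total, " signals: ", sep = "")
  cat(paste(sprintf("%d %s (%d%%)", x$counts, names(x$counts),
                    x$percentages), collapse = ", "), "\n")
  invisible(x)
}

#' Precision / recall / F-measure from raw counts
#'
#' Precision = 100*TP/(TP+FP), recall = 100*TP/(TP+FN), F = 2PR/(P+R), all
#' on the percentage scale. A zero denominator leaves the metric absent
#' (`NA`), never silently zero.
#'
#' @param tp,fp,fn non-negative counts.
#' @return an object of class `metrics_report`.
#' @examples
#' metrics_from_counts(389, 101, 32)
#' @export
metrics_from_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f_measure = f),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.1f", v)
  cat(sprintf("<metrics_report> TP=%d FP=%d FN=%d  P=%s%% R=%s%% F=%s%%\n",
              x$tp, x$fp, x$fn, fmt(x$precision), fmt(x$recall),
              fmt(x$f_measure)))
  invisible(x)
}

#' Evaluate a predicted term set against a gold standard
#'
#' TP = predicted terms in the gold set, FP = predicted terms outside it,
#' FN = gold terms missed. Both sets should already be normalized to the
#' same level (PT or higher).
#'
#' @param predicted,gold [term_set()]s (or plain code vectors); `gold`
#'   must be non-empty.
#' @return a [metrics_from_counts()] report.
#' @export
evaluate_terms <- function(predicted, gold) {
  p <- unique(term_codes(predicted))
  g <- unique(term_codes(gold))
  if (!length(g)) stop("usage error: empty gold set", call. = FALSE)
  tp <- length(intersect(p, g))
  metrics_from_counts(tp, fp = length(p) - tp, fn = length(g) - tp)
}

#' Cohen's kappa from a 2x2 agreement table
#'
#' Two raters, two categories. `n11` counts items both raters marked
#' positive, `n00` items both marked negative, `n10`/`n01` the
#' disagreements. kappa = (p_o - p_e)/(1 - p_e); when the expected
#' agreement p_e is 1 (both raters constant) kappa is flagged undefined.
#'
#' @param n11,n10,n01,n00 agreement-table counts.
#' @return an object of class `kappa_result`: the table, `p_o`, `p_e`,
#'   `kappa`, `undefined`.
#' @export
kappa_from_table <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  if (n < 2) stop("usage error: kappa needs at least 2 items", call. = FALSE)
  p_o <- (n11 + n00) / n
  p_a1 <- (n11 + n10) / n
  p_b1 <- (n11 + n01) / n
  p_e <- p_a1 * p_b1 + (1 - p_a1) * (1 - p_b1)
  undefined <- isTRUE(all.equal(p_e, 1))
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 p_o = p_o, p_e = p_e,
                 kappa = if (undefined) NA_real_ else (p_o - p_e) / (1 - p_e),
                 undefined = undefined),
            class = "kappa_result")
}

#' Cohen's kappa for two binary raters
#'
#' @param ratings_a,ratings_b logical vectors over the same items; when
#'   named, `ratings_b` is aligned to the names of `ratings_a` (the item
#'   sets must then be identical).
#' @return a [kappa_from_table()] result.
#' @examples
#' cohens_kappa(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE, FALSE))
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  stopifnot(is.logical(ratings_a), is.logical(ratings_b),
            length(ratings_a) == length(ratings_b))
  if (!is.null(names(ratings_a)) && !is.null(names(ratings_b))) {
    if (!setequal(names(ratings_a), names(ratings_b))) {
      stop("usage error: raters must rate identical item sets", call. = FALSE)
    }
    ratings_b <- ratings_b[names(ratings_a)]
  }
  kappa_from_table(sum(ratings_a & ratings_b),
                   sum(ratings_a & !ratings_b),
                   sum(!ratings_a & ratings_b),
                   sum(!ratings_a & !ratings_b))
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$undefined) {
    cat("<kappa_result> undefined (expected agreement = 1)\n")
  } else {
    cat(sprintf("<kappa_result> kappa=%.2f (p_o=%.3f, p_e=%.3f)\n",
                x$kappa, x$p_o, x$p_e))
  }
  invisible(x)
}

#' Write a signal classification as TSV
#'
#' Joins the classification with the signal table and writes columns
#' `event_code event_name ror ci_low ci_high category matched_via`, ranked
#' by descending ROR.
#'
#' @param classification a [classify_signals()] result.
#' @param signals the [detect_signals()] frame the codes came from.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_classification_tsv <- function(classification, signals, path) {
  stopifnot(inherits(classification, "signal_classification"))
  sig <- as.data.frame(signals)
  m <- merge(classification$assignments, sig[, c("event_code", "event_name",
                                                 "ror", "ci_low", "ci_high")],
             by = "event_code", all.x = TRUE)
  m <- m[order(is.na(m$ror), -ifelse(is.na(m$ror), 0, m$ror), m$event_code), ]
  out <- data.frame(event_code = m$event_code, event_name = m$event_name,
                    ror = sprintf("%.2f", m$ror),
                    ci_low = sprintf("%.2f", m$ci_low),
                    ci_high = sprintf("%.2f", m$ci_high),
                    category = m$category, matched_via = m$matched_via)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
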