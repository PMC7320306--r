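# Reporting odds ratio disproportionality. For an exposure concept set and
# an event, reports are cross-classified in the 2x2 table
#
#                with event   without event
#   exposed          a             b
#   unexposed        c             d
#
# ROR = (a*d)/(b*c), with a Woolf log-normal 95% CI
# exp(ln ROR +/- z*sqrt(1/a + 1/b + 1/c + 1/d)).  A signal is positive when
# the exposed-with-event report count a >= 3 and the CI lower bound
# exceeds 1.

#' 2x2 contingency table of report counts
#'
#' @param a exposed reports with the event.
#' @param b exposed reports without the event.
#' @param c unexposed reports with the event.
#' @param d unexposed reports without the event.
#' @param event_code,level optional event annotation.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, event_code = NA_integer_,
                              level = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0)) {
    stop("contingency_table: cells must be non-negative counts", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d,
                 event_code = event_code, level = level),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> a=%g b=%g c=%g d=%g (n=%g)\n",
              x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d))
  invisible(x)
}

#' Build the 2x2 table for one drug-event pair
#'
#' At PT level a report "has" the event iff the PT code is among its
#' events. At SOC level it has the event iff any of its PT events links
#' (primary or secondary) to that SOC; a report with several PTs under the
#' same SOC still contributes one count. Every report falls in exactly one
#' cell, so the cells always sum to the store size.
#'
#' @param store a [build_store()] case store.
#' @param exposure non-empty vector of ingredient concept ids.
#' @param event_code a PT code (`level = "PT"`) or SOC code
#'   (`level = "SOC"`).
#' @param level counting level.
#' @param h hierarchy; required for SOC level and for level validation.
#' @return a [contingency_table()].
#' @export
build_contingency <- function(store, exposure, event_code,
                              level = c("PT", "SOC"), h = NULL) {
  level <- match.arg(level)
  event_code <- as.integer(event_code)
  if (!is.null(h)) {
    lv <- term_level(h, event_code)
    if (is.na(lv) || lv != level) {
      stop("usage error: event code ", event_code, " is not a ", level,
           call. = FALSE)
    }
  }
  exposed <- query_reports(store, exposure)
  with_event <- if (level == "PT") {
    unique(store$events$primaryid[store$events$pt_code == event_code])
  } else {
    if (is.null(h)) {
      stop("usage error: SOC-level counting requires the hierarchy",
           call. = FALSE)
    }
    pts <- h$pt_links$pt_code[h$pt_links$soc_code == event_code]
    unique(store$events$primaryid[store$events$pt_code %in% pts])
  }
  a <- sum(with_event %in% exposed)
  b <- length(exposed) - a
  c <- length(with_event) - a
  d <- store$n_total - a - b - c
  contingency_table(a, b, c, d, event_code = event_code, level = level)
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' Any zero cell leaves the interval (and ROR) undefined; the result then
#' carries the table untouched and is flagged, never silently corrected.
#' Callers wanting a Haldane-style correction opt in through the
#' `continuity` flag of [detect_signals()].
#'
#' @param table a [contingency_table()] or any list with elements
#'   `a`, `b`, `c`, `d`.
#' @param z normal quantile for the interval (default `1.959964`, the
#'   two-sided 95% level).
#' @return an object of class `ror_result`: `ror`, `ci_low`, `ci_high`,
#'   `defined` flag and the input `table`.
#' @examples
#' compute_ror(contingency_table(6, 4, 3, 8))
#' @export
compute_ror <- function(table, z = 1.959964) {
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (any(c(a, b, c, d) == 0)) {
    return(structure(list(ror = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, defined = FALSE,
                          table = table, z = z), class = "ror_result"))
  }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  structure(list(ror = ror,
                 ci_low = exp(log(ror) - z * se),
                 ci_high = exp(log(ror) + z * se),
                 defined = TRUE, table = table, z = z),
            class = "ror_result")
}

#' @export
print.ror_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("ROR %.2f (95%% CI %.2f-%.2f)%s\n", x$ror, x$ci_low,
                x$ci_high,
                if (is_positive(x)) "  [positive signal]" else ""))
  } else {
    cat("ROR undefined (zero cell in the 2x2 table)\n")
  }
  invisible(x)
}

#' Positivity rule for a disproportionality result
#'
#' A signal is positive iff the exposed-with-event report count is at least
#' 3 and the 95% CI lower bound strictly exceeds 1. An undefined interval
#' is never positive.
#'
#' @param r a [compute_ror()] result.
#' @return logical.
#' @export
is_positive <- function(r) {
  stopifnot(inherits(r, "ror_result"))
  isTRUE(r$defined) && r$table$a >= 3 && r$ci_low > 1
}

woolf_ci <- function(a, b, c, d, z) {
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror, lo = exp(log(ror) - z * se), hi = exp(log(ror) + z * se))
}

#' Scan a case store for disproportionality signals
#'
#' Computes one result per event code observed in at least one exposed
#' report, at PT or SOC level, sorted by descending ROR (ties by ascending
#' event code). With `continuity = TRUE`, tables containing a zero cell get
#' 0.5 added to every cell before the ROR/CI computation and are flagged
#' `corrected`; the reported cells `a`-`d` always stay uncorrected, and the
#' positivity rule always evaluates the uncorrected `a`.
#'
#' @param store a [build_store()] case store.
#' @param exposure non-empty vector of ingredient concept ids (a drug class
#'   pools naturally; a single drug is a singleton set).
#' @param h a [load_meddra()] hierarchy.
#' @param level `"PT"` or `"SOC"`.
#' @param continuity opt-in 0.5 continuity correction for zero-cell tables.
#' @param z normal quantile for the interval.
#' @return a data frame of class `signal_results` with columns
#'   `event_code`, `event_name`, `level`, `a`, `b`, `c`, `d`, `ror`,
#'   `ci_low`, `ci_high`, `positive`, `corrected`.
#' @export
detect_signals <- function(store, exposure, h, level = c("PT", "SOC"),
                           continuity = FALSE, z = 1.959964) {
  level <- match.arg(level)
  stopifnot(inherits(store, "case_store"), inherits(h, "meddra_hierarchy"))
  exposed <- query_reports(store, exposure)

  ev <- store$events
  if (level == "SOC") {
    m <- merge(ev, h$pt_links[, c("pt_code", "soc_code")], by = "pt_code")
    ev <- unique(data.frame(primaryid = m$primaryid, code = m$soc_code))
  } else {
    ev <- unique(data.frame(primaryid = ev$primaryid, code = ev$pt_code))
  }

  empty <- data.frame(event_code = integer(), event_name = character(),
                      level = character(), a = numeric(), b = numeric(),
                      c = numeric(), d = numeric(), ror = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      positive = logical(), corrected = logical())
  if (!length(exposed) || !nrow(ev)) {
    return(structure(empty, class = c("signal_results", "data.frame")))
  }

  ev$exposed <- ev$primaryid %in% exposed
  codes <- sort(unique(ev$code[ev$exposed]))
  if (!length(codes)) {
    return(structure(empty, class = c("signal_results", "data.frame")))
  }

  n_with <- table(factor(ev$code, levels = codes))
  a <- as.numeric(table(factor(ev$code[ev$exposed], levels = codes)))
  n_with <- as.numeric(n_with)
  nE <- length(exposed)
  n <- store$n_total
  b <- nE - a
  c <- n_with - a
  d <- n - nE - c

  corrected <- rep(FALSE, length(codes))
  aa <- a; bb <- b; cc <- c; dd <- d
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (continuity && any(zero)) {
    aa[zero] <- a[zero] + 0.5; bb[zero] <- b[zero] + 0.5
    cc[zero] <- c[zero] + 0.5; dd[zero] <- d[zero] + 0.5
    corrected[zero] <- TRUE
  }
  defined <- aa > 0 & bb > 0 & cc > 0 & dd > 0
  ror <- ci_low <- ci_high <- rep(NA_real_, length(codes))
  if (any(defined)) {
    w <- woolf_ci(aa[defined], bb[defined], cc[defined], dd[defined], z)
    ror[defined] <- w$ror
    ci_low[defined] <- w$lo
    ci_high[defined] <- w$hi
  }
  positive <- !is.na(ci_low) & a >= 3 & ci_low > 1

  out <- data.frame(event_code = codes,
                    event_name = term_name(h, codes),
                    level = level, a = a, b = b, c = c, d = d,
                    ror = ror, ci_low = ci_low, ci_high = ci_high,
                    positive = positive, corrected = corrected)
  out <- out[order(is.na(out$ror), -ifelse(is.na(out$ror), 0, out$ror),
                   out$event_code), ]
  rownames(out) <- NULL
  structure(out, class = c("signal_results", "data.frame"))
}

#' Write a signal table as TSV
#'
#' Columns `event_code event_name level a b c d ror ci_low ci_high positive
#' corrected`, with ROR and CI bounds formatted to 2 decimals.
#'
#' @param signals a [detect_signals()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_signals_tsv <- function(signals, path) {
  out <- as.data.frame(signals)
  for (col in c("ror", "ci_low", "ci_high")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.2f", out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
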