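# CDM-lite case store: read FAERS-dialect report tables, deduplicate cases
# to their latest version, map verbatim drug names to standard concepts,
# normalize event codes to MedDRA PT level, and serve standardized
# drug-exposure queries. Three logical tables (report, exposure, event)
# stand in for the full common data model; the analysis only ever touches
# these.

faers_table_spec <- list(
  demo = list(file = "demo.txt",
              columns = c("primaryid", "caseid", "caseversion", "sex"),
              mandatory = c("primaryid", "caseid", "caseversion")),
  drug = list(file = "drug.txt",
              columns = c("primaryid", "drugname"),
              mandatory = c("primaryid", "drugname")),
  reac = list(file = "reac.txt",
              columns = c("primaryid", "meddra_code"),
              mandatory = c("primaryid", "meddra_code"))
)

read_faers_file <- function(path, spec) {
  if (!file.exists(path)) {
    stop("FAERS load error: missing file ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) {
    stop("format error in ", basename(path), ": empty file (header required)",
         call. = FALSE)
  }
  header <- tolower(trimws(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  missing_cols <- setdiff(spec$columns, header)
  if (length(missing_cols)) {
    stop("format error in ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  idx <- match(spec$columns, header)
  mand <- match(spec$mandatory, spec$columns)

  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  n_read <- length(body)
  if (!n_read) {
    df <- as.data.frame(matrix(character(), 0, length(spec$columns)))
    names(df) <- spec$columns
    return(list(rows = df, n_read = 0L, n_malformed = 0L))
  }
  parts <- strsplit(body, "$", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) >= max(idx) && all(nzchar(trimws(p[idx[mand]])))
  }, logical(1))
  rows <- do.call(rbind, lapply(parts[ok], function(p) trimws(p[idx])))
  df <- as.data.frame(rows)
  names(df) <- spec$columns
  list(rows = df, n_read = n_read, n_malformed = sum(!ok))
}

#' Read FAERS-dialect report tables
#'
#' Reads `demo.txt`, `drug.txt` and `reac.txt` from a directory. Files are
#' "$"-delimited with a mandatory header line:
#' `primaryid$caseid$caseversion$sex$`, `primaryid$drugname$` and
#' `primaryid$meddra_code$` respectively. Verbatim fields are preserved;
#' malformed rows (missing mandatory fields, non-numeric case versions or
#' event codes) are counted and reported, never silently dropped.
#'
#' @param dir directory containing the three tables.
#' @return an object of class `faers_raw`: data frames `demo`, `drug`,
#'   `reac` plus a `load` list of row/malformed counts.
#' @export
read_faers_tables <- function(dir) {
  raw <- lapply(faers_table_spec, function(spec) {
    read_faers_file(file.path(dir, spec$file), spec)
  })

  demo <- raw$demo$rows
  n_bad_demo <- raw$demo$n_malformed
  if (nrow(demo)) {
    ver <- suppressWarnings(as.integer(demo$caseversion))
    bad <- is.na(ver) | ver < 0
    n_bad_demo <- n_bad_demo + sum(bad)
    demo <- demo[!bad, , drop = FALSE]
    demo$caseversion <- ver[!bad]
  } else {
    demo$caseversion <- integer(0)
  }

  reac <- raw$reac$rows
  n_bad_reac <- raw$reac$n_malformed
  if (nrow(reac)) {
    code <- suppressWarnings(as.integer(reac$meddra_code))
    bad <- is.na(code) | code <= 0
    n_bad_reac <- n_bad_reac + sum(bad)
    reac <- reac[!bad, , drop = FALSE]
    reac$meddra_code <- code[!bad]
  } else {
    reac$meddra_code <- integer(0)
  }

  if (raw$drug$n_read == 0L) {
    warning("drug.txt contains no exposure rows", call. = FALSE)
  }

  structure(list(
    demo = demo, drug = raw$drug$rows, reac = reac,
    load = list(
      demo_rows_read = raw$demo$n_read,
      drug_rows_read = raw$drug$n_read,
      reac_rows_read = raw$reac$n_read,
      demo_rows_malformed = n_bad_demo,
      drug_rows_malformed = raw$drug$n_malformed,
      reac_rows_malformed = n_bad_reac,
      duplicates_removed = 0L
    ),
    deduplicated = FALSE
  ), class = "faers_raw")
}

#' Deduplicate cases to their latest version
#'
#' For each `caseid` only the rows with the maximum `caseversion` are kept;
#' remaining ties are broken by the lexicographically greatest `primaryid`.
#' Exact duplicate demographic rows collapse to one, and drug/reaction rows
#' belonging to discarded report versions are removed. Idempotent.
#'
#' @param raw a [read_faers_tables()] object.
#' @return the same object with duplicates removed and
#'   `load$duplicates_removed` updated.
#' @export
deduplicate_cases <- function(raw) {
  stopifnot(inherits(raw, "faers_raw"))
  demo <- unique(raw$demo)
  if (nrow(demo)) {
    # latest version per caseid, ties -> greatest primaryid
    ord <- order(demo$caseid, -demo$caseversion,
                 -xtfrm(demo$primaryid))
    demo <- demo[ord, , drop = FALSE]
    demo <- demo[!duplicated(demo$caseid), , drop = FALSE]
    demo <- demo[order(demo$caseid), , drop = FALSE]
    rownames(demo) <- NULL
  }
  removed <- nrow(raw$demo) - nrow(demo)
  raw$demo <- demo
  raw$drug <- unique(raw$drug[raw$drug$primaryid %in% demo$primaryid, ,
                              drop = FALSE])
  raw$reac <- unique(raw$reac[raw$reac$primaryid %in% demo$primaryid, ,
                              drop = FALSE])
  rownames(raw$drug) <- rownames(raw$reac) <- NULL
  raw$load$duplicates_removed <- raw$load$duplicates_removed + removed
  raw$deduplicated <- TRUE
  raw
}

#' Build a standardized case store
#'
#' The ETL end point: deduplicates (if not already done), maps verbatim
#' drug names to ingredient concept ids, normalizes reaction codes to PT
#' level via the MedDRA hierarchy, and drops (while counting) reports left
#' with zero mappable events. Reaction codes may arrive at LLT or PT level;
#' codes unknown to the hierarchy, or at HLT/SOC level, are counted as
#' unmappable and excluded.
#'
#' @param raw a [read_faers_tables()] object (deduplicated or not).
#' @param lexicon a [drug_lexicon()].
#' @param h a [load_meddra()] hierarchy.
#' @return an object of class `case_store` with data frames `reports`
#'   (`primaryid`, `caseid`, `case_version`, `sex`), `exposures`
#'   (`primaryid`, `verbatim`, `concept_id`), `events` (`primaryid`,
#'   `pt_code`), the report count `n_total` and a `load_report` list of
#'   conservation counts.
#' @export
build_store <- function(raw, lexicon, h) {
  stopifnot(inherits(raw, "faers_raw"), inherits(h, "meddra_hierarchy"))
  if (!isTRUE(raw$deduplicated)) raw <- deduplicate_cases(raw)

  demo <- raw$demo
  sex <- toupper(trimws(demo$sex))
  sex[!(sex %in% c("F", "M"))] <- "UNK"

  mapped <- map_drug_names(raw$drug$drugname, lexicon)
  exposures <- data.frame(primaryid = raw$drug$primaryid,
                          verbatim = mapped$verbatim,
                          concept_id = mapped$concept_id)

  reac <- raw$reac
  lv <- term_level(h, reac$meddra_code)
  mappable <- !is.na(lv) & lv %in% c("LLT", "PT")
  n_unmappable <- sum(!mappable)
  events <- if (any(mappable)) {
    norm <- normalize_to_pt(h, reac$meddra_code[mappable])
    unique(data.frame(primaryid = reac$primaryid[mappable],
                      pt_code = norm$code))
  } else {
    data.frame(primaryid = character(), pt_code = integer())
  }

  keep <- demo$primaryid %in% events$primaryid
  n_zero_event <- sum(!keep)
  reports <- data.frame(primaryid = demo$primaryid[keep],
                        caseid = demo$caseid[keep],
                        case_version = demo$caseversion[keep],
                        sex = sex[keep])
  rownames(reports) <- NULL
  exposures <- exposures[exposures$primaryid %in% reports$primaryid, ,
                         drop = FALSE]
  events <- events[events$primaryid %in% reports$primaryid, , drop = FALSE]
  rownames(exposures) <- rownames(events) <- NULL

  load_report <- raw$load
  load_report$unmapped_drugs <- sum(is.na(exposures$concept_id))
  load_report$unmappable_events <- n_unmappable
  load_report$zero_event_reports_dropped <- n_zero_event
  load_report$n_total <- nrow(reports)

  structure(list(reports = reports, exposures = exposures, events = events,
                 n_total = nrow(reports), load_report = load_report),
            class = "case_store")
}

#' @export
print.case_store <- function(x, ...) {
  cat("<case_store> ", x$n_total, " reports, ", nrow(x$exposures),
      " exposure rows (", sum(is.na(x$exposures$concept_id)), " unmapped), ",
      nrow(x$events), " PT events\n", sep = "")
  invisible(x)
}

#' Standardized drug-exposure query
#'
#' Returns the ids of reports with at least one exposure whose mapped
#' concept id is in `drug_concepts`. Each report is counted once regardless
#' of how many matching drug rows it has, so pooling a drug class is just a
#' larger concept set.
#'
#' @param store a [build_store()] case store.
#' @param drug_concepts non-empty vector of ingredient concept ids.
#' @return sorted character vector of report `primaryid`s.
#' @export
query_reports <- function(store, drug_concepts) {
  stopifnot(inherits(store, "case_store"))
  if (!length(drug_concepts)) {
    stop("usage error: drug_concepts must be non-empty", call. = FALSE)
  }
  e <- store$exposures
  hit <- !is.na(e$concept_id) & e$concept_id %in% as.integer(drug_concepts)
  sort(unique(e$primaryid[hit]))
}

#' Write the ETL load report
#'
#' Two-column TSV of the conservation counts tracked through the ETL:
#' rows read and malformed per table, duplicates removed, unmapped drug
#' names, unmappable event codes, zero-event reports dropped, and the final
#' store size.
#'
#' @param store a [build_store()] case store.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_load_report <- function(store, path) {
  stopifnot(inherits(store, "case_store"))
  rep <- store$load_report
  df <- data.frame(metric = names(rep), value = unlist(rep, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
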