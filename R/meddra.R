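# MedDRA-dialect dictionary: term levels, LLT->PT normalization, PT->SOC
# links with a primary-SOC designation, and the surface-form lexicon used by
# the text miner. The on-disk dialect mirrors the shape of the MedDRA ASCII
# distribution ("$"-delimited record files) so a licensed dictionary can be
# dropped in with a thin adapter.

#' Read a "$"-delimited record file
#'
#' One record per line, fields separated by `$`, trailing `$` tolerated.
#' Rows with fewer than `n_fields` non-empty fields are counted as malformed
#' and excluded.
#'
#' @param path file path.
#' @param n_fields number of mandatory leading fields.
#' @return list with `records` (character matrix, possibly 0-row) and
#'   `n_malformed` (count of excluded rows).
#' @keywords internal
#' @noRd
read_dollar_records <- function(path, n_fields) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(list(records = matrix(character(), 0, n_fields), n_malformed = 0L))
  }
  parts <- strsplit(lines, "$", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) >= n_fields && all(nzchar(trimws(p[seq_len(n_fields)])))
  }, logical(1))
  records <- if (any(ok)) {
    do.call(rbind, lapply(parts[ok], function(p) trimws(p[seq_len(n_fields)])))
  } else {
    matrix(character(), 0, n_fields)
  }
  list(records = records, n_malformed = sum(!ok))
}

check_unique_names <- function(name, level) {
  dup <- duplicated(tolower(name))
  if (any(dup)) {
    stop("MedDRA integrity error: duplicate ", level, " name (case-insensitive): ",
         paste(unique(name[dup]), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a MedDRA-dialect dictionary
#'
#' Reads the "$"-delimited dictionary files from `dictionary_dir` and builds
#' a validated hierarchy object. Expected files:
#'
#' * `soc.asc`: `soc_code$soc_name$`
#' * `pt.asc`: `pt_code$pt_name$primary_soc_code$`
#' * `llt.asc`: `llt_code$llt_name$pt_code$`
#' * `pt_soc.asc` (optional): `pt_code$soc_code$` secondary links
#' * `hlt.asc` (optional): `hlt_code$hlt_name$` (term identity only)
#'
#' Invariants enforced at load: codes unique across levels; names unique
#' case-insensitively within a level; every LLT links to exactly one existing
#' PT; every PT links to >= 1 existing SOC with exactly one primary.
#'
#' @param dictionary_dir directory holding the dictionary files.
#' @return an object of class `meddra_hierarchy` with elements `terms`
#'   (data frame: `code`, `name`, `level`), `llt_to_pt` (named integer
#'   vector keyed by LLT code) and `pt_links` (data frame: `pt_code`,
#'   `soc_code`, `primary`).
#' @examples
#' dir <- tempfile()
#' make_meddra_fixture(dir, n_soc = 2, n_pt_per_soc = 3, n_llt_per_pt = 2,
#'                     seed = 1)
#' h <- load_meddra(dir)
#' h
#' @export
load_meddra <- function(dictionary_dir) {
  required <- c("soc.asc", "pt.asc", "llt.asc")
  paths <- file.path(dictionary_dir, required)
  absent <- required[!file.exists(paths)]
  if (length(absent)) {
    stop("MedDRA load error: missing file(s) in ", dictionary_dir, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  soc <- read_dollar_records(file.path(dictionary_dir, "soc.asc"), 2L)$records
  pt  <- read_dollar_records(file.path(dictionary_dir, "pt.asc"),  3L)$records
  llt <- read_dollar_records(file.path(dictionary_dir, "llt.asc"), 3L)$records
  if (nrow(soc) == 0L || nrow(pt) == 0L) {
    stop("MedDRA load error: soc.asc and pt.asc must contain at least one record",
         call. = FALSE)
  }

  soc_df <- data.frame(code = as.integer(soc[, 1]), name = soc[, 2],
                       level = "SOC")
  pt_df  <- data.frame(code = as.integer(pt[, 1]), name = pt[, 2],
                       level = "PT")
  llt_df <- data.frame(code = if (nrow(llt)) as.integer(llt[, 1]) else integer(),
                       name = if (nrow(llt)) llt[, 2] else character(),
                       level = if (nrow(llt)) "LLT" else character())

  hlt_path <- file.path(dictionary_dir, "hlt.asc")
  hlt_df <- if (file.exists(hlt_path)) {
    hlt <- read_dollar_records(hlt_path, 2L)$records
    data.frame(code = if (nrow(hlt)) as.integer(hlt[, 1]) else integer(),
               name = if (nrow(hlt)) hlt[, 2] else character(),
               level = if (nrow(hlt)) "HLT" else character())
  } else {
    data.frame(code = integer(), name = character(), level = character())
  }

  terms <- rbind(soc_df, pt_df, hlt_df, llt_df)
  if (anyNA(terms$code) || any(terms$code <= 0)) {
    stop("MedDRA integrity error: non-numeric or non-positive term code",
         call. = FALSE)
  }
  if (anyDuplicated(terms$code)) {
    stop("MedDRA integrity error: duplicate code(s) across levels: ",
         paste(unique(terms$code[duplicated(terms$code)]), collapse = ", "),
         call. = FALSE)
  }
  for (lv in unique(terms$level)) {
    check_unique_names(terms$name[terms$level == lv], lv)
  }

  # LLT -> PT links: each LLT maps to exactly one existing PT
  llt_to_pt <- integer(0)
  if (nrow(llt)) {
    target <- as.integer(llt[, 3])
    bad <- !(target %in% pt_df$code)
    if (any(bad)) {
      stop("MedDRA integrity error: LLT ", paste(llt[bad, 1], collapse = ", "),
           " linked to unknown PT ", paste(unique(llt[bad, 3]), collapse = ", "),
           call. = FALSE)
    }
    llt_to_pt <- stats::setNames(target, llt[, 1])
  }

  # PT -> SOC links: primary from pt.asc, secondary from pt_soc.asc
  primary_soc <- as.integer(pt[, 3])
  bad <- !(primary_soc %in% soc_df$code)
  if (any(bad)) {
    stop("MedDRA integrity error: PT ", paste(pt[bad, 1], collapse = ", "),
         " has no resolvable primary SOC (",
         paste(unique(pt[bad, 3]), collapse = ", "), ")", call. = FALSE)
  }
  pt_links <- data.frame(pt_code = pt_df$code, soc_code = primary_soc,
                         primary = TRUE)

  sec_path <- file.path(dictionary_dir, "pt_soc.asc")
  if (file.exists(sec_path)) {
    sec <- read_dollar_records(sec_path, 2L)$records
    if (nrow(sec)) {
      sec_df <- data.frame(pt_code = as.integer(sec[, 1]),
                           soc_code = as.integer(sec[, 2]), primary = FALSE)
      if (!all(sec_df$pt_code %in% pt_df$code)) {
        stop("MedDRA integrity error: secondary link for unknown PT ",
             paste(setdiff(sec_df$pt_code, pt_df$code), collapse = ", "),
             call. = FALSE)
      }
      if (!all(sec_df$soc_code %in% soc_df$code)) {
        stop("MedDRA integrity error: secondary link to unknown SOC ",
             paste(setdiff(sec_df$soc_code, soc_df$code), collapse = ", "),
             call. = FALSE)
      }
      # a secondary link duplicating the primary is redundant, not an error
      sec_df <- sec_df[!paste(sec_df$pt_code, sec_df$soc_code) %in%
                         paste(pt_links$pt_code, pt_links$soc_code), ]
      pt_links <- rbind(pt_links, unique(sec_df))
    }
  }

  structure(
    list(terms = terms, llt_to_pt = llt_to_pt, pt_links = pt_links),
    class = "meddra_hierarchy"
  )
}

#' @export
print.meddra_hierarchy <- function(x, ...) {
  cnt <- table(factor(x$terms$level, levels = c("LLT", "PT", "HLT", "SOC")))
  cat("<meddra_hierarchy> ", nrow(x$terms), " terms: ",
      paste(sprintf("%d %s", as.integer(cnt), names(cnt)), collapse = ", "),
      "; ", nrow(x$pt_links), " PT-SOC links\n", sep = "")
  invisible(x)
}

term_level <- function(h, codes) {
  h$terms$level[match(as.integer(codes), h$terms$code)]
}

term_name <- function(h, codes) {
  h$terms$name[match(as.integer(codes), h$terms$code)]
}

#' Normalize term codes to preferred-term level
#'
#' LLT codes are replaced by their unique linked PT; PT, HLT and SOC codes
#' map to themselves with their own level flagged. This is the standard
#' "map all LLTs into PTs" unification step applied before any counting or
#' set comparison.
#'
#' @param h a [load_meddra()] hierarchy.
#' @param codes vector of term codes present in `h`.
#' @return data frame with one row per input: `code` (normalized code) and
#'   `level` (`"PT"`, `"HLT"` or `"SOC"` - never `"LLT"`).
#' @export
normalize_to_pt <- function(h, codes) {
  codes <- as.integer(codes)
  lv <- term_level(h, codes)
  if (anyNA(lv)) {
    stop("MedDRA lookup error: unknown code(s): ",
         paste(codes[is.na(lv)], collapse = ", "), call. = FALSE)
  }
  out_code <- codes
  is_llt <- lv == "LLT"
  if (any(is_llt)) {
    out_code[is_llt] <- unname(h$llt_to_pt[as.character(codes[is_llt])])
  }
  data.frame(code = out_code, level = ifelse(is_llt, "PT", lv))
}

#' System organ classes linked to a preferred term
#'
#' @param h a [load_meddra()] hierarchy.
#' @param pt a single PT code.
#' @param primary_only if `TRUE`, return only the designated primary SOC
#'   (always exactly one).
#' @return integer vector of SOC codes, primary first, then secondary links
#'   in ascending code order.
#' @export
socs_for_pt <- function(h, pt, primary_only = FALSE) {
  pt <- as.integer(pt)
  stopifnot(length(pt) == 1L)
  lv <- term_level(h, pt)
  if (is.na(lv) || lv != "PT") {
    stop("usage error: code ", pt, " is not a PT in this hierarchy",
         call. = FALSE)
  }
  ln <- h$pt_links[h$pt_links$pt_code == pt, ]
  if (primary_only) ln <- ln[ln$primary, ]
  ln <- ln[order(!ln$primary, ln$soc_code), ]
  ln$soc_code
}

#' Surface-form lexicon for dictionary matching
#'
#' One entry per LLT and PT name, case-folded, in deterministic ascending
#' code order. This is the dictionary consumed by [match_terms()].
#'
#' @param h a [load_meddra()] hierarchy.
#' @return data frame with columns `surface` (lower-cased name), `code` and
#'   `level`.
#' @export
matching_lexicon <- function(h) {
  keep <- h$terms$level %in% c("LLT", "PT")
  out <- data.frame(surface = tolower(h$terms$name[keep]),
                    code = h$terms$code[keep],
                    level = h$terms$level[keep])
  out <- out[order(out$code), ]
  rownames(out) <- NULL
  out
}
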