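# Dictionary-lookup adverse-event term extraction. Surfaces come from the
# MedDRA LLT/PT lexicon; matching is case-insensitive exact-phrase on token
# boundaries with greedy left-to-right longest match, hyphens in dictionary
# terms treated as spaces, and every hit normalized to PT level. This is a
# deterministic stand-in for a full clinical NER engine: no stemming, no
# lexical variants, no negation handling.

#' Default drug-label target sections
#'
#' The two label sections mined for adverse-event terms, identified by
#' their LOINC section codes with a case-insensitive title fallback.
#'
#' @return data frame with columns `code`, `title`, `source`.
#' @export
default_label_sections <- function() {
  data.frame(
    code = c("43685-7", "34084-4"),
    title = c("WARNINGS AND PRECAUTIONS", "ADVERSE REACTIONS"),
    source = c("label_warnings", "label_adverse_reactions")
  )
}

squish <- function(x) gsub("\\s+", " ", trimws(x))

#' Extract target sections from a structured product label
#'
#' Parses an SPL XML document and returns one document per configured
#' target section. A section is selected when its `<code code=...>`
#' attribute equals a configured code or, failing that, when its title
#' matches a configured title case-insensitively. All descendant text is
#' concatenated with single-space joins; other sections are ignored.
#'
#' @param spl_xml path to an SPL XML file.
#' @param sections data frame of (code, title, source) target pairs; see
#'   [default_label_sections()].
#' @return data frame with columns `doc_id`, `source`, `text` (zero rows,
#'   with a warning, when no target section is present).
#' @export
extract_label_sections <- function(spl_xml, sections = default_label_sections()) {
  doc <- xml2::read_xml(spl_xml)
  secs <- xml2::xml_find_all(doc, ".//*[local-name()='section']")
  base <- tools::file_path_sans_ext(basename(spl_xml))

  rows <- list()
  for (sec in secs) {
    code <- xml2::xml_attr(
      xml2::xml_find_first(sec, "./*[local-name()='code']"), "code")
    title <- squish(xml2::xml_text(
      xml2::xml_find_first(sec, "./*[local-name()='title']")))
    j <- if (!is.na(code)) match(code, sections$code) else NA_integer_
    if (is.na(j) && nzchar(title)) {
      j <- match(toupper(title), toupper(sections$title))
    }
    if (is.na(j)) next
    txt <- xml2::xml_find_all(sec, ".//text()")
    txt <- squish(xml2::xml_text(txt))
    rows[[length(rows) + 1L]] <- data.frame(
      doc_id = paste0(base, "#", sections$source[j], ".",
                      length(rows) + 1L),
      source = sections$source[j],
      text = paste(txt[nzchar(txt)], collapse = " ")
    )
  }
  if (!length(rows)) {
    warning("no target section found in ", basename(spl_xml), call. = FALSE)
    return(data.frame(doc_id = character(), source = character(),
                      text = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a literature corpus
#'
#' Accepts either a directory of UTF-8 `.txt` files (one abstract each) or
#' a single TSV file with header columns `doc_id` and `text`.
#'
#' @param path directory or TSV file.
#' @param source source tag stored on each document.
#' @return data frame with columns `doc_id`, `source`, `text`.
#' @export
read_abstract_corpus <- function(path, source = "abstract") {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    out <- data.frame(
      doc_id = tools::file_path_sans_ext(basename(files)),
      source = source,
      text = vapply(files, function(f) {
        paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = " ")
      }, character(1))
    )
    rownames(out) <- NULL
    return(out)
  }
  tab <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                           colClasses = "character")
  if (!all(c("doc_id", "text") %in% names(tab))) {
    stop("corpus TSV must have columns doc_id and text", call. = FALSE)
  }
  data.frame(doc_id = tab$doc_id, source = source, text = tab$text)
}

# Tokenize a surface form the way the matcher sees text: lower-case,
# hyphens as spaces, tokens = maximal runs of letters/digits.
surface_tokens <- function(x) {
  x <- gsub("-", " ", tolower(x), fixed = TRUE)
  toks <- strsplit(x, "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Build a reusable dictionary matcher
#'
#' Precompiles the [matching_lexicon()] of a hierarchy into a token-keyed
#' hash for [match_terms()]. When an LLT and a PT share a surface the PT
#' wins; within a level the smallest code wins.
#'
#' @param h a [load_meddra()] hierarchy.
#' @return an object of class `term_matcher`.
#' @export
build_term_matcher <- function(h) {
  lex <- matching_lexicon(h)
  keys <- vapply(lex$surface, function(s) paste(surface_tokens(s), collapse = " "),
                 character(1), USE.NAMES = FALSE)
  keep <- nzchar(keys)
  lex <- lex[keep, ]; keys <- keys[keep]
  # insertion order: LLTs (descending code) then PTs (descending code),
  # so the last write - the preferred entry - is the smallest PT code.
  ord <- order(lex$level == "PT", -lex$code)
  dict <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in ord) {
    assign(keys[i], c(code = lex$code[i]), envir = dict)
  }
  lens <- lengths(gregexpr(" ", keys, fixed = TRUE)) + 1L
  lens[!grepl(" ", keys)] <- 1L
  structure(list(dict = dict, max_len = max(lens), h = h),
            class = "term_matcher")
}

#' Match dictionary terms in a document
#'
#' Case-insensitive exact-phrase matching on token boundaries (tokens are
#' maximal runs of letters and digits; hyphens inside dictionary terms are
#' treated as spaces), greedy left-to-right longest match, non-overlapping.
#' Each hit is normalized to PT level.
#'
#' @param text a single document text string.
#' @param h a [load_meddra()] hierarchy (ignored when `matcher` is given).
#' @param matcher optional precompiled [build_term_matcher()].
#' @return data frame with columns `start`, `end` (0-based half-open
#'   character offsets), `surface` (matched substring), `code` (matched
#'   LLT/PT code), `normalized_pt` and `level_of_result`.
#' @examples
#' dir <- tempfile()
#' make_meddra_fixture(dir, 2, 3, 2, seed = 1)
#' h <- load_meddra(dir)
#' nm <- h$terms$name[h$terms$level == "PT"][1]
#' match_terms(paste("Patients developed", nm, "on treatment."), h)
#' @export
match_terms <- function(text, h = NULL, matcher = NULL) {
  if (is.null(matcher)) matcher <- build_term_matcher(h)
  empty <- data.frame(start = integer(), end = integer(),
                      surface = character(), code = integer(),
                      normalized_pt = integer(),
                      level_of_result = character())
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(empty)

  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  toks <- tolower(substring(text, starts, starts + lens - 1L))
  nt <- length(toks)

  hit_i <- integer(); hit_j <- integer(); hit_code <- integer()
  i <- 1L
  while (i <= nt) {
    advanced <- FALSE
    for (len in seq.int(min(matcher$max_len, nt - i + 1L), 1L)) {
      j <- i + len - 1L
      key <- paste(toks[i:j], collapse = " ")
      entry <- get0(key, envir = matcher$dict, ifnotfound = NULL)
      if (!is.null(entry)) {
        hit_i <- c(hit_i, i); hit_j <- c(hit_j, j)
        hit_code <- c(hit_code, entry[["code"]])
        i <- j + 1L
        advanced <- TRUE
        break
      }
    }
    if (!advanced) i <- i + 1L
  }
  if (!length(hit_i)) return(empty)

  hh <- if (is.null(h)) matcher$h else h
  norm <- normalize_to_pt(hh, hit_code)
  data.frame(
    start = starts[hit_i] - 1L,
    end = starts[hit_j] + lens[hit_j] - 1L,
    surface = substring(text, starts[hit_i], starts[hit_j] + lens[hit_j] - 1L),
    code = hit_code,
    normalized_pt = norm$code,
    level_of_result = norm$level
  )
}

#' Construct a PT-level term set
#'
#' @param codes term codes; when a hierarchy is supplied they are
#'   normalized to PT (or retained at HLT/SOC) level, so the set never
#'   contains LLT codes. Without a hierarchy the codes are taken as already
#'   normalized opaque identifiers.
#' @param h optional [load_meddra()] hierarchy.
#' @param provenance corpus identifier recorded on the set.
#' @return data frame of class `term_set` with columns `code`, `name`,
#'   `level` and attribute `provenance`.
#' @export
term_set <- function(codes, h = NULL, provenance = "user") {
  codes <- unique(as.integer(codes))
  if (!is.null(h) && length(codes)) {
    norm <- normalize_to_pt(h, codes)
    keep <- !duplicated(norm$code)
    out <- data.frame(code = norm$code[keep], level = norm$level[keep])
    out$name <- term_name(h, out$code)
  } else {
    out <- data.frame(code = codes,
                      level = rep(NA_character_, length(codes)),
                      name = rep(NA_character_, length(codes)))
  }
  out <- out[order(out$code), c("code", "name", "level")]
  rownames(out) <- NULL
  structure(out, provenance = provenance,
            class = c("term_set", "data.frame"))
}

term_codes <- function(x) {
  if (is.data.frame(x)) as.integer(x$code) else as.integer(x)
}

#' Mine a document corpus into a term set
#'
#' Runs [match_terms()] over every document and returns the union of the
#' normalized codes; duplicate hits collapse.
#'
#' @param docs data frame with a `text` column (e.g. from
#'   [extract_label_sections()] or [read_abstract_corpus()]).
#' @param h a [load_meddra()] hierarchy.
#' @param provenance corpus identifier recorded on the result.
#' @return a [term_set()].
#' @export
mine_corpus <- function(docs, h, provenance = "corpus") {
  stopifnot(is.data.frame(docs), "text" %in% names(docs))
  matcher <- build_term_matcher(h)
  codes <- integer()
  for (txt in docs$text) {
    hits <- match_terms(txt, matcher = matcher)
    codes <- c(codes, hits$code)
  }
  term_set(unique(codes), h = h, provenance = provenance)
}

#' Overlap report between two term sets
#'
#' Reports set sizes, intersection, asymmetric differences and the
#' percentage of set B covered by set A (2-decimal rounding), the quantity
#' used to compare label-derived and literature-derived term sets.
#'
#' @param set_a,set_b [term_set()]s (or plain code vectors).
#' @return an object of class `term_overlap`: `n_a`, `n_b`, `n_common`,
#'   `n_a_only`, `n_b_only`, `pct_b_covered`, `pct_a_covered`.
#' @export
term_overlap <- function(set_a, set_b) {
  a <- unique(term_codes(set_a))
  b <- unique(term_codes(set_b))
  common <- length(intersect(a, b))
  structure(list(
    n_a = length(a), n_b = length(b), n_common = common,
    n_a_only = length(a) - common, n_b_only = length(b) - common,
    pct_b_covered = if (length(b)) round(100 * common / length(b), 2) else NA_real_,
    pct_a_covered = if (length(a)) round(100 * common / length(a), 2) else NA_real_
  ), class = "term_overlap")
}

#' @export
print.term_overlap <- function(x, ...) {
  cat(sprintf("<term_overlap> |A|=%d |B|=%d |A&B|=%d; %.2f%% of B covered by A\n",
              x$n_a, x$n_b, x$n_common, x$pct_b_covered))
  invisible(x)
}

#' Write a term set as TSV
#'
#' Columns `code name level provenance`.
#'
#' @param terms a [term_set()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_term_set_tsv <- function(terms, path) {
  out <- as.data.frame(terms)
  out$provenance <- rep(attr(terms, "provenance"), length.out = nrow(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
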