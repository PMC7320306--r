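write_fixture_spl <- function(path, include_targets = TRUE) {
  sections <- if (include_targets) {
    '      <component><section>
        <code code="43685-7" codeSystem="2.16.840.1.113883.6.1"/>
        <title>Warnings and Precautions</title>
        <text>
          <paragraph>Immune-mediated colitis occurred in 2% of patients.</paragraph>
          <table><tr><td>Severe</td><td>hepatitis</td></tr></table>
        </text>
      </section></component>
      <component><section>
        <code code="34084-4" codeSystem="2.16.840.1.113883.6.1"/>
        <title>ADVERSE REACTIONS</title>
        <text><paragraph>Blood corticotrophin decreased was reported.</paragraph></text>
      </section></component>
      <component><section>
        <code code="34068-7" codeSystem="2.16.840.1.113883.6.1"/>
        <title>DOSAGE AND ADMINISTRATION</title>
        <text><paragraph>200 mg every three weeks.</paragraph></text>
      </section></component>'
  } else {
    '      <component><section>
        <code code="34068-7" codeSystem="2.16.840.1.113883.6.1"/>
        <title>DOSAGE AND ADMINISTRATION</title>
        <text><paragraph>200 mg every three weeks.</paragraph></text>
      </section></component>'
  }
  writeLines(paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                    '<document xmlns="urn:hl7-org:v3"><component><structuredBody>\n',
                    sections,
                    '\n</structuredBody></component></document>'), path)
  path
}

test_that("SPL target sections are selected by code and concatenated", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_fixture_spl(path)
  docs <- extract_label_sections(path)
  expect_equal(nrow(docs), 2L)
  expect_setequal(docs$source, c("label_warnings", "label_adverse_reactions"))
  warn <- docs$text[docs$source == "label_warnings"]
  # nested paragraph and table text all present, single-space joined
  expect_match(warn, "Immune-mediated colitis occurred in 2% of patients\\.")
  expect_match(warn, "Severe hepatitis")
  expect_false(grepl("  ", warn))
  # the dosage section is ignored
  expect_false(any(grepl("200 mg", docs$text)))
})

test_that("section titles are a case-insensitive fallback when codes are absent", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0('<?xml version="1.0"?><document xmlns="urn:hl7-org:v3">',
                    '<component><structuredBody><component><section>',
                    '<title>Warnings And Precautions</title>',
                    '<text><paragraph>colitis</paragraph></text>',
                    '</section></component></structuredBody></component></document>'),
             path)
  docs <- extract_label_sections(path)
  expect_equal(docs$source, "label_warnings")
})

test_that("labels without target sections warn and yield no documents", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_fixture_spl(path, include_targets = FALSE)
  expect_warning(docs <- extract_label_sections(path), "no target section")
  expect_equal(nrow(docs), 0L)

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<document><unclosed>", bad)
  expect_error(extract_label_sections(bad))
})

test_that("dictionary matching is exact-phrase, case-insensitive, on token boundaries", {
  h <- fixture_meddra()
  expect_equal(nrow(match_terms("", h)), 0L)

  hits <- match_terms("Patients developed colitis and hepatitis.", h)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$normalized_pt, c(10009887L, 10019717L))
  expect_true(all(hits$level_of_result == "PT"))
  # PT surface preferred over the identical LLT surface
  expect_equal(hits$code[hits$surface == "colitis"], 10009887L)

  # no match inside a larger token
  expect_equal(nrow(match_terms("procolitisol is not an event", h)), 0L)
})

test_that("greedy longest match wins over an embedded shorter surface", {
  h <- fixture_meddra()
  txt <- "Labs showed blood corticotrophin decreased on day 3."
  hits <- match_terms(txt, h)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$code, 10005452L)  # the long PT, not LLT "Blood corticotrophin"
  expect_equal(hits$surface, "blood corticotrophin decreased")
})

test_that("offsets are 0-based half-open and matches never overlap", {
  h <- fixture_meddra(extra_hyphen_llt = TRUE)
  txt <- "Noted Drug-Induced Hepatitis, then COLITIS; also blood corticotrophin."
  hits <- match_terms(txt, h)
  expect_gte(nrow(hits), 3L)
  for (k in seq_len(nrow(hits))) {
    sub <- substr(txt, hits$start[k] + 1, hits$end[k])
    expect_equal(tolower(sub), tolower(hits$surface[k]))
  }
  ord <- order(hits$start)
  expect_true(all(hits$start[ord][-1] >= hits$end[ord][-nrow(hits)]))
  # hyphenated dictionary surface matched with hyphen/space equivalence
  expect_true(30000005L %in% hits$code)
  expect_equal(hits$normalized_pt[hits$code == 30000005L], 10019717L)
})

test_that("corpus mining unions documents and never leaks LLT codes", {
  h <- fixture_meddra()
  docs <- data.frame(
    doc_id = c("d1", "d2", "d3", "d4"),
    source = "abstract",
    text = c("colitis was seen", "Colitis again, plus hepatitis aggravated",
             "nothing here", ""))
  ts <- mine_corpus(docs, h, provenance = "unit")
  expect_s3_class(ts, "term_set")
  expect_setequal(ts$code, c(10009887L, 10019717L))  # duplicates collapse
  expect_false(any(ts$level == "LLT"))
  expect_equal(attr(ts, "provenance"), "unit")

  empty <- mine_corpus(docs[docs$doc_id == "d4", ], h)
  expect_equal(nrow(empty), 0L)
})

test_that("matching the concatenated PT names recovers the full PT set exactly", {
  rs <- random_store(seed = 77, n_reports = 50)  # only the hierarchy is used
  pt_names <- rs$h$terms$name[rs$h$terms$level == "PT"]
  docs <- data.frame(doc_id = "all", source = "abstract",
                     text = paste(pt_names, collapse = "; "))
  mined <- mine_corpus(docs, rs$h)
  expect_setequal(mined$code, rs$pts)
  m <- evaluate_terms(mined, term_set(rs$pts, h = rs$h))
  expect_equal(m$precision, 100)
  expect_equal(m$recall, 100)
})

test_that("overlap reports cover identity, partial and disjoint cases", {
  a <- term_set(1:10)
  expect_equal(term_overlap(a, a)$pct_b_covered, 100)
  expect_equal(term_overlap(term_set(1:5), term_set(6:10))$pct_b_covered, 0)
  ov <- term_overlap(term_set(1:3), term_set(c(2:3, 11:14)))
  expect_equal(ov$n_common, 2L)
  expect_equal(ov$n_a_only, 1L)
  expect_equal(ov$n_b_only, 4L)
  expect_equal(ov$pct_b_covered, round(100 * 2 / 6, 2))
})

test_that("abstract corpora read from TSV and from a directory of text files", {
  h <- fixture_meddra()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("doc_id\ttext", "a1\tcolitis seen", "a2\tno events"), tsv)
  docs <- read_abstract_corpus(tsv)
  expect_equal(nrow(docs), 2L)
  expect_equal(mine_corpus(docs, h)$code, 10009887L)

  dir <- withr::local_tempdir()
  writeLines("hepatitis aggravated", file.path(dir, "a3.txt"))
  docs2 <- read_abstract_corpus(dir)
  expect_equal(docs2$doc_id, "a3")
  expect_equal(mine_corpus(docs2, h)$code, 10019717L)
})
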