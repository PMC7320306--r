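test_that("dictionary fixtures have forced counts and are byte-stable", {
  dir1 <- withr::local_tempdir()
  fix <- make_meddra_fixture(dir1, 2, 3, 2, secondary_link_prob = 0,
                             seed = 7)
  h <- load_meddra(dir1)
  expect_equal(sum(h$terms$level == "SOC"), 2L)
  expect_equal(sum(h$terms$level == "PT"), 6L)
  expect_equal(sum(h$terms$level == "LLT"), 12L)
  expect_equal(sum(h$pt_links$primary), 6L)
  expect_equal(sum(!h$pt_links$primary), 0L)

  dir2 <- withr::local_tempdir()
  make_meddra_fixture(dir2, 2, 3, 2, secondary_link_prob = 0, seed = 7)
  for (f in c("soc.asc", "pt.asc", "llt.asc", "pt_soc.asc")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }

  dir3 <- withr::local_tempdir()
  make_meddra_fixture(dir3, 2, 2, 1, secondary_link_prob = 1, seed = 3)
  h3 <- load_meddra(dir3)
  sec <- h3$pt_links[!h3$pt_links$primary, ]
  expect_equal(nrow(sec), 4L)           # every PT got one secondary link
  expect_equal(anyDuplicated(sec$pt_code), 0L)
})

test_that("designs validate probabilities and injection solvability", {
  expect_error(simulation_design(100, c("1" = 1.2), c("10" = 0.1)),
               "exposure_prob")
  expect_error(
    simulation_design(100, c("1" = 0.3), c("10" = 0.1),
                      injections = data.frame(concept_id = 2, pt_code = 10,
                                              omega = 5)),
    "unknown drug concept")
  expect_error(
    simulation_design(100, c("1" = 0.3), c("10" = 0.1),
                      injections = data.frame(concept_id = 1, pt_code = 10,
                                              omega = -2)),
    "omega")
  d <- simulation_design(100, c("1" = 0.3), c("10" = 0.1),
                         injections = data.frame(concept_id = 1,
                                                 pt_code = 10, omega = 20))
  # p1 solves p1/(1-p1) = omega * p0/(1-p0)
  expect_equal(d$injections$p1 / (1 - d$injections$p1),
               20 * 0.1 / 0.9, tolerance = 1e-12)
})

test_that("report simulation is deterministic given the seed", {
  dir <- withr::local_tempdir()
  fixdir <- file.path(dir, "meddra")
  make_meddra_fixture(fixdir, 2, 2, 2, seed = 1)
  h <- load_meddra(fixdir)
  pts <- h$terms$code[h$terms$level == "PT"]
  design <- simulation_design(500, c("45775965" = 0.3),
                              setNames(rep(0.2, 4), pts),
                              duplicate_fraction = 0.3, llt_fraction = 0.4,
                              seed = 99)
  simulate_reports(design, icb_lexicon(), file.path(dir, "a"), h = h)
  simulate_reports(design, icb_lexicon(), file.path(dir, "b"), h = h)
  for (f in c("demo.txt", "drug.txt", "reac.txt")) {
    expect_identical(readLines(file.path(dir, "a", f)),
                     readLines(file.path(dir, "b", f)))
  }
})

test_that("duplicated cases collapse to distinct caseids after dedup", {
  dir <- withr::local_tempdir()
  make_meddra_fixture(file.path(dir, "m"), 2, 2, 1, seed = 2)
  h <- load_meddra(file.path(dir, "m"))
  pts <- h$terms$code[h$terms$level == "PT"]
  design <- simulation_design(400, c("45775965" = 0.4),
                              setNames(rep(0.3, 4), pts),
                              duplicate_fraction = 0.5, seed = 5)
  simulate_reports(design, icb_lexicon(), file.path(dir, "f"), h = h)
  raw <- read_faers_tables(file.path(dir, "f"))
  n_caseids <- length(unique(raw$demo$caseid))
  expect_gt(nrow(raw$demo), n_caseids)  # duplicates really were emitted
  dedup <- deduplicate_cases(raw)
  expect_equal(nrow(dedup$demo), n_caseids)
  store <- build_store(raw, icb_lexicon(), h)
  expect_equal(store$n_total, n_caseids)
  # the latest version was kept for every duplicated case
  dup_cases <- names(which(table(raw$demo$caseid) > 1))
  expect_true(all(dedup$demo$caseversion[dedup$demo$caseid %in% dup_cases] == 2L))
})

test_that("empirical exposed-event frequency calibrates to the design p1", {
  # 20 moderately common PTs keep the zero-event redraw/drop truncation
  # negligible, so the post-drop marginal stays within Monte-Carlo error
  dir <- withr::local_tempdir()
  make_meddra_fixture(file.path(dir, "m"), 4, 5, 1, seed = 8)
  h <- load_meddra(file.path(dir, "m"))
  pts <- h$terms$code[h$terms$level == "PT"]
  omega <- 2; p0 <- 0.3
  design <- simulation_design(
    50000, c("45775965" = 0.3), setNames(rep(p0, 20), pts),
    injections = data.frame(concept_id = 45775965, pt_code = pts[1],
                            omega = omega),
    seed = 13)
  simulate_reports(design, icb_lexicon(), file.path(dir, "f"))
  store <- build_store(read_faers_tables(file.path(dir, "f")),
                       icb_lexicon(), h)
  tab <- build_contingency(store, 45775965, pts[1], level = "PT", h = h)
  p1 <- design$injections$p1
  freq <- tab$a / (tab$a + tab$b)
  mc_se <- sqrt(p1 * (1 - p1) / (tab$a + tab$b))
  expect_lt(abs(freq - p1), 3 * mc_se + p1 * 0.002)
})

test_that("planted label corpora mine back exactly, with LLTs surfacing as PTs", {
  dir <- withr::local_tempdir()
  make_meddra_fixture(file.path(dir, "m"), 2, 3, 2, seed = 21)
  h <- load_meddra(file.path(dir, "m"))
  pts <- h$terms$code[h$terms$level == "PT"]
  llts <- h$terms$code[h$terms$level == "LLT"]
  planted <- c(pts[1], pts[4], llts[5])  # llts[5] belongs to pts[3]
  make_label_corpus(file.path(dir, "lab"), h, planted, distractors = 10,
                    seed = 2)
  docs <- extract_label_sections(
    file.path(dir, "lab", "synthetic_label_001.xml"))
  mined <- mine_corpus(docs, h, provenance = "drug_labels")
  expect_setequal(mined$code, unique(normalize_to_pt(h, planted)$code))
  expect_true(pts[3] %in% mined$code)   # the LLT surfaced as its PT

  # empty plant list -> empty term set
  make_label_corpus(file.path(dir, "lab0"), h, integer(), distractors = 5,
                    seed = 3)
  docs0 <- extract_label_sections(
    file.path(dir, "lab0", "synthetic_label_001.xml"))
  expect_equal(nrow(mine_corpus(docs0, h)), 0L)
})

test_that("planted abstract corpora mine back exactly", {
  dir <- withr::local_tempdir()
  make_meddra_fixture(file.path(dir, "m"), 2, 2, 1, seed = 33)
  h <- load_meddra(file.path(dir, "m"))
  pts <- h$terms$code[h$terms$level == "PT"]
  tsv <- file.path(dir, "abs.tsv")
  make_abstract_corpus(tsv, h, pts[2:3], distractors = 6, seed = 4)
  mined <- mine_corpus(read_abstract_corpus(tsv), h)
  expect_setequal(mined$code, pts[2:3])
})

test_that("the full synthetic pipeline classifies planted vs unplanted injections", {
  dir <- withr::local_tempdir()
  make_meddra_fixture(file.path(dir, "m"), 2, 4, 1, seed = 17)
  h <- load_meddra(file.path(dir, "m"))
  pts <- h$terms$code[h$terms$level == "PT"]
  design <- simulation_design(
    4000, c("45775965" = 0.3), setNames(rep(0.05, 8), pts),
    injections = data.frame(concept_id = 45775965, pt_code = pts[1:2],
                            omega = 20),
    seed = 19)
  simulate_reports(design, icb_lexicon(), file.path(dir, "f"))
  store <- build_store(read_faers_tables(file.path(dir, "f")),
                       icb_lexicon(), h)
  sig <- detect_signals(store, 45775965, h, level = "PT")
  expect_true(all(pts[1:2] %in% sig$event_code[sig$positive]))

  make_label_corpus(file.path(dir, "lab"), h, pts[1], seed = 23)
  label_terms <- mine_corpus(
    extract_label_sections(file.path(dir, "lab", "synthetic_label_001.xml")),
    h, provenance = "drug_labels")
  cls <- classify_signals(sig, label_terms, term_set(integer()), h = h)
  asg <- setNames(cls$assignments$category,
                  cls$assignments$event_code)
  expect_equal(unname(asg[as.character(pts[1])]), "labeled")
  expect_equal(unname(asg[as.character(pts[2])]), "new")
})
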