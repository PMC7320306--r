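# Fixtures are built in code at test time; nothing binary ships with the
# package. The hand-written dictionary mirrors real MedDRA codes for a
# handful of immune-related terms so the hierarchy semantics are easy to
# eyeball: 2 SOCs, 3 PTs, 4 LLTs, one secondary PT-SOC link.

write_fixture_meddra <- function(dir, extra_hyphen_llt = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("20000001$Gastrointestinal disorders$",
               "20000002$Investigations$"),
             file.path(dir, "soc.asc"))
  writeLines(c("10009887$Colitis$20000001$",
               "10019717$Hepatitis$20000001$",
               "10005452$Blood corticotrophin decreased$20000002$"),
             file.path(dir, "pt.asc"))
  llt <- c("30000001$Inflammation of colon$10009887$",
           "30000002$Colitis$10009887$",
           "30000003$Hepatitis aggravated$10019717$",
           "30000004$Blood corticotrophin$10005452$")
  if (extra_hyphen_llt) {
    llt <- c(llt, "30000005$Drug-induced hepatitis$10019717$")
  }
  writeLines(llt, file.path(dir, "llt.asc"))
  writeLines("10005452$20000001$", file.path(dir, "pt_soc.asc"))
  dir
}

fixture_meddra <- function(extra_hyphen_llt = FALSE,
                           env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  write_fixture_meddra(dir, extra_hyphen_llt)
  load_meddra(dir)
}

# Hand FAERS-dialect fixture exercising versioned duplicates, exact
# duplicate rows, synonym-only drug names, unmapped drugs, LLT-coded and
# unmappable events, and a report with zero mappable events.
write_fixture_faers <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("primaryid$caseid$caseversion$sex$",
               "P100.1$100$1$F$",
               "P100.2$100$2$F$",
               "P101.1$101$1$M$",
               "P102.1$102$1$x$",
               "P102.1$102$1$x$",
               "P103.1$103$1$$",
               "P104.1$104$1$F$",
               "P105.1$105$$F$"),
             file.path(dir, "demo.txt"))
  writeLines(c("primaryid$drugname$",
               "P100.1$Pembrolizumab$",
               "P100.2$Pembrolizumab$",
               "P101.1$KEYTRUDA  $",
               "P101.1$keytruda$",
               "P102.1$notadrug$",
               "P103.1$Opdivo$",
               "P104.1$MK-3475$"),
             file.path(dir, "drug.txt"))
  writeLines(c("primaryid$meddra_code$",
               "P100.1$10009887$",
               "P100.2$30000001$",
               "P101.1$10009887$",
               "P101.1$10019717$",
               "P102.1$10019717$",
               "P103.1$99999999$",
               "P104.1$10005452$"),
             file.path(dir, "reac.txt"))
  dir
}

fixture_store <- function(env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  write_fixture_faers(dir)
  h <- fixture_meddra(env = env)
  build_store(read_faers_tables(dir), icb_lexicon(), h)
}

# Build a case store from inline row specifications:
# reports = list(list(id, drugs = character(), events = integer()), ...)
make_inline_store <- function(reports, h, lexicon = icb_lexicon(),
                              env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  demo <- c("primaryid$caseid$caseversion$sex$",
            vapply(reports, function(r)
              sprintf("%s$%s$1$F$", r$id, r$id), character(1)))
  drug <- c("primaryid$drugname$", unlist(lapply(reports, function(r)
    sprintf("%s$%s$", r$id, r$drugs))))
  reac <- c("primaryid$meddra_code$", unlist(lapply(reports, function(r)
    sprintf("%s$%d$", r$id, r$events))))
  writeLines(demo, file.path(dir, "demo.txt"))
  writeLines(drug, file.path(dir, "drug.txt"))
  writeLines(reac, file.path(dir, "reac.txt"))
  build_store(read_faers_tables(dir), lexicon, h)
}

# Independent brute-force oracle: enumerate reports one by one and place
# each in exactly one 2x2 cell.
brute_cells <- function(store, exposure, event_code, level, h) {
  a <- b <- c <- d <- 0L
  for (id in store$reports$primaryid) {
    cids <- store$exposures$concept_id[store$exposures$primaryid == id]
    exposed <- any(!is.na(cids) & cids %in% exposure)
    pts <- store$events$pt_code[store$events$primaryid == id]
    has <- if (level == "PT") {
      event_code %in% pts
    } else {
      any(vapply(pts, function(p) event_code %in% socs_for_pt(h, p),
                 logical(1)))
    }
    if (exposed && has) a <- a + 1L
    else if (exposed && !has) b <- b + 1L
    else if (!exposed && has) c <- c + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c, d = d)
}

# A random synthetic store (dictionary + reports) of modest size.
random_store <- function(seed, n_reports = 150, env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  make_meddra_fixture(file.path(dir, "meddra"), n_soc = 2, n_pt_per_soc = 3,
                      n_llt_per_pt = 2, secondary_link_prob = 0.5,
                      seed = seed)
  h <- load_meddra(file.path(dir, "meddra"))
  pts <- h$terms$code[h$terms$level == "PT"]
  design <- simulation_design(
    n_reports = n_reports,
    exposure_prob = c("45775965" = 0.4, "45892628" = 0.25),
    background_rates = stats::setNames(rep(0.2, length(pts)), pts),
    injections = data.frame(concept_id = 45775965, pt_code = pts[1],
                            omega = 8),
    duplicate_fraction = 0.2, llt_fraction = 0.3, seed = seed + 1)
  simulate_reports(design, icb_lexicon(), file.path(dir, "faers"), h = h)
  store <- build_store(read_faers_tables(file.path(dir, "faers")),
                       icb_lexicon(), h)
  list(store = store, h = h, pts = pts)
}
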