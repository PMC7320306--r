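# Synthetic fixtures for the whole pipeline: a mini MedDRA-dialect
# dictionary, FAERS-dialect report files with injected drug-event
# associations of specified odds ratio, and SPL/abstract corpora with
# planted dictionary surfaces. Everything is deterministic given a seed,
# so fixtures are generated at test time rather than shipped.

syllable_pool <- function() {
  list(cons = c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r",
                "s", "t", "v", "z"),
       vows = c("a", "e", "i", "o", "u"))
}

random_word <- function(n_syllables = 3L) {
  p <- syllable_pool()
  paste(paste0(sample(p$cons, n_syllables, replace = TRUE),
               sample(p$vows, n_syllables, replace = TRUE)),
        collapse = "")
}

capitalize <- function(x) {
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}

# n unique pronounceable term names, distinct (case-insensitively) from
# everything in `used`.
unique_term_names <- function(n, used, n_words = 2L) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 10000L) stop("name generator exhausted", call. = FALSE)
    nm <- capitalize(paste(vapply(seq_len(n_words), function(i)
      random_word(sample(2:3, 1)), character(1)), collapse = " "))
    if (!(tolower(nm) %in% used)) {
      out <- c(out, nm)
      used <- c(used, tolower(nm))
    }
  }
  list(names = out, used = used)
}

write_dollar_lines <- function(path, ...) {
  fields <- list(...)
  lines <- do.call(paste, c(fields, sep = "$"))
  writeLines(paste0(lines, "$"), path, useBytes = TRUE)
}

#' Generate a MedDRA-dialect dictionary fixture
#'
#' Writes `soc.asc`, `pt.asc`, `llt.asc` and `pt_soc.asc` to `dir`:
#' `n_soc` system organ classes, `n_pt_per_soc` preferred terms under each
#' (that SOC being their primary), and `n_llt_per_pt` lowest-level terms
#' under each PT. Term names are pronounceable unique tokens; with
#' probability `secondary_link_prob` a PT additionally gets one secondary
#' SOC link. Codes are assigned deterministically: SOCs from 10000001,
#' PTs from 20000001, LLTs from 30000001. Byte-identical output for a
#' given seed.
#'
#' @param dir output directory (created if needed).
#' @param n_soc,n_pt_per_soc,n_llt_per_pt fixture dimensions (all >= 1).
#' @param secondary_link_prob probability that a PT gains one secondary
#'   SOC link (requires `n_soc >= 2` to take effect).
#' @param seed RNG seed.
#' @return invisibly, a list with the code vectors (`soc_codes`,
#'   `pt_codes`, `llt_codes`) and the written file paths.
#' @export
make_meddra_fixture <- function(dir, n_soc, n_pt_per_soc, n_llt_per_pt,
                                secondary_link_prob = 0, seed = 1L) {
  stopifnot(n_soc >= 1, n_pt_per_soc >= 1, n_llt_per_pt >= 1,
            secondary_link_prob >= 0, secondary_link_prob <= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_pt <- n_soc * n_pt_per_soc
  n_llt <- n_pt * n_llt_per_pt

  withr::with_seed(seed, {
    used <- character(0)
    g <- unique_term_names(n_soc, used); soc_names <- g$names; used <- g$used
    g <- unique_term_names(n_pt, used);  pt_names <- g$names;  used <- g$used
    g <- unique_term_names(n_llt, used); llt_names <- g$names

    soc_codes <- 10000000L + seq_len(n_soc)
    pt_codes <- 20000000L + seq_len(n_pt)
    llt_codes <- 30000000L + seq_len(n_llt)
    pt_primary <- rep(soc_codes, each = n_pt_per_soc)
    llt_parent <- rep(pt_codes, each = n_llt_per_pt)

    sec <- data.frame(pt_code = integer(), soc_code = integer())
    if (n_soc >= 2 && secondary_link_prob > 0) {
      gets <- stats::runif(n_pt) < secondary_link_prob
      for (i in which(gets)) {
        others <- setdiff(soc_codes, pt_primary[i])
        pick <- if (length(others) == 1L) others else sample(others, 1L)
        sec <- rbind(sec, data.frame(pt_code = pt_codes[i], soc_code = pick))
      }
    }

    files <- file.path(dir, c("soc.asc", "pt.asc", "llt.asc", "pt_soc.asc"))
    write_dollar_lines(files[1], soc_codes, paste(soc_names, "disorders"))
    write_dollar_lines(files[2], pt_codes, pt_names, pt_primary)
    write_dollar_lines(files[3], llt_codes, llt_names, llt_parent)
    write_dollar_lines(files[4], sec$pt_code, sec$soc_code)

    invisible(list(soc_codes = soc_codes, pt_codes = pt_codes,
                   llt_codes = llt_codes, files = files))
  })
}

#' Specify a spontaneous-report simulation
#'
#' For each injected (drug, PT, omega) triple the exposed event
#' probability `p1` solves `p1/(1-p1) = omega * p0/(1-p0)`, so the design
#' odds ratio of the injected pair is `omega`; all other drug-PT pairs are
#' null by construction (event probabilities independent of exposure).
#'
#' @param n_reports number of case reports to draw (before the zero-event
#'   drop; see [simulate_reports()]).
#' @param exposure_prob named numeric vector: per-drug exposure
#'   probability, names = ingredient concept ids.
#' @param background_rates named numeric vector: per-PT baseline event
#'   probability `p0`, names = PT codes.
#' @param injections optional data frame with columns `concept_id`,
#'   `pt_code`, `omega`.
#' @param duplicate_fraction fraction of kept cases additionally emitted
#'   as an earlier case version, to exercise deduplication.
#' @param llt_fraction fraction of reaction rows coded at LLT rather than
#'   PT level (requires a hierarchy at simulation time).
#' @param seed RNG seed.
#' @return an object of class `simulation_design` (the validated inputs
#'   plus per-injection `p1`).
#' @export
simulation_design <- function(n_reports, exposure_prob, background_rates,
                              injections = NULL, duplicate_fraction = 0,
                              llt_fraction = 0, seed = 1L) {
  stopifnot(n_reports >= 1,
            !is.null(names(exposure_prob)), !is.null(names(background_rates)),
            all(exposure_prob > 0 & exposure_prob < 1),
            all(background_rates > 0 & background_rates < 1),
            duplicate_fraction >= 0, duplicate_fraction <= 1,
            llt_fraction >= 0, llt_fraction <= 1)
  if (!is.null(injections) && nrow(injections)) {
    stopifnot(all(c("concept_id", "pt_code", "omega") %in% names(injections)))
    bad <- !(as.character(injections$concept_id) %in% names(exposure_prob)) |
      !(as.character(injections$pt_code) %in% names(background_rates))
    if (any(bad)) {
      stop("design error: injection ", which(bad)[1],
           " references an unknown drug concept or PT", call. = FALSE)
    }
    if (any(injections$omega <= 0)) {
      stop("design error: omega must be > 0", call. = FALSE)
    }
    p0 <- background_rates[as.character(injections$pt_code)]
    odds1 <- injections$omega * p0 / (1 - p0)
    injections$p1 <- odds1 / (1 + odds1)
    if (any(injections$p1 >= 1 | injections$p1 <= 0)) {
      stop("design error: unsatisfiable exposed event probability for injection ",
           which(injections$p1 >= 1 | injections$p1 <= 0)[1], call. = FALSE)
    }
  } else {
    injections <- data.frame(concept_id = integer(), pt_code = integer(),
                             omega = numeric(), p1 = numeric())
  }
  structure(list(n_reports = as.integer(n_reports),
                 exposure_prob = exposure_prob,
                 background_rates = background_rates,
                 injections = injections,
                 duplicate_fraction = duplicate_fraction,
                 llt_fraction = llt_fraction,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate FAERS-dialect report files
#'
#' Per report, exposure to each drug is drawn independently; each PT event
#' is then drawn with its injected `p1` when an injecting drug is present,
#' else with its baseline `p0`. Reports whose event draw comes up empty
#' get one redraw and are dropped if still empty (spontaneous reports
#' always list at least one reaction). Verbatim drug names are sampled
#' uniformly among the concept's surface forms (ingredient, brand,
#' synonyms); reports with no study-drug exposure carry a single
#' non-lexicon filler drug name. A `duplicate_fraction` of kept cases is
#' emitted twice with incremented case version. Deterministic given the
#' design seed.
#'
#' @param design a [simulation_design()].
#' @param lexicon a [drug_lexicon()] covering the design's drug concepts.
#' @param dir output directory for `demo.txt`, `drug.txt`, `reac.txt`.
#' @param h optional hierarchy; required when `llt_fraction > 0` so PT
#'   events can be recoded as one of their LLTs.
#' @return invisibly, a summary list: `n_drawn`, `n_dropped`, `n_cases`,
#'   `files`.
#' @export
simulate_reports <- function(design, lexicon, dir, h = NULL) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(lexicon, "drug_lexicon"))
  if (design$llt_fraction > 0 && is.null(h)) {
    stop("design error: llt_fraction > 0 requires the hierarchy", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  concepts <- as.integer(names(design$exposure_prob))
  pts <- as.integer(names(design$background_rates))
  n <- design$n_reports
  K <- length(concepts)
  J <- length(pts)

  withr::with_seed(design$seed, {
    # exposure matrix: n x K
    E <- matrix(stats::runif(n * K) <
                  rep(design$exposure_prob, each = n), n, K)

    # per-report event probability matrix: n x J
    P <- matrix(rep(design$background_rates, each = n), n, J)
    inj <- design$injections
    for (r in seq_len(nrow(inj))) {
      kk <- match(as.integer(inj$concept_id[r]), concepts)
      jj <- match(as.integer(inj$pt_code[r]), pts)
      P[E[, kk], jj] <- inj$p1[r]
    }

    Y <- matrix(stats::runif(n * J) < P, n, J)
    none <- rowSums(Y) == 0
    if (any(none)) {
      Y[none, ] <- stats::runif(sum(none) * J) < P[none, , drop = FALSE]
      none2 <- rowSums(Y) == 0
      keep <- !none2
    } else {
      keep <- rep(TRUE, n)
    }
    n_dropped <- sum(!keep)
    E <- E[keep, , drop = FALSE]
    Y <- Y[keep, , drop = FALSE]
    nk <- nrow(E)

    caseid <- sprintf("C%06d", seq_len(nk))
    sex <- sample(c("F", "M", "UNK"), nk, replace = TRUE,
                  prob = c(0.558, 0.347, 0.095))

    n_dup <- floor(design$duplicate_fraction * nk)
    dup <- if (n_dup > 0) sort(sample.int(nk, n_dup)) else integer(0)

    # demo: every kept case at version 1; duplicated cases again at 2
    demo <- data.frame(primaryid = paste0(caseid, ".1"), caseid = caseid,
                       caseversion = 1L, sex = sex)
    if (length(dup)) {
      demo <- rbind(demo, data.frame(primaryid = paste0(caseid[dup], ".2"),
                                     caseid = caseid[dup], caseversion = 2L,
                                     sex = sex[dup]))
    }

    # drug rows: verbatim form sampled per exposed (report, concept) pair;
    # reports exposed to no study drug carry one filler name outside the
    # lexicon
    forms_by_concept <- lapply(concepts, concept_surface_forms,
                               lexicon = lexicon)
    n_forms <- lengths(forms_by_concept)
    all_forms <- unlist(forms_by_concept)
    offs <- cumsum(c(0L, n_forms))
    pairs_e <- which(E, arr.ind = TRUE)
    pick <- ceiling(stats::runif(nrow(pairs_e)) * n_forms[pairs_e[, 2]])
    unexposed <- which(rowSums(E) == 0)
    drug_case <- c(pairs_e[, 1], unexposed)
    drug_name <- c(all_forms[offs[pairs_e[, 2]] + pick],
                   rep("comparatorol", length(unexposed)))

    # reaction rows: PT code, or one of its LLTs with prob llt_fraction
    pairs_y <- which(Y, arr.ind = TRUE)
    reac_case <- pairs_y[, 1]
    reac_code <- pts[pairs_y[, 2]]
    if (design$llt_fraction > 0) {
      kids_by_pt <- lapply(pts, function(p) {
        as.integer(names(h$llt_to_pt))[unname(h$llt_to_pt) == p]
      })
      n_kids <- lengths(kids_by_pt)
      all_kids <- unlist(kids_by_pt)
      koffs <- cumsum(c(0L, n_kids))
      swap <- stats::runif(length(reac_code)) < design$llt_fraction &
        n_kids[pairs_y[, 2]] > 0
      kpick <- ceiling(stats::runif(length(reac_code)) *
                         pmax(n_kids[pairs_y[, 2]], 1L))
      reac_code[swap] <- all_kids[koffs[pairs_y[swap, 2]] + kpick[swap]]
    }

    # duplicated cases re-emit their drug/reaction rows under version 2
    dup_drug <- drug_case %in% dup
    dup_reac <- reac_case %in% dup
    drug_rows <- data.frame(primaryid = paste0(caseid[drug_case], ".1"),
                            drugname = drug_name)
    if (any(dup_drug)) {
      drug_rows <- rbind(drug_rows, data.frame(
        primaryid = paste0(caseid[drug_case[dup_drug]], ".2"),
        drugname = drug_name[dup_drug]))
    }
    reac_rows <- data.frame(primaryid = paste0(caseid[reac_case], ".1"),
                            meddra_code = reac_code)
    if (any(dup_reac)) {
      reac_rows <- rbind(reac_rows, data.frame(
        primaryid = paste0(caseid[reac_case[dup_reac]], ".2"),
        meddra_code = reac_code[dup_reac]))
    }

    files <- file.path(dir, c("demo.txt", "drug.txt", "reac.txt"))
    writeLines(c("primaryid$caseid$caseversion$sex$",
                 sprintf("%s$%s$%d$%s$", demo$primaryid, demo$caseid,
                         demo$caseversion, demo$sex)),
               files[1], useBytes = TRUE)
    writeLines(c("primaryid$drugname$",
                 sprintf("%s$%s$", drug_rows$primaryid, drug_rows$drugname)),
               files[2], useBytes = TRUE)
    writeLines(c("primaryid$meddra_code$",
                 sprintf("%s$%d$", reac_rows$primaryid, reac_rows$meddra_code)),
               files[3], useBytes = TRUE)

    invisible(list(n_drawn = n, n_dropped = n_dropped, n_cases = nk,
                   files = files))
  })
}

# A sentence of random non-dictionary words; resampled until it contains
# no dictionary surface at all.
safe_sentence <- function(matcher, n_words = 6L) {
  repeat {
    words <- vapply(seq_len(n_words), function(i) random_word(sample(2:3, 1)),
                    character(1))
    sent <- paste0(capitalize(paste(words, collapse = " ")), ".")
    if (nrow(match_terms(sent, matcher = matcher)) == 0L) return(sent)
  }
}

# Embed one surface form in a filler sentence that adds no other match.
plant_sentence <- function(matcher, surface) {
  repeat {
    pre <- vapply(1:2, function(i) random_word(sample(2:3, 1)), character(1))
    post <- vapply(1:2, function(i) random_word(sample(2:3, 1)), character(1))
    frame <- paste0(capitalize(paste(pre, collapse = " ")), " ",
                    paste(post, collapse = " "), ".")
    if (nrow(match_terms(frame, matcher = matcher)) == 0L) {
      return(paste0(capitalize(paste(pre, collapse = " ")), " ", surface,
                    " ", paste(post, collapse = " "), "."))
    }
  }
}

spl_skeleton <- function(sections_xml) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<document xmlns="urn:hl7-org:v3">\n  <component>\n',
         '    <structuredBody>\n', sections_xml,
         '    </structuredBody>\n  </component>\n</document>\n')
}

spl_section <- function(code, title, sentences) {
  paste0('      <component>\n        <section>\n',
         '          <code code="', code,
         '" codeSystem="2.16.840.1.113883.6.1"/>\n',
         '          <title>', title, '</title>\n          <text>\n',
         paste0('            <paragraph>', sentences, '</paragraph>\n',
                collapse = ""),
         '          </text>\n        </section>\n      </component>\n')
}

#' Generate an SPL drug-label fixture with planted terms
#'
#' Writes one synthetic SPL XML file whose WARNINGS AND PRECAUTIONS and
#' ADVERSE REACTIONS sections embed the surface form of each planted term
#' exactly once inside filler sentences, plus `distractors` sentences
#' containing no dictionary surface. Planted LLT codes surface as the LLT
#' name and therefore mine back as their PT.
#'
#' @param dir output directory.
#' @param h a [load_meddra()] hierarchy.
#' @param planted vector of LLT/PT codes from `h` to embed (may be empty).
#' @param distractors number of distractor sentences per section.
#' @param seed RNG seed.
#' @param file_name name of the XML file written into `dir`.
#' @return invisibly, the written file path.
#' @export
make_label_corpus <- function(dir, h, planted, distractors = 10L, seed = 1L,
                              file_name = "synthetic_label_001.xml") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  planted <- as.integer(planted)
  if (length(planted)) {
    lv <- term_level(h, planted)
    if (anyNA(lv) || !all(lv %in% c("LLT", "PT"))) {
      stop("planted codes must be LLT or PT codes of the hierarchy",
           call. = FALSE)
    }
  }
  matcher <- build_term_matcher(h)
  path <- file.path(dir, file_name)

  withr::with_seed(seed, {
    half <- ceiling(length(planted) / 2)
    groups <- list(warnings = planted[seq_len(half)],
                   adverse = planted[setdiff(seq_along(planted),
                                             seq_len(half))])
    sec_xml <- mapply(function(codes, code, title) {
      planted_sent <- vapply(codes, function(cd) {
        plant_sentence(matcher, term_name(h, cd))
      }, character(1))
      filler <- vapply(seq_len(distractors), function(i)
        safe_sentence(matcher), character(1))
      spl_section(code, title, c(planted_sent, filler))
    }, groups, c("43685-7", "34084-4"),
    c("WARNINGS AND PRECAUTIONS", "ADVERSE REACTIONS"))
    writeLines(spl_skeleton(paste(sec_xml, collapse = "")), path,
               useBytes = TRUE)
  })
  invisible(path)
}

#' Generate a literature-abstract fixture with planted terms
#'
#' Writes a TSV corpus (`doc_id`, `text`) of one synthetic abstract per
#' planted term (its surface embedded once in filler sentences) plus
#' `distractors` abstracts containing no dictionary surface.
#'
#' @param path output TSV file path.
#' @param h a [load_meddra()] hierarchy.
#' @param planted vector of LLT/PT codes from `h` to embed (may be empty).
#' @param distractors number of term-free abstracts.
#' @param seed RNG seed.
#' @return invisibly, the written file path.
#' @export
make_abstract_corpus <- function(path, h, planted, distractors = 5L,
                                 seed = 1L) {
  planted <- as.integer(planted)
  if (length(planted)) {
    lv <- term_level(h, planted)
    if (anyNA(lv) || !all(lv %in% c("LLT", "PT"))) {
      stop("planted codes must be LLT or PT codes of the hierarchy",
           call. = FALSE)
    }
  }
  matcher <- build_term_matcher(h)
  withr::with_seed(seed, {
    texts <- c(
      vapply(planted, function(cd) {
        paste(plant_sentence(matcher, term_name(h, cd)),
              safe_sentence(matcher))
      }, character(1)),
      vapply(seq_len(distractors), function(i) {
        paste(safe_sentence(matcher), safe_sentence(matcher))
      }, character(1))
    )
    df <- data.frame(doc_id = sprintf("abstract_%03d", seq_along(texts)),
                     text = texts)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  invisible(path)
}
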