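# Drug lexicon: maps verbatim drug names (ingredient, brand, development
# codes) to a standard ingredient concept id. Spontaneous-report drug fields
# are free text, so every surface form is matched case-insensitively after
# whitespace normalization.

norm_surface <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Build a drug lexicon
#'
#' @param concepts data frame with columns `concept_id` (positive integer,
#'   ingredient-level standard concept), `ingredient_name`, `brand_name`,
#'   and optionally `brand_concept_id` and `synonyms` (a `|`-separated
#'   string of additional surface forms such as development codes).
#' @return an object of class `drug_lexicon` with the concept table and a
#'   `surfaces` lookup table (normalized surface -> ingredient concept id).
#' @examples
#' lex <- drug_lexicon(data.frame(
#'   concept_id = 45775965, ingredient_name = "Pembrolizumab",
#'   brand_name = "Keytruda", synonyms = "MK-3475"))
#' map_drug_names(c("KEYTRUDA  ", "mk-3475", "notadrug"), lex)
#' @export
drug_lexicon <- function(concepts) {
  stopifnot(is.data.frame(concepts),
            all(c("concept_id", "ingredient_name", "brand_name") %in%
                  names(concepts)))
  concepts$concept_id <- as.integer(concepts$concept_id)
  if (anyNA(concepts$concept_id) || any(concepts$concept_id <= 0)) {
    stop("drug lexicon error: concept_id must be a positive integer",
         call. = FALSE)
  }
  if (anyDuplicated(concepts$concept_id)) {
    stop("drug lexicon error: duplicate concept_id", call. = FALSE)
  }
  if (is.null(concepts$synonyms)) concepts$synonyms <- ""

  surfaces <- do.call(rbind, lapply(seq_len(nrow(concepts)), function(i) {
    syn <- strsplit(concepts$synonyms[i], "|", fixed = TRUE)[[1]]
    forms <- c(concepts$ingredient_name[i], concepts$brand_name[i], syn)
    forms <- forms[nzchar(trimws(forms))]
    data.frame(surface = norm_surface(forms),
               concept_id = concepts$concept_id[i])
  }))
  if (anyDuplicated(surfaces$surface)) {
    stop("drug lexicon error: duplicate surface form(s): ",
         paste(unique(surfaces$surface[duplicated(surfaces$surface)]),
               collapse = ", "), call. = FALSE)
  }
  structure(list(concepts = concepts, surfaces = surfaces),
            class = "drug_lexicon")
}

#' @export
print.drug_lexicon <- function(x, ...) {
  cat("<drug_lexicon> ", nrow(x$concepts), " concepts, ",
      nrow(x$surfaces), " surface forms\n", sep = "")
  invisible(x)
}

#' Immune checkpoint inhibitor lexicon
#'
#' The six FDA-approved immune checkpoint inhibitors (anti-CTLA-4 and
#' anti-PD-1/PD-L1 antibodies approved 2011-2017) with their OHDSI
#' ingredient/brand concept ids and early-development code names as
#' synonyms (e.g. MK-3475, the original designation of pembrolizumab, which
#' appears verbatim in spontaneous reports).
#'
#' @return a [drug_lexicon()].
#' @export
icb_lexicon <- function() {
  drug_lexicon(data.frame(
    concept_id = c(40238188L, 45775965L, 45892628L, 42629079L,
                   1594034L, 1593273L),
    ingredient_name = c("Ipilimumab", "Pembrolizumab", "Nivolumab",
                        "Atezolizumab", "Durvalumab", "Avelumab"),
    brand_name = c("Yervoy", "Keytruda", "Opdivo", "Tecentriq",
                   "Imfinzi", "Bavencio"),
    brand_concept_id = c(40238070L, 45775969L, 45892632L, 42629083L,
                         1594039L, 1593278L),
    synonyms = c("MDX-010", "MK-3475|lambrolizumab", "BMS-936558|ONO-4538",
                 "MPDL3280A", "MEDI4736", "MSB0010718C")
  ))
}

#' Map verbatim drug names to standard concept ids
#'
#' Matching is case-insensitive after trimming and collapsing internal
#' whitespace; ingredient, brand and synonym forms all resolve to the
#' ingredient concept id. Names with no lexicon entry get `NA` (the
#' unmapped marker) with the verbatim text preserved.
#'
#' @param drug_names character vector of verbatim drug names.
#' @param lexicon a [drug_lexicon()].
#' @return data frame with columns `verbatim` and `concept_id` (`NA` when
#'   unmapped).
#' @export
map_drug_names <- function(drug_names, lexicon) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  i <- match(norm_surface(drug_names), lexicon$surfaces$surface)
  data.frame(verbatim = as.character(drug_names),
             concept_id = lexicon$surfaces$concept_id[i])
}

# All surface forms of one concept, as printed (verbatim) strings.
concept_surface_forms <- function(lexicon, concept_id) {
  row <- lexicon$concepts[lexicon$concepts$concept_id == as.integer(concept_id), ]
  if (nrow(row) != 1L) {
    stop("unknown concept_id: ", concept_id, call. = FALSE)
  }
  syn <- strsplit(row$synonyms, "|", fixed = TRUE)[[1]]
  forms <- c(row$ingredient_name, row$brand_name, syn)
  forms[nzchar(trimws(forms))]
}
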