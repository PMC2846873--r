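# ICD-9-CM hierarchy: chapter and section resolution for inpatient main
# diagnoses. Chapter boundaries are the standard 17 disease chapters plus the
# V (factors influencing health status) and E (external causes) supplementary
# classifications; section ranges ship as a packaged lookup table.

.icd9_chapters <- data.frame(
  kind = c(rep("N", 17L), "V", "E"),
  lo = c(1, 140, 240, 280, 290, 320, 390, 460, 520, 580, 630, 680, 710,
         740, 760, 780, 800, 1, 0),
  hi = c(139, 239, 279, 289, 319, 389, 459, 519, 579, 629, 679, 709, 739,
         759, 779, 799, 999, 91, 999),
  chapter = c(
    "Infectious and parasitic diseases",
    "Neoplasms",
    "Endocrine, nutritional and metabolic diseases, and immunity disorders",
    "Diseases of the blood and blood-forming organs",
    "Mental disorders",
    "Diseases of the nervous system and sense organs",
    "Diseases of the circulatory system",
    "Diseases of the respiratory system",
    "Diseases of the digestive system",
    "Diseases of the genitourinary system",
    "Complications of pregnancy, childbirth, and the puerperium",
    "Diseases of the skin and subcutaneous tissue",
    "Diseases of the musculoskeletal system and connective tissue",
    "Congenital anomalies",
    "Certain conditions originating in the perinatal period",
    "Symptoms, signs, and ill-defined conditions",
    "Injury and poisoning",
    paste("Supplementary classification of factors influencing health",
          "status and contact with health services"),
    "Supplementary classification of external causes of injury and poisoning"
  ),
  stringsAsFactors = FALSE
)

.icd9_env <- new.env(parent = emptyenv())

#' ICD-9-CM section lookup table
#'
#' The packaged table of ICD-9-CM section code ranges (three-digit rubric
#' ranges within each chapter), used to roll a main diagnosis code up to its
#' section. V-code sections are grouped at the standard rubric ranges; E codes
#' are kept as a single supplementary section.
#'
#' @return a data.table with columns `kind` ("N", "V" or "E"), `lo`, `hi`
#'   (inclusive three-digit rubric bounds) and `section` (label).
#' @export
icd9_sections <- function() {
  if (is.null(.icd9_env$sections)) {
    path <- system.file("extdata", "icd9_sections.csv", package = "reportlife")
    .icd9_env$sections <- data.table::fread(path, colClasses = list(
      character = c("kind", "section"), integer = c("lo", "hi")))
  }
  data.table::copy(.icd9_env$sections)
}

# Split a code vector into (kind, rubric): "162.9" -> ("N", 162),
# "V58.1" -> ("V", 58), "E880.0" -> ("E", 880). Invalid codes -> NA kind.
.icd9_parse <- function(code) {
  code <- toupper(trimws(as.character(code)))
  head3 <- sub("\\..*$", "", code)
  kind <- rep(NA_character_, length(code))
  rubric <- rep(NA_integer_, length(code))
  is_v <- grepl("^V[0-9]{1,2}$", head3)
  is_e <- grepl("^E[0-9]{1,3}$", head3)
  is_n <- grepl("^[0-9]{1,3}$", head3)
  kind[is_v] <- "V"; kind[is_e] <- "E"; kind[is_n] <- "N"
  rubric[is_v | is_e] <- as.integer(sub("^[VE]", "", head3[is_v | is_e]))
  rubric[is_n] <- as.integer(head3[is_n])
  list(kind = kind, rubric = rubric)
}

.icd9_range_lookup <- function(code, table, value_col) {
  p <- .icd9_parse(code)
  out <- rep(NA_character_, length(code))
  ok <- !is.na(p$kind)
  if (any(ok)) {
    for (i in which(ok)) {
      hit <- table$kind == p$kind[i] &
        table$lo <= p$rubric[i] & table$hi >= p$rubric[i]
      if (any(hit)) out[i] <- table[[value_col]][which(hit)[1L]]
    }
  }
  out
}

#' Map ICD-9-CM codes to chapters or sections
#'
#' @param code character vector of ICD-9-CM codes ("162.9", "V58.1",
#'   "E880.0"); subcategory digits after the decimal point are ignored.
#' @return character vector of chapter (resp. section) labels; `NA` for codes
#'   that do not parse as ICD-9-CM.
#' @examples
#' icd9_chapter(c("162.9", "820.8", "V58.1"))
#' icd9_section("959.9")
#' @export
icd9_chapter <- function(code) {
  u <- unique(code)
  .icd9_range_lookup(u, .icd9_chapters, "chapter")[match(code, u)]
}

#' @rdname icd9_chapter
#' @export
icd9_section <- function(code) {
  u <- unique(code)
  .icd9_range_lookup(u, icd9_sections(), "section")[match(code, u)]
}
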