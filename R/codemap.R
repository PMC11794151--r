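## ICD-9 / ICD-10 hematological malignancy code map. Matching is by
## longest normalized prefix (dots stripped), so "C92.01" hits the "C920"
## entry before "C92". The shipped default is user-overridable via YAML
## (see read_codemap).

#' Default hematological-malignancy ICD code map
#'
#' Maps ICD-9 and ICD-10/10-CM code prefixes to a canonical malignancy
#' group, a hematological-malignancy (HM) flag and a myeloid-malignancy
#' (MM) flag. HM covers ICD-10 C81-C96 and D45-D47 (ICD-9 200-208,
#' 238.7x); the MM subset is C92-C94, D45, D46, D47.1, D47.3 (ICD-9
#' 205-206, 238.72-238.75). Institutional code lists vary; supply your
#' own map to [map_icd_code()] where needed.
#'
#' @return Data frame with columns `icd_version` (`"9"` or `"10"`;
#'   `"10CM"` shares the `"10"` entries), `prefix` (normalized, no dots),
#'   `group`, `is_HM`, `is_MM`.
#' @export
default_codemap <- function() {
  e <- function(version, prefix, group, mm)
    data.frame(icd_version = version, prefix = prefix, group = group,
               is_HM = TRUE, is_MM = mm, stringsAsFactors = FALSE)
  rbind(
    e("10", "C81", "HL", FALSE),
    e("10", "C82", "NHL", FALSE),
    e("10", "C83", "NHL", FALSE),
    e("10", "C833", "DLBCL", FALSE),
    e("10", "C84", "NHL", FALSE),
    e("10", "C85", "NHL", FALSE),
    e("10", "C86", "NHL", FALSE),
    e("10", "C88", "NHL", FALSE),
    e("10", "C90", "PCM", FALSE),
    e("10", "C91", "ALL_CLL", FALSE),
    e("10", "C92", "AML", TRUE),
    e("10", "C93", "CMML", TRUE),
    e("10", "C94", "OTHER_MYELOID", TRUE),
    e("10", "C95", "LEUKEMIA_NOS", FALSE),
    e("10", "C96", "OTHER_HM", FALSE),
    e("10", "D45", "PV", TRUE),
    e("10", "D46", "MDS", TRUE),
    e("10", "D47", "OTHER_HM", FALSE),
    e("10", "D471", "MPN", TRUE),
    e("10", "D473", "ET", TRUE),
    e("9", "200", "NHL", FALSE),
    e("9", "201", "HL", FALSE),
    e("9", "202", "NHL", FALSE),
    e("9", "203", "PCM", FALSE),
    e("9", "204", "ALL_CLL", FALSE),
    e("9", "205", "AML", TRUE),
    e("9", "206", "OTHER_MYELOID", TRUE),
    e("9", "207", "OTHER_MYELOID", TRUE),
    e("9", "208", "LEUKEMIA_NOS", FALSE),
    e("9", "2387", "OTHER_HM", FALSE),
    e("9", "23872", "MDS", TRUE),
    e("9", "23873", "MDS", TRUE),
    e("9", "23874", "MDS", TRUE),
    e("9", "23875", "MDS", TRUE),
    e("9", "23876", "MPN", TRUE)
  )
}

normalize_icd <- function(code) gsub("[. ]", "", toupper(trimws(code)))

#' Map one ICD code to a malignancy group
#'
#' Longest-prefix match of the normalized code (dots stripped) against a
#' code map. Codes not matching any entry — anything that is not a
#' hematological malignancy — return `NULL`.
#'
#' @param code ICD code string (e.g. `"C92.0"`).
#' @param icd_version 9, 10 or `"10CM"` (10-CM uses the ICD-10 entries).
#' @param codemap Code map data frame, see [default_codemap()].
#' @return `NULL`, or a list with `group`, `is_HM`, `is_MM`.
#' @export
#' @examples
#' map_icd_code("C92.0", 10)  # AML: HM and MM
#' map_icd_code("C83.3", 10)  # DLBCL: HM, not MM
#' map_icd_code("I10", 10)    # NULL
map_icd_code <- function(code, icd_version, codemap = default_codemap()) {
  v <- as.character(icd_version)
  if (v == "10CM") v <- "10"
  if (!v %in% c("9", "10"))
    stop("unknown ICD version: ", icd_version)
  code <- normalize_icd(code)
  cand <- codemap[codemap$icd_version == v &
                  startsWith(code, codemap$prefix), , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  hit <- cand[which.max(nchar(cand$prefix)), ]
  list(group = hit$group, is_HM = hit$is_HM, is_MM = hit$is_MM)
}

map_icd_codes <- function(codes, versions, codemap = default_codemap()) {
  res <- mapply(function(c, v) {
    m <- map_icd_code(c, v, codemap)
    if (is.null(m)) c(NA_character_, NA, NA)
    else c(m$group, m$is_HM, m$is_MM)
  }, codes, versions, SIMPLIFY = TRUE, USE.NAMES = FALSE)
  data.frame(group = res[1, ],
             is_HM = as.logical(res[2, ]),
             is_MM = as.logical(res[3, ]),
             stringsAsFactors = FALSE)
}
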