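#' @name acmg
#' @title Points-based ClinGen/ACMG/AMP classification engine
#' @description Evidence codes carry integer point weights: very strong +8,
#'   strong +4, moderate +2, supporting +1 for pathogenic evidence;
#'   stand-alone -8, strong -4, moderate -2, supporting -1 for benign
#'   evidence. Point totals map to classes: B (<= -7), LB (-6 to -2),
#'   VUS (-1 to +5), LP (+6 to +9), P (>= +10). Functional evidence from
#'   the integrated models enters as PS3/BS3 with strength set by the
#'   seven-level category, structurally capped at +/-4 (strong).
NULL

STRENGTH_MAGNITUDE <- c(very_strong = 8L, strong = 4L, moderate = 2L,
                        supporting = 1L, stand_alone = 8L)
STRENGTH_SUFFIX <- c(VeryStrong = "very_strong", Strong = "strong",
                     Moderate = "moderate", Supporting = "supporting",
                     StandAlone = "stand_alone")

code_base <- function(code) {
  sub("_(VeryStrong|Strong|Moderate|Supporting|StandAlone)$", "", code)
}

default_strength <- function(base) {
  ifelse(startsWith(base, "PVS"), "very_strong",
  ifelse(startsWith(base, "PS"), "strong",
  ifelse(startsWith(base, "PM"), "moderate",
  ifelse(startsWith(base, "PP"), "supporting",
  ifelse(startsWith(base, "BA"), "stand_alone",
  ifelse(startsWith(base, "BS"), "strong",
  ifelse(startsWith(base, "BP"), "supporting", NA_character_)))))))
}

#' Construct an evidence code with its point weight
#'
#' @param code code identifier, optionally carrying a strength-modulation
#'   suffix (e.g. `PM2_Supporting`, `PS3_Moderate`, `BP7_Strong`). Without
#'   a suffix the canonical strength of the code's prefix applies
#'   (PVS very strong, PS/BS strong, PM moderate, PP/BP supporting,
#'   BA stand-alone).
#' @param source `"derived"` (computed here) or `"preassigned"`
#'   (externally supplied).
#' @return one-row data frame: `code`, `strength`, `points`, `source`.
#' @export
evidence_code <- function(code, source = "derived") {
  base <- code_base(code)
  suffix <- sub("^.*_", "", code)
  strength <- if (code != base && suffix %in% names(STRENGTH_SUFFIX)) {
    STRENGTH_SUFFIX[[suffix]]
  } else {
    default_strength(base)
  }
  if (is.na(strength)) stop("unrecognised evidence code: ", code)
  sign <- if (startsWith(base, "B")) -1L else 1L
  data.frame(code = code, strength = strength,
             points = sign * STRENGTH_MAGNITUDE[[strength]],
             source = source, stringsAsFactors = FALSE)
}

#' Functional evidence code from a seven-level category
#'
#' Maps the integrated model's strength category to PS3/BS3 at matching
#' strength: `P_Strong` +4, `P_Moderate` +2, `P_Supporting` +1,
#' `B_Supporting` -1, `B_Moderate` -2, `B_Strong` -4. The cap at +/-4 is
#' structural: no category maps beyond strong. `Uncertain` yields no code.
#'
#' @param category a single category from [CATEGORY_LEVELS] (or `NA`).
#' @return an evidence-code row, or `NULL`.
#' @export
functional_evidence <- function(category) {
  if (is.na(category) || category == "Uncertain") return(NULL)
  map <- c(P_Strong = "PS3", P_Moderate = "PS3_Moderate",
           P_Supporting = "PS3_Supporting",
           B_Strong = "BS3", B_Moderate = "BS3_Moderate",
           B_Supporting = "BS3_Supporting")
  if (!category %in% names(map)) stop("unknown category: ", category)
  evidence_code(map[[category]])
}

#' Population-frequency evidence code
#'
#' Filter allele frequency above 0.001 triggers stand-alone benign BA1;
#' above 0.0001, strong benign BS1; above 0.00002, supporting benign
#' BS1_Supporting. Absence from the population (missing or zero FAF)
#' triggers PM2_Supporting. A present sub-threshold frequency yields no
#' code (absence and sub-threshold presence are treated as mutually
#' exclusive states).
#'
#' @param faf filter allele frequency in `[0, 1]`, or `NA` when the
#'   variant is absent from the population resource.
#' @return an evidence-code row, or `NULL`.
#' @export
frequency_evidence <- function(faf) {
  if (is.na(faf) || faf == 0) return(evidence_code("PM2_Supporting"))
  if (faf < 0 || faf > 1) stop("faf must lie in [0, 1]")
  if (faf > 0.001) return(evidence_code("BA1"))
  if (faf > 0.0001) return(evidence_code("BS1"))
  if (faf > 0.00002) return(evidence_code("BS1_Supporting"))
  NULL
}

#' In-silico prediction evidence code
#'
#' BayesDel >= 0.3 triggers PP3_Moderate; otherwise a SpliceAI flag
#' triggers supporting PP3; otherwise BayesDel at or below the benign
#' cutoff with no splice flag triggers BP4. The benign cutoff default
#' (0.15) is an externally sourced expert-panel value, configurable.
#'
#' @param bayesdel BayesDel score or `NA`.
#' @param spliceai_flag logical splice-prediction flag (`NA` treated as
#'   `FALSE`).
#' @param bp4_cutoff BayesDel threshold at or below which BP4 applies.
#' @return an evidence-code row, or `NULL`.
#' @export
insilico_evidence <- function(bayesdel, spliceai_flag = FALSE,
                              bp4_cutoff = 0.15) {
  if (is.na(spliceai_flag)) spliceai_flag <- FALSE
  if (!is.na(bayesdel) && bayesdel >= 0.3) return(evidence_code("PP3_Moderate"))
  if (spliceai_flag) return(evidence_code("PP3"))
  if (!is.na(bayesdel) && bayesdel <= bp4_cutoff) return(evidence_code("BP4"))
  NULL
}

#' Loss-of-function evidence code
#'
#' Nonsense and canonical-splice variants default to very-strong PVS1
#' (+8); expert-panel decision-tree modulation arrives as a preassigned
#' strength instead.
#'
#' @param consequence consequence class string.
#' @return an evidence-code row, or `NULL`.
#' @export
pvs1_evidence <- function(consequence) {
  if (consequence %in% c("nonsense", "canonical_splice")) {
    return(evidence_code("PVS1"))
  }
  NULL
}

#' Parse a semicolon-separated preassigned-code string
#'
#' @param s e.g. `"PS1;PP4_Moderate"`; empty or `NA` yields no codes.
#' @return data frame of evidence-code rows (possibly empty).
#' @export
parse_preassigned <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  toks <- strsplit(s, ";", fixed = TRUE)[[1]]
  toks <- trimws(toks[nzchar(trimws(toks))])
  if (!length(toks)) return(NULL)
  do.call(rbind, lapply(toks, evidence_code, source = "preassigned"))
}

# mutually exclusive code families; at most one member may apply
EXCLUSIVE_FAMILIES <- list(
  functional = c("PS3", "BS3"),
  frequency = c("BA1", "BS1", "PM2"),
  insilico = c("PP3", "BP4")
)

#' Assemble and validate the evidence profile for one variant
#'
#' Derives the in-scope codes (PVS1, frequency, in-silico, and — when a
#' functional category is given — PS3/BS3), merges externally preassigned
#' codes, enforces the mutual-exclusion invariants, and sums points.
#'
#' @param variant one-row data frame or list with `variant_id`,
#'   `consequence`, `faf`, `bayesdel`, `spliceai_flag`,
#'   `preassigned_codes`.
#' @param category functional category (or `NA` to omit functional
#'   evidence).
#' @param include_functional include the PS3/BS3 code (default `TRUE`).
#' @param bp4_cutoff passed to [insilico_evidence()].
#' @return an object of class `evidence_profile`: list with `variant_id`,
#'   `codes` (data frame), `total_points`.
#' @export
build_evidence_profile <- function(variant, category = NA,
                                   include_functional = TRUE,
                                   bp4_cutoff = 0.15) {
  faf <- variant$faf
  if (is.null(faf)) faf <- NA_real_
  codes <- list(
    pvs1_evidence(variant$consequence),
    if (include_functional) functional_evidence(category),
    frequency_evidence(faf),
    insilico_evidence(
      if (is.null(variant$bayesdel)) NA_real_ else variant$bayesdel,
      if (is.null(variant$spliceai_flag)) FALSE else variant$spliceai_flag,
      bp4_cutoff),
    parse_preassigned(
      if (is.null(variant$preassigned_codes)) "" else variant$preassigned_codes)
  )
  codes <- do.call(rbind, codes[!vapply(codes, is.null, logical(1))])
  if (is.null(codes)) {
    codes <- data.frame(code = character(0), strength = character(0),
                        points = integer(0), source = character(0))
  }
  bases <- code_base(codes$code)
  for (fam in EXCLUSIVE_FAMILIES) {
    hit <- codes$code[bases %in% fam]
    if (length(hit) > 1L) {
      stop("mutually exclusive evidence codes applied to ",
           variant$variant_id, ": ", paste(hit, collapse = ", "))
    }
  }
  structure(list(variant_id = variant$variant_id, codes = codes,
                 total_points = sum(codes$points)),
            class = "evidence_profile")
}

#' Map a point total to the clinical class
#'
#' @param points integer point total(s).
#' @return character vector: `B` (<= -7), `LB` (-6..-2), `VUS` (-1..5),
#'   `LP` (6..9), `P` (>= 10).
#' @export
classify_points <- function(points) {
  ifelse(points >= 10, "P",
  ifelse(points >= 6, "LP",
  ifelse(points >= -1, "VUS",
  ifelse(points >= -6, "LB", "B"))))
}

#' Classify one variant from its evidence profile
#'
#' The class follows from the point total alone, unless the functional
#' category's side conflicts with a ClinVar standard or HDR label for the
#' variant, in which case the final class is `VUS_discordant` (the
#' variant is withheld from P/B classification). The override requires a
#' standards label and an opposite-side functional call; an `Uncertain`
#' call never triggers it.
#'
#' @param profile an `evidence_profile` from [build_evidence_profile()].
#' @param category functional category used for the override check (`NA`
#'   to skip).
#' @param clinvar_standard `"P/LP"`, `"B/LB"` or `"none"`.
#' @param hdr_standard `"abnormal"`, `"normal"` or `"none"`.
#' @return list with `variant_id`, `class`, `total_points`, `rationale`.
#' @export
classify_variant <- function(profile, category = NA,
                             clinvar_standard = "none",
                             hdr_standard = "none") {
  cls <- classify_points(profile$total_points)
  side <- if (is.na(category)) NA_character_ else category_side(category)
  conflict <- !is.na(side) && (
    (side == "P" && (clinvar_standard == "B/LB" || hdr_standard == "normal")) ||
    (side == "B" && (clinvar_standard == "P/LP" || hdr_standard == "abnormal"))
  )
  if (conflict) cls <- "VUS_discordant"
  rationale <- if (nrow(profile$codes)) {
    paste(sprintf("%s(%+d)", profile$codes$code, profile$codes$points),
          collapse = ";")
  } else ""
  list(variant_id = profile$variant_id, class = cls,
       total_points = profile$total_points, rationale = rationale)
}

#' Classify every variant with and without functional evidence
#'
#' Runs the points-based classifier twice per variant — once including
#' the PS3/BS3 code from its functional call (with the VUS(discordant)
#' override active) and once without any functional evidence — and
#' summarises class counts and the classified fraction (variants reaching
#' P/LP or B/LB; `VUS_discordant` counts as VUS).
#'
#' @param variants variant table (see [build_evidence_profile()] fields,
#'   plus `clinvar_standard`, `hdr_standard`).
#' @param calls call table with `variant_id` and `category`; variants
#'   without a call are classified without functional evidence.
#' @param bp4_cutoff passed to [insilico_evidence()].
#' @return list with `classifications` (data frame: `variant_id`,
#'   `class_with_functional`, `class_without_functional`, `points_with`,
#'   `points_without`, `codes_applied`) and `summary` (class count tables
#'   and classified fractions for both runs).
#' @export
run_classification <- function(variants, calls, bp4_cutoff = 0.15) {
  cat_of <- calls$category[match(variants$variant_id, calls$variant_id)]
  n_missing <- sum(is.na(cat_of))
  if (n_missing > 0) {
    message(n_missing, " variant(s) lack a functional call; ",
            "classified without functional evidence")
  }
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    pw <- build_evidence_profile(v, cat_of[i], include_functional = TRUE,
                                 bp4_cutoff = bp4_cutoff)
    po <- build_evidence_profile(v, NA, include_functional = FALSE,
                                 bp4_cutoff = bp4_cutoff)
    cw <- classify_variant(pw, cat_of[i], v$clinvar_standard, v$hdr_standard)
    co <- classify_variant(po, NA)
    data.frame(variant_id = v$variant_id,
               class_with_functional = cw$class,
               class_without_functional = co$class,
               points_with = cw$total_points, points_without = co$total_points,
               codes_applied = cw$rationale, stringsAsFactors = FALSE)
  })
  cls <- do.call(rbind, rows)
  lv <- c("P", "LP", "VUS", "VUS_discordant", "LB", "B")
  classified <- function(x) mean(x %in% c("P", "LP", "LB", "B"))
  list(
    classifications = cls,
    summary = list(
      counts_with = table(factor(cls$class_with_functional, lv)),
      counts_without = table(factor(cls$class_without_functional, lv)),
      classified_fraction_with = classified(cls$class_with_functional),
      classified_fraction_without = classified(cls$class_without_functional),
      n_missing_call = n_missing
    )
  )
}
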