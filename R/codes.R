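#' Medication vocabulary used throughout the package
#'
#' The feature space tracks 29 DMARD indicator variables and 8 corticosteroid
#' indicator variables, one per medication code. Real extracts map local drug
#' names onto these codes; the synthetic generator emits them directly. Codes
#' `DMARD_01`..`DMARD_15` are conventional synthetic DMARDs, `DMARD_16`..
#' `DMARD_28` biologics and `DMARD_29` tofacitinib (a targeted synthetic
#' DMARD); `CS_01`..`CS_08` are corticosteroids, with `CS_01` labelled
#' prednisone.
#'
#' @return a data.frame with columns `med_code`, `med_class` and `label`.
#' @export
#' @examples
#' table(medication_codes()$med_class)
medication_codes <- function() {
  dmard <- sprintf("DMARD_%02d", 1:29)
  cs <- sprintf("CS_%02d", 1:8)
  data.frame(
    med_code = c(dmard, cs),
    med_class = c(rep("csDMARD", 15), rep("biologic", 13), "tofacitinib",
                  rep("corticosteroid", 8)),
    label = c(dmard, "prednisone", cs[-1]),
    stringsAsFactors = FALSE
  )
}

MED_CLASSES <- c("csDMARD", "biologic", "tofacitinib", "corticosteroid")
DMARD_CLASSES <- c("csDMARD", "biologic", "tofacitinib")
RACE_LEVELS <- c("white", "african_american", "hispanic", "asian", "other")
QUALIFYING_ICD9 <- c("714.0", "714.1", "714.2")
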