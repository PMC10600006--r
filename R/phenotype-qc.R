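#' Phenotype quality-control rules
#'
#' Bounds and adjustment constants for biometric QC: plausible height
#' (100-200 cm) and weight (25-300 kg) ranges, blood-pressure pair
#' concordance (two readings must not differ by more than 20 units),
#' absolute BP bounds (30-300), the treated-hypertension adjustment
#' (+15 systolic / +10 diastolic) and the 140/90 case cutoff.
#'
#' @param height_bounds,weight_bounds Length-2 numeric bounds.
#' @param bp_pair_diff Maximum tolerated difference between the two
#'   readings of the same pressure.
#' @param bp_bounds Absolute plausible BP range.
#' @param treated_sbp_add,treated_dbp_add Units added for treated
#'   individuals when forming adjusted BP phenotypes.
#' @param htn_sbp,htn_dbp Case-definition cutoffs.
#' @return A `qc_rules` list.
#' @export
qc_rules <- function(height_bounds = c(100, 200), weight_bounds = c(25, 300),
                     bp_pair_diff = 20, bp_bounds = c(30, 300),
                     treated_sbp_add = 15, treated_dbp_add = 10,
                     htn_sbp = 140, htn_dbp = 90) {
  stopifnot(height_bounds[1] < height_bounds[2],
            weight_bounds[1] < weight_bounds[2],
            bp_bounds[1] < bp_bounds[2])
  structure(list(height_bounds = height_bounds, weight_bounds = weight_bounds,
                 bp_pair_diff = bp_pair_diff, bp_bounds = bp_bounds,
                 treated_sbp_add = treated_sbp_add,
                 treated_dbp_add = treated_dbp_add,
                 htn_sbp = htn_sbp, htn_dbp = htn_dbp),
            class = "qc_rules")
}

#' Apply phenotype quality control
#'
#' QC never aborts and never silently drops: every removed value is
#' replaced by `NA` in the returned table and logged with a reason code in
#' the `qc_log` attribute, so removed + retained = input for each field.
#' Rules applied: height/weight bounds; negative biochemical values
#' (`glucose`, `cholesterol`, `triglycerides`, `hdl`, `ldl`, `creatinine`)
#' removed; blood-pressure readings failing absolute bounds or with
#' diastolic above systolic removed individually; pairs of readings
#' differing by more than the pair bound have the second (unverifiable)
#' reading removed. Final `sbp`/`dbp` columns take the first valid
#' reading, else the second.
#'
#' @param raw Data frame with an `individual` column; recognised columns
#'   among `height`, `weight`, the biochemical traits, and BP reading
#'   pairs `sbp1`, `sbp2`, `dbp1`, `dbp2`.
#' @param rules A [qc_rules()].
#' @return The QC'd data frame with attribute `qc_log` (a data frame of
#'   `individual`, `field`, `value`, `reason`).
#' @export
phenotype_qc <- function(raw, rules = qc_rules()) {
  stopifnot(is.data.frame(raw), "individual" %in% names(raw),
            inherits(rules, "qc_rules"))
  tab <- raw
  log <- list()
  drop_vals <- function(field, bad, reason) {
    bad <- which(bad)
    if (length(bad)) {
      log[[length(log) + 1L]] <<- data.frame(
        individual = tab$individual[bad], field = field,
        value = tab[[field]][bad], reason = reason)
      tab[[field]][bad] <<- NA
    }
  }
  if ("height" %in% names(tab)) {
    drop_vals("height", !is.na(tab$height) &
              (tab$height < rules$height_bounds[1] |
               tab$height > rules$height_bounds[2]), "bounds")
  }
  if ("weight" %in% names(tab)) {
    drop_vals("weight", !is.na(tab$weight) &
              (tab$weight < rules$weight_bounds[1] |
               tab$weight > rules$weight_bounds[2]), "bounds")
  }
  for (field in intersect(c("glucose", "cholesterol", "triglycerides",
                            "hdl", "ldl", "creatinine"), names(tab))) {
    drop_vals(field, !is.na(tab[[field]]) & tab[[field]] < 0, "negative")
  }
  bp_cols <- c("sbp1", "sbp2", "dbp1", "dbp2")
  if (all(bp_cols %in% names(tab))) {
    for (r in 1:2) {
      s <- paste0("sbp", r)
      d <- paste0("dbp", r)
      drop_vals(s, !is.na(tab[[s]]) &
                (tab[[s]] < rules$bp_bounds[1] | tab[[s]] > rules$bp_bounds[2]),
                "bp_bounds")
      drop_vals(d, !is.na(tab[[d]]) &
                (tab[[d]] < rules$bp_bounds[1] | tab[[d]] > rules$bp_bounds[2]),
                "bp_bounds")
      inverted <- !is.na(tab[[s]]) & !is.na(tab[[d]]) & tab[[d]] > tab[[s]]
      drop_vals(s, inverted, "dbp_above_sbp")
      drop_vals(d, inverted, "dbp_above_sbp")
    }
    for (pfx in c("sbp", "dbp")) {
      a <- tab[[paste0(pfx, "1")]]
      b <- tab[[paste0(pfx, "2")]]
      disc <- !is.na(a) & !is.na(b) & abs(a - b) > rules$bp_pair_diff
      drop_vals(paste0(pfx, "2"), disc, "pair_discordant")
    }
    tab$sbp <- ifelse(!is.na(tab$sbp1), tab$sbp1, tab$sbp2)
    tab$dbp <- ifelse(!is.na(tab$dbp1), tab$dbp1, tab$dbp2)
  }
  qc_log <- if (length(log)) do.call(rbind, log) else
    data.frame(individual = character(0), field = character(0),
               value = numeric(0), reason = character(0))
  attr(tab, "qc_log") <- qc_log
  tab
}

#' Define binary hypertension outcomes and adjusted blood pressure
#'
#' `hypertension_1` is the diagnosis-only definition; `hypertension_2`
#' additionally counts medication use or a blood pressure reading above
#' the 140/90 cutoff as a case. Questionnaire responses other than
#' yes/no ("do not know", "prefer not to answer", "no response") leave
#' case-control status missing. For individuals on antihypertensive
#' treatment the adjusted phenotypes `sbp_adj`/`dbp_adj` add 15 and 10
#' units respectively.
#'
#' @param tab QC'd phenotype table with columns `sbp`, `dbp` and
#'   optionally `htn_diagnosis` (character yes/no/other) and
#'   `bp_medication` (logical or yes/no).
#' @param rules A [qc_rules()].
#' @return `tab` with added columns `hypertension_1`, `hypertension_2`,
#'   `sbp_adj`, `dbp_adj`.
#' @export
define_outcomes <- function(tab, rules = qc_rules()) {
  stopifnot(is.data.frame(tab), inherits(rules, "qc_rules"))
  yes_no <- function(x) {
    if (is.logical(x)) return(x)
    x <- tolower(as.character(x))
    out <- rep(NA, length(x))
    out[x %in% c("yes", "1", "true")] <- TRUE
    out[x %in% c("no", "0", "false")] <- FALSE
    out
  }
  dx <- if ("htn_diagnosis" %in% names(tab)) yes_no(tab$htn_diagnosis)
        else rep(NA, nrow(tab))
  med <- if ("bp_medication" %in% names(tab)) yes_no(tab$bp_medication)
         else rep(NA, nrow(tab))
  high_bp <- tab$sbp > rules$htn_sbp | tab$dbp > rules$htn_dbp
  tab$hypertension_1 <- dx
  # case if any criterion is met; control only when all known criteria say no
  h2 <- ifelse(!is.na(dx) & dx, TRUE,
        ifelse(!is.na(med) & med, TRUE,
        ifelse(!is.na(high_bp) & high_bp, TRUE,
        ifelse(is.na(dx), NA, FALSE))))
  tab$hypertension_2 <- h2
  treated <- !is.na(med) & med
  tab$sbp_adj <- tab$sbp + ifelse(treated, rules$treated_sbp_add, 0)
  tab$dbp_adj <- tab$dbp + ifelse(treated, rules$treated_dbp_add, 0)
  tab
}
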