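#' Per-patient quartile thresholds of a damage signal
#'
#' Lower quartile, median and upper quartile of a patient's pooled fiber
#' damage values (all fields pooled), computed by linear interpolation
#' between order statistics (the inclusive "type 7" convention by
#' default). The convention is configurable because class membership of
#' boundary fibers depends on it.
#'
#' @param values Numeric vector of fiber damage values (gsu); at least 4.
#' @param patient_id,marker Identifiers stored with the thresholds;
#'   `marker` is `"carbonyl"` or `"hne"`.
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return A `quartile_thresholds` list: `lower_quartile`, `median`,
#'   `upper_quartile`, `marker`, `patient_id`.
#' @export
quartile_thresholds <- function(values, patient_id = NA_character_,
                                marker = c("carbonyl", "hne"), type = 7) {
  marker <- match.arg(marker)
  values <- values[!is.na(values)]
  if (length(values) < 4)
    stop("fewer than 4 fiber values for patient ", patient_id,
         ": quartile classes are undefined")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = type))
  structure(list(lower_quartile = q[1], median = q[2], upper_quartile = q[3],
                 marker = marker, patient_id = patient_id),
            class = "quartile_thresholds")
}

#' Assign fibers to quartile classes Q1-Q4
#'
#' Class rules: Q1 holds all fibers at or below the lower quartile; Q2
#' those at or below the median and above the lower quartile; Q3 those at
#' or below the upper quartile and above the median; Q4 those above the
#' upper quartile. Fibers equal to a threshold fall in the lower class.
#'
#' @param values Numeric vector of fiber damage values.
#' @param thresholds A [quartile_thresholds()].
#' @return Factor with levels `Q1`..`Q4`, one per fiber.
#' @export
assign_classes <- function(values, thresholds) {
  cls <- ifelse(values <= thresholds$lower_quartile, "Q1",
         ifelse(values <= thresholds$median, "Q2",
         ifelse(values <= thresholds$upper_quartile, "Q3", "Q4")))
  factor(cls, levels = c("Q1", "Q2", "Q3", "Q4"))
}

#' Mean CSA per quartile class
#'
#' @param csa_um2 Numeric vector of fiber cross-sectional areas.
#' @param classes Factor from [assign_classes()], same length.
#' @return Data frame with one row per class (`Q1`..`Q4`): `class`,
#'   `n_fibers`, `mean_csa_um2`. Empty classes have `NA` mean (missing,
#'   not zero, so repeated-measures models drop them).
#' @export
class_csa_means <- function(csa_um2, classes) {
  stopifnot(length(csa_um2) == length(classes))
  n <- as.integer(table(classes))
  m <- tapply(csa_um2, classes, mean)
  data.frame(class = levels(classes), n_fibers = n,
             mean_csa_um2 = as.numeric(m), stringsAsFactors = FALSE)
}

#' Quartile-class table for a cohort
#'
#' For every patient and marker: pools the patient's fibers across fields,
#' computes the damage quartile thresholds, assigns each fiber to
#' Q1-Q4 and records the per-class fiber counts and mean CSA.
#'
#' @param measurements Fiber table with `patient_id`, `csa_um2`,
#'   `carbonyl_gsu`, `hne_gsu`.
#' @param metadata Optional patient metadata; when given, `group` is
#'   joined onto the result.
#' @param markers Damage markers to stratify by.
#' @param type Quantile convention (see [quartile_thresholds()]).
#' @return Long data frame: `patient_id`, `marker`, `class`, `n_fibers`,
#'   `mean_csa_um2` (+ `group` if `metadata` given).
#' @export
quartile_table <- function(measurements, metadata = NULL,
                           markers = c("carbonyl", "hne"), type = 7) {
  rows <- list()
  for (pid in unique(measurements$patient_id)) {
    mm <- measurements[measurements$patient_id == pid, , drop = FALSE]
    for (mk in markers) {
      v <- mm[[paste0(mk, "_gsu")]]
      thr <- quartile_thresholds(v, pid, mk, type = type)
      tab <- class_csa_means(mm$csa_um2, assign_classes(v, thr))
      rows[[length(rows) + 1]] <- cbind(patient_id = pid, marker = mk, tab)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(metadata))
    out$group <- metadata$group[match(out$patient_id, metadata$patient_id)]
  out
}
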