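#' Estimate the background level of a channel
#'
#' The field background (near the black level of the camera) that is
#' subtracted from per-fiber mean intensities. `extracellular_median`
#' takes the median over label-0 (extracellular) pixels; `fixed` returns a
#' configured constant.
#'
#' For the carbonyl channel the extracellular compartment carries genuine
#' signal (oxidative damage in the extracellular matrix is detected as
#' carbonyl groups), so the extracellular median *over-corrects* that
#' marker: use `method = "fixed"` with the camera black level for
#' carbonyl. HNE is absent from the extracellular matrix, so the
#' extracellular median is an unbiased background estimate for HNE.
#'
#' For a [label_map()] produced by [segment_fibers()] the extracellular
#' median is taken over the pixels the algorithm classified as membrane:
#' plain label-0 pixels also cover the interiors of size- or edge-filtered
#' fibers, whose intracellular signal does not belong in a background
#' estimate. A bare label matrix falls back to all label-0 pixels.
#'
#' @param channel Numeric matrix (gsu).
#' @param label_map A [label_map()] (or integer matrix) aligned to
#'   `channel`.
#' @param method `"extracellular_median"` or `"fixed"`.
#' @param fixed_value Background in gsu when `method = "fixed"`.
#' @return Background level in gsu (>= 0).
#' @export
estimate_background <- function(channel, label_map,
                                method = c("extracellular_median", "fixed"),
                                fixed_value = 0) {
  method <- match.arg(method)
  if (method == "fixed") {
    stopifnot(fixed_value >= 0)
    return(fixed_value)
  }
  mask <- NULL
  if (inherits(label_map, "label_map")) {
    mask <- label_map$membrane_mask
    lab <- label_map$labels
  } else lab <- label_map
  stopifnot(identical(dim(lab), dim(channel)))
  if (is.null(mask)) mask <- lab == 0
  if (!any(mask)) stop("no extracellular (label-0) pixels to estimate background")
  max(median(channel[mask]), 0)
}

#' Measure per-fiber signal and cross-sectional area
#'
#' For every labeled fiber: background-corrected mean carbonyl and HNE
#' intensity (mean over fiber pixels minus the per-channel background;
#' negative corrected means are kept as-is, preserving unbiased group
#' means) and cross-sectional area (pixel count times pixel area).
#'
#' @param stack An [image_stack()].
#' @param label_map A [label_map()] aligned to the stack.
#' @param background_carbonyl,background_hne Per-channel background in gsu
#'   (>= 0), e.g. from [estimate_background()].
#' @param patient_id,field_id Identifiers attached to the rows.
#' @return Data frame with columns `patient_id`, `field_id`, `fiber_id`,
#'   `csa_um2`, `carbonyl_gsu`, `hne_gsu`; empty for an empty label map.
#' @export
measure_fibers <- function(stack, label_map, background_carbonyl,
                           background_hne, patient_id = NA_character_,
                           field_id = NA_character_) {
  stopifnot(background_carbonyl >= 0, background_hne >= 0)
  lab <- if (inherits(label_map, "label_map")) label_map$labels else label_map
  stopifnot(identical(dim(lab), dim(stack$carbonyl)))
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids))
    return(data.frame(patient_id = character(), field_id = character(),
                      fiber_id = integer(), csa_um2 = numeric(),
                      carbonyl_gsu = numeric(), hne_gsu = numeric()))
  inside <- lab > 0
  g <- lab[inside]
  npx <- tabulate(g)[ids]
  car <- rowsum(stack$carbonyl[inside], g)[, 1] / npx
  hne <- rowsum(stack$hne[inside], g)[, 1] / npx
  data.frame(
    patient_id = patient_id, field_id = field_id, fiber_id = ids,
    csa_um2 = npx * stack$pixel_size_um^2,
    carbonyl_gsu = unname(car) - background_carbonyl,
    hne_gsu = unname(hne) - background_hne,
    stringsAsFactors = FALSE
  )
}

#' Measure one field end to end
#'
#' Convenience wrapper: estimates per-channel backgrounds with the
#' recommended defaults (fixed camera black for carbonyl, extracellular
#' median for HNE) and measures all fibers.
#'
#' @param stack An [image_stack()].
#' @param label_map A [label_map()].
#' @param camera_black_gsu Camera black level used for the carbonyl
#'   background.
#' @inheritParams measure_fibers
#' @return See [measure_fibers()].
#' @export
measure_field <- function(stack, label_map, camera_black_gsu,
                          patient_id = NA_character_,
                          field_id = NA_character_) {
  bg_hne <- estimate_background(stack$hne, label_map, "extracellular_median")
  measure_fibers(stack, label_map,
                 background_carbonyl = camera_black_gsu,
                 background_hne = bg_hne,
                 patient_id = patient_id, field_id = field_id)
}

#' Pool a specimen's fibers into one summary
#'
#' Fiber-weighted pooling across all of a specimen's fields: every fiber
#' counts once, fields are not averaged first (the mean of all myofibers
#' in the specimen). Attaches the patient's clinical attributes.
#'
#' @param measurements Fiber table (rows of one patient) as returned by
#'   [measure_fibers()] or built from ground truth.
#' @param patient_record One-row data frame with `patient_id`, `group`,
#'   `fontaine_stage`, `abi`, `cad`, `htn`.
#' @return One-row data frame: clinical attributes plus `n_fibers`,
#'   `mean_carbonyl_gsu`, `mean_hne_gsu`, `mean_csa_um2`.
#' @export
summarize_specimen <- function(measurements, patient_record) {
  if (nrow(measurements) == 0)
    stop("zero fibers for specimen ", patient_record$patient_id)
  data.frame(
    patient_id = patient_record$patient_id,
    group = patient_record$group,
    fontaine_stage = patient_record$fontaine_stage,
    abi = patient_record$abi,
    cad = patient_record$cad,
    htn = patient_record$htn,
    n_fibers = nrow(measurements),
    mean_carbonyl_gsu = mean(measurements$carbonyl_gsu),
    mean_hne_gsu = mean(measurements$hne_gsu),
    mean_csa_um2 = mean(measurements$csa_um2),
    stringsAsFactors = FALSE
  )
}

#' Summarize every specimen of a cohort
#'
#' @param measurements Fiber table for all patients (columns `patient_id`,
#'   `csa_um2`, `carbonyl_gsu`, `hne_gsu`).
#' @param metadata Patient metadata table (one row per patient).
#' @return Specimen summary table, one row per patient, in `metadata`
#'   order.
#' @export
summarize_cohort <- function(measurements, metadata) {
  out <- lapply(seq_len(nrow(metadata)), function(i) {
    rec <- metadata[i, ]
    summarize_specimen(measurements[measurements$patient_id == rec$patient_id, ,
                                    drop = FALSE], rec)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ground-truth fiber table in measurement format
#'
#' Renames a generator ground-truth fiber table to the measured-fiber
#' schema so the quantification, quartile and statistics modules can run
#' on programmed truth directly (edge-touching fibers are dropped, as the
#' measurement path would drop them).
#'
#' @param truth_fibers `fibers` table from [generate_cohort()].
#' @return Data frame with the [measure_fibers()] columns.
#' @export
truth_as_measurements <- function(truth_fibers) {
  tf <- truth_fibers[!truth_fibers$edge_touching, , drop = FALSE]
  data.frame(patient_id = tf$patient_id, field_id = tf$field_id,
             fiber_id = tf$fiber_id, csa_um2 = tf$true_csa_um2,
             carbonyl_gsu = tf$true_carbonyl_gsu, hne_gsu = tf$true_hne_gsu,
             stringsAsFactors = FALSE)
}
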