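#' Configuration of one synthetic microscopic field
#'
#' Describes the raster and optics of a single simulated field of a muscle
#' cross-section: image size, physical pixel size, how many fibers tile the
#' field, the width and brightness of the sarcolemmal membrane rim, the
#' camera black level, and the noise model applied after the field is
#' painted.
#'
#' @param image_height_px,image_width_px Raster dimensions in pixels.
#' @param pixel_size_um Physical size of one pixel in micrometers. The
#'   default 0.65 corresponds to a typical 10x objective on a CCD camera of
#'   the class used for muscle morphometry.
#' @param fibers_per_field Number of fibers tiling the field.
#' @param membrane_width_px Width of the extracellular/membrane rim between
#'   adjacent fiber interiors, in pixels.
#' @param membrane_intensity_gsu Brightness painted on the rim (gsu, before
#'   the camera black level is added).
#' @param camera_black_gsu Background floor added to every pixel of every
#'   channel, emulating the black level of the camera.
#' @param psf_sigma_px Standard deviation of an optional Gaussian
#'   point-spread blur applied to each channel; 0 disables it.
#' @param noise_model One of `"none"`, `"gaussian"` (additive read noise) or
#'   `"poisson_gaussian"` (Poisson shot noise followed by Gaussian read
#'   noise).
#' @param noise_scale Standard deviation of the Gaussian read noise in gsu.
#'
#' @return A `field_config` list. All painted intensities are clamped to the
#'   12-bit range \[0, 4095\].
#' @export
field_config <- function(image_height_px = 288,
                         image_width_px = 384,
                         pixel_size_um = 1.3,
                         fibers_per_field = 40,
                         membrane_width_px = 3,
                         membrane_intensity_gsu = 2500,
                         camera_black_gsu = 100,
                         psf_sigma_px = 0.8,
                         noise_model = c("gaussian", "none", "poisson_gaussian"),
                         noise_scale = 25) {
  noise_model <- match.arg(noise_model)
  fc <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_size_um = pixel_size_um,
    fibers_per_field = as.integer(fibers_per_field),
    membrane_width_px = membrane_width_px,
    membrane_intensity_gsu = membrane_intensity_gsu,
    camera_black_gsu = camera_black_gsu,
    psf_sigma_px = psf_sigma_px,
    noise_model = noise_model,
    noise_scale = noise_scale,
    bit_depth = 12L
  )
  stopifnot(
    fc$image_height_px >= 16, fc$image_width_px >= 16,
    fc$pixel_size_um > 0, fc$fibers_per_field >= 1,
    fc$membrane_width_px > 0,
    fc$membrane_intensity_gsu >= 0, fc$membrane_intensity_gsu <= GSU_MAX,
    fc$camera_black_gsu >= 0, fc$psf_sigma_px >= 0, fc$noise_scale >= 0
  )
  class(fc) <- "field_config"
  fc
}

#' Configuration of a synthetic patient cohort
#'
#' Defines the study conditions of a simulated case-control cohort of
#' gastrocnemius biopsies: group sizes, the Fontaine-stage mix of the PAD
#' (peripheral arterial disease) group, per-group specimen-level means and
#' SDs of carbonyl content, HNE content (gsu) and fiber cross-sectional
#' area (um^2), the per-stage damage increments, the coupling of fiber
#' damage to fiber size, and the clinical covariates (CAD, HTN, ABI).
#'
#' Defaults reproduce the cohort scale of a 21-control / 34-PAD biopsy
#' study: carbonyl 486 +/- 135 vs 695 +/- 132 gsu, HNE 261 +/- 101 vs
#' 436 +/- 119 gsu, CSA 5324 +/- 1371 vs 3760 +/- 1546 um^2, stage
#' proportions 13:9:12 over Fontaine stages 2:3:4, CAD prevalence
#' 23.8%/61.7%, HTN 57.1%/82.3%, ABI 0.94-1.34 (control) and 0.01-0.81
#' (PAD).
#'
#' @param n_control,n_pad Number of patients per group.
#' @param stage_proportions Named probabilities over Fontaine stages
#'   `"2"`, `"3"`, `"4"` for PAD patients; must sum to 1.
#' @param fields_per_specimen_range Integer interval from which each
#'   specimen's number of microscopic fields is drawn.
#' @param control_csa_mean_um2,control_csa_sd_um2 Specimen-level mean/SD of
#'   control fiber cross-sectional area.
#' @param pad_csa_mean_um2,pad_csa_sd_um2 Same for the PAD group.
#' @param control_carbonyl_mean_gsu,control_carbonyl_sd_gsu Specimen-level
#'   mean/SD of background-corrected carbonyl signal, control group.
#' @param pad_carbonyl_mean_gsu,pad_carbonyl_sd_gsu Same for PAD.
#' @param control_hne_mean_gsu,control_hne_sd_gsu Specimen-level mean/SD of
#'   HNE signal, control group.
#' @param pad_hne_mean_gsu,pad_hne_sd_gsu Same for PAD.
#' @param stage_effect_gsu_per_stage Named numeric (`carbonyl`, `hne`):
#'   added damage per Fontaine step for PAD patients.
#' @param abi_damage_slope Damage change (gsu) per ABI unit, applied to the
#'   within-stage ABI residual of PAD patients; negative means more damage
#'   at lower perfusion.
#' @param csa_damage_coupling Named numeric (`control`, `pad`): change of
#'   fiber CSA (um^2) per gsu of within-patient fiber damage deviation;
#'   must be <= 0 for PAD and 0 for controls.
#' @param fiber_level_sd_gsu Named numeric (`carbonyl`, `hne`):
#'   within-specimen fiber-to-fiber SD of damage signal.
#' @param fiber_marker_cor Correlation of the two markers at the fiber
#'   level (shared latent damage factor).
#' @param patient_marker_cor Correlation of the patient-level random
#'   effects of the two markers.
#' @param fiber_csa_sd_um2 Within-specimen fiber CSA SD not explained by
#'   the damage coupling.
#' @param ecm_carbonyl_gsu Extra carbonyl signal painted over the
#'   extracellular matrix compartment (HNE gets none: it is confined to
#'   fiber interiors).
#' @param cad_prevalence,htn_prevalence Named probabilities (`control`,
#'   `pad`) of coronary artery disease and hypertension.
#' @param abi_control_range,abi_pad_range Ankle-brachial-index intervals
#'   per group, inside \[0, 2\]; PAD implies ABI < 0.9.
#' @param seed Integer seed making the whole cohort reproducible.
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_control = 21,
                          n_pad = 34,
                          stage_proportions = c("2" = 13 / 34, "3" = 9 / 34, "4" = 12 / 34),
                          fields_per_specimen_range = c(5L, 15L),
                          control_csa_mean_um2 = 5324, control_csa_sd_um2 = 1371,
                          pad_csa_mean_um2 = 3760, pad_csa_sd_um2 = 1546,
                          control_carbonyl_mean_gsu = 486, control_carbonyl_sd_gsu = 135,
                          pad_carbonyl_mean_gsu = 695, pad_carbonyl_sd_gsu = 132,
                          control_hne_mean_gsu = 261, control_hne_sd_gsu = 101,
                          pad_hne_mean_gsu = 436, pad_hne_sd_gsu = 119,
                          stage_effect_gsu_per_stage = c(carbonyl = 137, hne = 119),
                          abi_damage_slope = -150,
                          csa_damage_coupling = c(control = 0, pad = -1.5),
                          fiber_level_sd_gsu = c(carbonyl = 150, hne = 120),
                          fiber_marker_cor = 0.7,
                          patient_marker_cor = 0.8,
                          fiber_csa_sd_um2 = 1000,
                          ecm_carbonyl_gsu = 300,
                          cad_prevalence = c(control = 0.238, pad = 0.617),
                          htn_prevalence = c(control = 0.571, pad = 0.823),
                          abi_control_range = c(0.94, 1.34),
                          abi_pad_range = c(0.01, 0.81),
                          seed = 1L) {
  cc <- as.list(environment())
  stopifnot(
    cc$n_control >= 0, cc$n_pad >= 0,
    all(cc$stage_proportions >= 0), abs(sum(cc$stage_proportions) - 1) < 1e-8,
    all(names(cc$stage_proportions) %in% c("2", "3", "4")),
    length(cc$fields_per_specimen_range) == 2,
    cc$fields_per_specimen_range[1] >= 1,
    diff(cc$fields_per_specimen_range) >= 0,
    cc$control_csa_sd_um2 >= 0, cc$pad_csa_sd_um2 >= 0,
    cc$control_carbonyl_sd_gsu >= 0, cc$pad_carbonyl_sd_gsu >= 0,
    cc$control_hne_sd_gsu >= 0, cc$pad_hne_sd_gsu >= 0,
    all(cc$fiber_level_sd_gsu >= 0), cc$fiber_csa_sd_um2 >= 0,
    cc$csa_damage_coupling[["pad"]] <= 0, cc$csa_damage_coupling[["control"]] == 0,
    all(cc$cad_prevalence >= 0 & cc$cad_prevalence <= 1),
    all(cc$htn_prevalence >= 0 & cc$htn_prevalence <= 1),
    all(cc$abi_control_range >= 0 & cc$abi_control_range <= 2),
    all(cc$abi_pad_range >= 0 & cc$abi_pad_range <= 2),
    cc$fiber_marker_cor >= -1, cc$fiber_marker_cor <= 1,
    cc$patient_marker_cor >= -1, cc$patient_marker_cor <= 1
  )
  # reference stage: the proportion-weighted mean stage, so the PAD group
  # mean stays at pad_*_mean_gsu whatever the stage effect is
  st <- as.numeric(names(cc$stage_proportions))
  cc$stage_ref <- sum(st * cc$stage_proportions)
  # mean ABI by stage (declining with clinical progression) and the
  # within-stage ABI spread
  cc$abi_stage_means <- c("2" = 0.50, "3" = 0.35, "4" = 0.20)
  cc$abi_within_stage_sd <- 0.12
  class(cc) <- "cohort_config"
  cc
}

#' Draw one patient record
#'
#' Samples the clinical attributes of a single simulated patient: the
#' Fontaine stage (PAD only), the ankle-brachial index (declining, on
#' average, with stage so that damage and ABI end up negatively
#' correlated), and coronary-artery-disease / hypertension indicators drawn
#' as independent Bernoulli variables at the group prevalences.
#'
#' @param cohort A [cohort_config()].
#' @param group `"control"` or `"pad"`.
#' @param patient_id Identifier stored in the record.
#' @param seed Optional integer; if given, seeds the RNG before drawing.
#' @return A one-row data frame: `patient_id`, `group`, `fontaine_stage`
#'   (NA for controls), `abi`, `cad`, `htn`.
#' @export
sample_patient <- function(cohort, group = c("control", "pad"),
                           patient_id = "P01", seed = NULL) {
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  if (group == "pad") {
    if (length(cohort$stage_proportions) == 0 || sum(cohort$stage_proportions) == 0)
      stop("stage_proportions is empty")
    stage <- as.integer(sample(names(cohort$stage_proportions), 1,
                               prob = cohort$stage_proportions))
    abi <- clamp(rnorm(1, cohort$abi_stage_means[[as.character(stage)]],
                       cohort$abi_within_stage_sd),
                 cohort$abi_pad_range[1], cohort$abi_pad_range[2])
  } else {
    stage <- NA_integer_
    abi <- runif(1, cohort$abi_control_range[1], cohort$abi_control_range[2])
  }
  data.frame(
    patient_id = patient_id, group = group, fontaine_stage = stage,
    abi = abi,
    cad = rbinom(1, 1, cohort$cad_prevalence[[group]]) == 1,
    htn = rbinom(1, 1, cohort$htn_prevalence[[group]]) == 1,
    stringsAsFactors = FALSE
  )
}

# Patient-level random-effect SD per marker: target specimen-level SD minus
# the variance already induced by the stage effect and the ABI residual
# slope (PAD), floored so the effect never vanishes entirely.
patient_effect_sd <- function(cohort, group, marker) {
  target <- cohort[[paste0(group, "_", marker, "_sd_gsu")]]
  if (group == "control") return(target)
  st <- as.numeric(names(cohort$stage_proportions))
  p <- as.numeric(cohort$stage_proportions)
  var_stage <- sum(p * (st - cohort$stage_ref)^2)
  v <- target^2 -
    cohort$stage_effect_gsu_per_stage[[marker]]^2 * var_stage -
    (cohort$abi_damage_slope * cohort$abi_within_stage_sd)^2
  sqrt(max(v, (0.15 * target)^2))
}

#' Programmed specimen means for one patient
#'
#' Computes (and draws the patient-level random effects for) the true
#' specimen means of carbonyl, HNE and CSA implied by the cohort model:
#' group mean + stage effect + ABI-residual effect + correlated patient
#' random effects.
#'
#' @param cohort A [cohort_config()].
#' @param record One-row patient data frame from [sample_patient()].
#' @return Named list `carbonyl`, `hne`, `csa` (gsu, gsu, um^2).
#' @export
patient_programmed_means <- function(cohort, record) {
  group <- record$group
  z_shared <- rnorm(1)
  rho <- cohort$patient_marker_cor
  eff <- function(marker) {
    z <- rho * z_shared + sqrt(1 - rho^2) * rnorm(1)
    base <- cohort[[paste0(group, "_", marker, "_mean_gsu")]]
    m <- base + patient_effect_sd(cohort, group, marker) * z
    if (group == "pad") {
      stage <- record$fontaine_stage
      m <- m + cohort$stage_effect_gsu_per_stage[[marker]] * (stage - cohort$stage_ref) +
        cohort$abi_damage_slope *
          (record$abi - cohort$abi_stage_means[[as.character(stage)]])
    }
    max(m, 0)
  }
  csa <- max(rnorm(1, cohort[[paste0(group, "_csa_mean_um2")]],
                   cohort[[paste0(group, "_csa_sd_um2")]]), 800)
  list(carbonyl = eff("carbonyl"), hne = eff("hne"), csa = csa)
}

#' Fiber-level sampler for one patient
#'
#' Returns a function `f(n)` that draws `n` fibers' true per-fiber values
#' around the patient's programmed means: a shared latent damage factor
#' drives both markers (fiber-level marker agreement), and fiber CSA is
#' coupled to the fiber's carbonyl deviation by the group's
#' `csa_damage_coupling` (negative for PAD: the most damaged fibers are the
#' smallest). True gsu values are rounded to integers (a 12-bit camera
#' digitizes integer counts) and clamped to \[0, 4095 - camera black\].
#'
#' @param cohort A [cohort_config()].
#' @param means Output of [patient_programmed_means()].
#' @param group `"control"` or `"pad"`.
#' @return Function of `n` returning a data frame with columns
#'   `carbonyl_gsu`, `hne_gsu`, `csa_um2`.
#' @export
fiber_sampler <- function(cohort, means, group) {
  force(means); force(group)
  function(n) {
    rho <- cohort$fiber_marker_cor
    u <- rnorm(n)
    dev_c <- cohort$fiber_level_sd_gsu[["carbonyl"]] *
      (rho * u + sqrt(1 - rho^2) * rnorm(n))
    dev_h <- cohort$fiber_level_sd_gsu[["hne"]] *
      (rho * u + sqrt(1 - rho^2) * rnorm(n))
    carbonyl <- round(clamp(means$carbonyl + dev_c, 0, GSU_MAX))
    hne <- round(clamp(means$hne + dev_h, 0, GSU_MAX))
    csa <- means$csa +
      cohort$csa_damage_coupling[[group]] * (carbonyl - means$carbonyl) +
      rnorm(n, 0, cohort$fiber_csa_sd_um2)
    data.frame(carbonyl_gsu = carbonyl, hne_gsu = hne,
               csa_um2 = pmax(csa, 0.1 * means$csa))
  }
}

# Capacity-controlled power-diagram tessellation of the pixel grid.
# Random seeds -> Lloyd relaxation (unweighted Voronoi, centroid updates)
# -> weight iterations pushing each cell's realized pixel count toward its
# target area (for a hexagonal cell, dArea/dweight ~ 1.65 independent of
# cell size). Recentering accompanies the first capacity iterations, then
# seeds are frozen so the weights can converge.
tessellate_field <- function(nrow, ncol, target_px,
                             n_lloyd = 2, n_capacity = c(4, 8), eta = 0.5) {
  n <- length(target_px)
  target_px <- target_px * (nrow * ncol) / sum(target_px)
  sx <- runif(n, 0.05 * ncol, 0.95 * ncol)
  sy <- runif(n, 0.05 * nrow, 0.95 * nrow)
  w <- numeric(n)
  recenter <- function(lab) {
    cs <- tabulate(lab, n)
    xs <- rowsum_by(rep(seq_len(ncol), each = nrow), lab, n)
    ys <- rowsum_by(rep(seq_len(nrow), times = ncol), lab, n)
    keep <- cs > 0
    sx[keep] <<- xs[keep] / cs[keep]
    sy[keep] <<- ys[keep] / cs[keep]
  }
  for (i in seq_len(n_lloyd)) {
    a <- power_assign(nrow, ncol, sx, sy, w)
    recenter(a$label)
  }
  for (i in seq_len(n_capacity[1])) {
    a <- power_assign(nrow, ncol, sx, sy, w)
    w <- w + eta * (target_px - tabulate(a$label, n)) / 1.65
    recenter(a$label)
  }
  for (i in seq_len(n_capacity[2])) {
    a <- power_assign(nrow, ncol, sx, sy, w)
    w <- w + eta * (target_px - tabulate(a$label, n)) / 1.65
  }
  power_assign(nrow, ncol, sx, sy, w)
}

rowsum_by <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, as.vector(g))
  out[as.integer(rownames(s))] <- s
  out
}

apply_psf <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma))
}

apply_noise <- function(m, model, scale) {
  if (model == "none") return(m)
  if (model == "poisson_gaussian") m <- rpois(length(m), pmax(m, 0))
  m <- m + rnorm(length(m), 0, scale)
  round(m)
}

#' Generate one synthetic three-channel field
#'
#' Tessellates the field into `fibers_per_field` convex polygonal fibers
#' (capacity-controlled power diagram on the pixel grid, 2 Lloyd
#' relaxations), shrinks each cell by the membrane width to leave an
#' extracellular rim, and paints the three channels: membrane signal along
#' the rims; carbonyl = per-fiber level inside fibers plus the ECM carbonyl
#' level over the rim, plus the camera black floor everywhere; HNE =
#' per-fiber level inside fibers plus the black floor only (HNE is absent
#' from the extracellular matrix). Optional PSF blur, then noise, then a
#' clamp to the 12-bit range.
#'
#' @param field A [field_config()].
#' @param fiber_sampler Function of `n` returning a data frame with columns
#'   `carbonyl_gsu`, `hne_gsu`, `csa_um2` (see [fiber_sampler()]).
#' @param seed Optional integer seeding the RNG.
#' @return List with `stack` (an `image_stack`: matrices `membrane`,
#'   `carbonyl`, `hne` plus `pixel_size_um`) and `truth` (list: `label`
#'   matrix of fiber interiors, 0 = extracellular; `fibers` data frame with
#'   `fiber_id`, `true_csa_um2`, `true_carbonyl_gsu`, `true_hne_gsu`,
#'   `edge_touching`; `membrane` logical matrix).
#' @export
generate_field <- function(field, fiber_sampler, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- field$image_height_px; wd <- field$image_width_px
  n <- field$fibers_per_field
  min_px <- (3 * field$membrane_width_px)^2
  if (h * wd / n < min_px)
    stop("fibers_per_field too large for the image area: ",
         "minimum feasible fiber size violated")
  fib <- fiber_sampler(n)
  target_px <- pmax(fib$csa_um2 / field$pixel_size_um^2, min_px)
  tess <- tessellate_field(h, wd, target_px)
  membrane <- tess$edge_dist <= field$membrane_width_px / 2
  label <- tess$label
  label[membrane] <- 0L

  black <- field$camera_black_gsu
  interior <- label > 0
  mem_ch <- matrix(black, h, wd)
  mem_ch[membrane] <- black + field$membrane_intensity_gsu
  car_ch <- matrix(black, h, wd)
  car_ch[!interior] <- black + field$ecm_carbonyl_gsu %||% 0
  hne_ch <- matrix(black, h, wd)
  car_ch[interior] <- black + fib$carbonyl_gsu[label[interior]]
  hne_ch[interior] <- black + fib$hne_gsu[label[interior]]

  finish <- function(m) {
    m <- apply_psf(m, field$psf_sigma_px)
    m <- apply_noise(m, field$noise_model, field$noise_scale)
    matrix(clamp(m, 0, GSU_MAX), h, wd)
  }
  stack <- image_stack(finish(mem_ch), finish(car_ch), finish(hne_ch),
                       field$pixel_size_um)

  px_count <- tabulate(label[interior], n)
  edge <- logical(n)
  border <- c(label[1, ], label[h, ], label[, 1], label[, wd])
  edge[unique(border[border > 0])] <- TRUE
  truth_fibers <- data.frame(
    fiber_id = seq_len(n),
    true_csa_um2 = px_count * field$pixel_size_um^2,
    true_carbonyl_gsu = fib$carbonyl_gsu,
    true_hne_gsu = fib$hne_gsu,
    edge_touching = edge
  )
  list(stack = stack,
       truth = list(label = label, fibers = truth_fibers, membrane = membrane))
}

# ecm_carbonyl is carried on the field config when the field is generated
# inside a cohort; standalone fields default to 0 unless set.
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic cohort
#'
#' Draws the patients, per-patient programmed specimen means, the number of
#' fields per specimen, and per-fiber ground truth; optionally rasterizes
#' every field into a three-channel image and writes the dataset (TIFFs,
#' metadata CSV, ground-truth fiber CSV, manifest JSON) to `outdir`.
#'
#' Fibers per field are set by the field area divided by the patient's
#' programmed mean CSA, so a specimen's realized mean fiber size matches
#' its programmed mean. With `render_images = FALSE`, the ground-truth
#' fiber table is produced from the statistical model directly (no
#' rasterization), which is the fast path for cohort-level simulation
#' studies.
#'
#' @param cohort A [cohort_config()].
#' @param field A [field_config()]; `fibers_per_field` is overridden per
#'   patient as described above.
#' @param outdir Optional output directory; created if missing.
#' @param render_images If `FALSE`, skip image rasterization and emit
#'   ground-truth tables only.
#' @return List: `patients` (metadata), `fibers` (ground-truth fiber
#'   table), `fields` (per-field manifest), `programmed` (per-patient true
#'   means), and, when `outdir` is given, `files`.
#' @export
generate_cohort <- function(cohort, field = field_config(), outdir = NULL,
                            render_images = TRUE) {
  set.seed(cohort$seed)
  ids <- c(sprintf("C%02d", seq_len(cohort$n_control)),
           sprintf("P%02d", seq_len(cohort$n_pad)))
  groups <- rep(c("control", "pad"), c(cohort$n_control, cohort$n_pad))
  patients <- do.call(rbind, Map(function(id, g)
    sample_patient(cohort, g, patient_id = id), ids, groups))
  rownames(patients) <- NULL

  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  area_um2 <- field$image_height_px * field$image_width_px * field$pixel_size_um^2

  fibers <- list(); fields <- list(); programmed <- list(); files <- character()
  for (i in seq_len(nrow(patients))) {
    rec <- patients[i, ]
    pm <- patient_programmed_means(cohort, rec)
    programmed[[rec$patient_id]] <- pm
    field_counts <- seq(cohort$fields_per_specimen_range[1],
                        cohort$fields_per_specimen_range[2])
    n_fields <- if (length(field_counts) == 1) field_counts
                else sample(field_counts, 1)
    n_per_field <- max(4L, as.integer(round(area_um2 / pm$csa)))
    sampler <- fiber_sampler(cohort, pm, rec$group)
    for (f in seq_len(n_fields)) {
      field_id <- sprintf("f%02d", f)
      if (render_images) {
        fc <- field
        fc$fibers_per_field <- n_per_field
        fc$ecm_carbonyl_gsu <- cohort$ecm_carbonyl_gsu
        fld <- generate_field(fc, sampler)
        tf <- fld$truth$fibers
        if (!is.null(outdir)) {
          path <- file.path(outdir, sprintf("%s_%s.tif", rec$patient_id, field_id))
          write_image_stack(fld$stack, path)
          files <- c(files, path)
        }
      } else {
        draws <- sampler(n_per_field)
        tf <- data.frame(fiber_id = seq_len(n_per_field),
                         true_csa_um2 = draws$csa_um2,
                         true_carbonyl_gsu = draws$carbonyl_gsu,
                         true_hne_gsu = draws$hne_gsu,
                         edge_touching = FALSE)
      }
      tf <- cbind(patient_id = rec$patient_id, field_id = field_id, tf)
      fibers[[length(fibers) + 1]] <- tf
      fields[[length(fields) + 1]] <- data.frame(
        patient_id = rec$patient_id, field_id = field_id,
        n_fibers = nrow(tf),
        file = if (render_images && !is.null(outdir))
          sprintf("%s_%s.tif", rec$patient_id, field_id) else NA_character_)
    }
  }
  fibers <- do.call(rbind, fibers); rownames(fibers) <- NULL
  fields <- do.call(rbind, fields); rownames(fields) <- NULL

  out <- list(patients = patients, fibers = fibers, fields = fields,
              programmed = programmed)
  if (!is.null(outdir)) {
    meta_path <- file.path(outdir, "patients.csv")
    write.csv(patients, meta_path, row.names = FALSE)
    truth_path <- file.path(outdir, "ground_truth_fibers.csv")
    write.csv(fibers, truth_path, row.names = FALSE)
    manifest <- list(seed = cohort$seed,
                     n_control = cohort$n_control, n_pad = cohort$n_pad,
                     fields = fields)
    man_path <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    out$files <- c(files, meta_path, truth_path, man_path)
  }
  out
}
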