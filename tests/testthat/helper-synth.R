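# Shared fixtures and independent oracles, all built in code.

# Noise-free field configuration used wherever exact pixel values matter.
quiet_field <- function(...) {
  field_config(noise_model = "none", psf_sigma_px = 0, ...)
}

# Sampler painting every fiber with the same true values.
uniform_sampler <- function(carbonyl = 800, hne = 400, csa = 5000, csa_cv = 0) {
  function(n) data.frame(
    carbonyl_gsu = rep(carbonyl, n),
    hne_gsu = rep(hne, n),
    csa_um2 = if (csa_cv > 0) exp(rnorm(n, log(csa), csa_cv)) else rep(csa, n))
}

# Hand-built single-fiber fixture: a square membrane ring (width 3 px)
# around one interior region, away from the image border.
ring_fixture <- function(size = 100, lo = 20, hi = 80,
                         black = 100, membrane = 2500, carbonyl = 800,
                         hne = 400, pixel_size = 1) {
  lab <- matrix(0L, size, size)
  lab[(lo + 3):(hi - 3), (lo + 3):(hi - 3)] <- 1L
  ring <- matrix(FALSE, size, size)
  ring[lo:hi, lo:hi] <- TRUE
  ring[(lo + 3):(hi - 3), (lo + 3):(hi - 3)] <- FALSE
  mem <- matrix(black, size, size); mem[ring] <- black + membrane
  car <- matrix(black, size, size); car[lab == 1L] <- black + carbonyl
  hne_m <- matrix(black, size, size); hne_m[lab == 1L] <- black + hne
  list(stack = image_stack(mem, car, hne_m, pixel_size), label = lab,
       ring = ring)
}

# Truth label map with edge-touching fibers removed, for matching against
# a segmentation run with exclude_edge_fibers = TRUE.
interior_truth <- function(field_out) {
  lab <- field_out$truth$label
  edge_ids <- field_out$truth$fibers$fiber_id[field_out$truth$fibers$edge_touching]
  lab[lab %in% edge_ids] <- 0L
  lab
}

# Brute-force quartile-class oracle: evaluates the four class predicates
# independently of the package's assignment path.
oracle_classes <- function(values, q) {
  in_q1 <- values <= q[1]
  in_q2 <- values > q[1] & values <= q[2]
  in_q3 <- values > q[2] & values <= q[3]
  in_q4 <- values > q[3]
  stopifnot(all(in_q1 + in_q2 + in_q3 + in_q4 == 1))
  factor(ifelse(in_q1, "Q1", ifelse(in_q2, "Q2", ifelse(in_q3, "Q3", "Q4"))),
         levels = c("Q1", "Q2", "Q3", "Q4"))
}

# Normal-equations partial-correlation oracle: solve the two small
# regressions explicitly and correlate the residuals.
oracle_partial_r <- function(y, x, Z) {
  X <- cbind(1, as.matrix(Z))
  ry <- y - X %*% solve(crossprod(X), crossprod(X, y))
  rx <- x - X %*% solve(crossprod(X), crossprod(X, x))
  cor(rx, ry)[1, 1]
}

# Small fast cohort for pipeline-level tests.
tiny_cohort <- function(seed, n_control = 2, n_pad = 3, fields = c(2L, 2L)) {
  cohort_config(n_control = n_control, n_pad = n_pad,
                fields_per_specimen_range = fields, seed = seed)
}

tiny_field <- function(image_height_px = 160, image_width_px = 160, ...) {
  field_config(image_height_px = image_height_px,
               image_width_px = image_width_px,
               noise_model = "none", psf_sigma_px = 0, ...)
}
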