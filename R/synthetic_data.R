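# Seeded generators of ground-truthed synthetic scenes. Every generator is
# deterministic in its seed (bit-identical outputs) and returns the exact
# ground truth alongside the data, so every pipeline stage can be tested
# without microscopy data.
#
# Texture model: per-pixel i.i.d. Gaussian noise, with the object-to-
# background variance ratio as the single difficulty knob. This matches the
# segmentation principle (cells show large local brightness variability)
# without modeling phase-contrast optics.

render_texture <- function(mask, background_sd = 1, variance_ratio = 10) {
  stopifnot(variance_ratio > 0)
  nr <- nrow(mask); nc <- ncol(mask)
  px <- matrix(rnorm(nr * nc, sd = background_sd), nr, nc)
  inside <- mask == 1L
  px[inside] <- rnorm(sum(inside), sd = background_sd * sqrt(variance_ratio))
  px
}

#' Render a textured phase-contrast-like frame from a truth mask
#'
#' Background pixels are i.i.d. Gaussian with `background_sd`; mask pixels
#' are i.i.d. Gaussian with variance `variance_ratio` times higher (equal
#' means, pure variability contrast).
#'
#' @param mask a [binary_mask()] (the ground truth).
#' @param background_sd background noise SD (intensity units).
#' @param variance_ratio object-to-background variance ratio (> 0).
#' @param seed integer seed.
#' @param time frame time in hours.
#' @return a [calibrated_frame()].
#' @export
render_textured_frame <- function(mask, background_sd = 1, variance_ratio = 10,
                                  seed = 1L, time = 0) {
  px <- withr::with_seed(seed,
    render_texture(mask$pixels, background_sd, variance_ratio))
  calibrated_frame(px, mask$pixel_size, time = time)
}

place_rect <- function(occ, h, w, gap = 2L, max_tries = 200L) {
  nr <- nrow(occ); nc <- ncol(occ)
  for (k in seq_len(max_tries)) {
    i <- sample.int(nr - h - 2L * gap, 1L) + gap
    j <- sample.int(nc - w - 2L * gap, 1L) + gap
    if (all(occ[(i - gap):(i + h - 1L + gap), (j - gap):(j + w - 1L + gap)] == 0L))
      return(c(i, j))
  }
  stop("could not place a non-overlapping object after ", max_tries,
       " attempts; reduce object count or areas", call. = FALSE)
}

#' Synthetic culture scene with known cluster layout
#'
#' Places non-touching rectangular (exact-area) or disk clusters at random
#' positions and renders them as high-variance texture on a quiet noisy
#' background. The truth mask and a truth cluster table (exact rasterized
#' areas) are returned alongside.
#'
#' @param areas_um2 target cluster areas in µm². Rectangles realize the
#'   requested pixel area exactly; disk areas are exact as rasterized and
#'   reported in the truth table.
#' @param shape `"rect"` or `"disk"`.
#' @param frame_shape image dimensions `c(rows, cols)` in pixels.
#' @param pixel_size µm per pixel.
#' @param background_sd,variance_ratio see [render_textured_frame()].
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @return list with `frame` ([calibrated_frame()]), `truth_mask`
#'   ([binary_mask()]), `truth_table` (`ClusterTable` of the truth mask,
#'   `min_area = 0`).
#' @export
make_culture_scene <- function(areas_um2, shape = c("rect", "disk"),
                               frame_shape = c(256L, 256L), pixel_size = 1,
                               background_sd = 1, variance_ratio = 10,
                               seed = 1L) {
  shape <- match.arg(shape)
  withr::with_seed(seed, {
    mask <- matrix(0L, frame_shape[1], frame_shape[2])
    for (a in areas_um2) {
      apx <- max(round(a / pixel_size^2), 1)
      if (shape == "rect") {
        h <- max(floor(sqrt(apx)), 1L)
        w <- ceiling(apx / h)
        # trim the last row to hit the pixel area exactly
        pos <- place_rect(mask, h, w)
        block <- matrix(1L, h, w)
        extra <- h * w - apx
        if (extra > 0) block[1L, seq_len(extra)] <- 0L
        mask[pos[1]:(pos[1] + h - 1L), pos[2]:(pos[2] + w - 1L)] <-
          pmax(mask[pos[1]:(pos[1] + h - 1L), pos[2]:(pos[2] + w - 1L)], block)
      } else {
        r <- sqrt(apx / pi)
        d <- ceiling(2 * r) + 2L
        pos <- place_rect(mask, d, d)
        cx <- pos[1] + (d - 1) / 2; cy <- pos[2] + (d - 1) / 2
        ii <- pos[1]:(pos[1] + d - 1L); jj <- pos[2]:(pos[2] + d - 1L)
        disk <- outer(ii, jj, function(i, j) (i - cx)^2 + (j - cy)^2 <= r^2)
        mask[ii, jj] <- pmax(mask[ii, jj], disk * 1L)
      }
    }
    px <- render_texture(mask, background_sd, variance_ratio)
    bm <- binary_mask(mask, pixel_size)
    list(frame = calibrated_frame(px, pixel_size),
         truth_mask = bm,
         truth_table = label_clusters(bm, connectivity = 8L, min_area = 0))
  })
}

periodic_smooth <- function(w, sigma) {
  nr <- nrow(w); nc <- ncol(w)
  fx <- c(0:(floor(nr / 2)), -((ceiling(nr / 2) - 1):1)) / nr
  fy <- c(0:(floor(nc / 2)), -((ceiling(nc / 2) - 1):1)) / nc
  H <- exp(-2 * pi^2 * sigma^2 * outer(fx^2, fy^2, `+`))
  out <- Re(stats::fft(stats::fft(w) * H, inverse = TRUE)) / (nr * nc)
  (out - mean(out)) / sd(out)
}

#' Uniformly translating texture time lapse
#'
#' A smooth periodic random texture translated by a constant sub-pixel
#' displacement per frame (bilinear interpolation, periodic boundary); the
#' exact per-frame shift is the PIV ground truth.
#'
#' @param velocity_um_h velocity as `c(v_row, v_col)` in µm/h (a scalar is
#'   taken along the row axis).
#' @param n_frames number of frames (>= 2).
#' @param interval_min frame interval in minutes.
#' @param frame_shape `c(rows, cols)` pixels.
#' @param pixel_size µm per pixel.
#' @param smooth_sigma texture correlation length in px (default 1, the
#'   fine granularity of phase-contrast cell texture; larger values blur the
#'   correlation peak and weaken the PIV peak-ratio contrast).
#' @param seed integer seed.
#' @return list with `timelapse` ([time_lapse()]), `shift_px_per_frame`
#'   (`c(d_row, d_col)`), `speed_um_h` (truth speed magnitude).
#' @export
make_translating_timelapse <- function(velocity_um_h, n_frames = 2L,
                                       interval_min = 10, frame_shape = c(128L, 128L),
                                       pixel_size = 1, smooth_sigma = 1,
                                       seed = 1L) {
  if (length(velocity_um_h) == 1L) velocity_um_h <- c(velocity_um_h, 0)
  stop_if_not(n_frames >= 2, "need >= 2 frames")
  shift <- velocity_um_h / pixel_size * interval_min / 60   # px per frame
  withr::with_seed(seed, {
    nr <- frame_shape[1]; nc <- frame_shape[2]
    tex <- periodic_smooth(matrix(rnorm(nr * nc), nr, nc), smooth_sigma)
    frames <- lapply(seq_len(n_frames) - 1L, function(k) {
      off <- k * shift
      calibrated_frame(sample_periodic(tex, off[1], off[2]), pixel_size,
                       time = k * interval_min / 60)
    })
    list(timelapse = time_lapse(frames, interval_min),
         shift_px_per_frame = shift,
         speed_um_h = sqrt(sum(velocity_um_h^2)))
  })
}

# bilinear sampling of tex at (i - oi, j - oj) with periodic wraparound
sample_periodic <- function(tex, oi, oj) {
  nr <- nrow(tex); nc <- ncol(tex)
  i <- seq_len(nr) - 1 - oi; j <- seq_len(nc) - 1 - oj
  i0 <- floor(i); fi <- i - i0
  j0 <- floor(j); fj <- j - j0
  w <- function(a, n) (a %% n) + 1L
  r0 <- w(i0, nr); r1 <- w(i0 + 1, nr)
  c0 <- w(j0, nc); c1 <- w(j0 + 1, nc)
  t00 <- tex[r0, c0]; t10 <- tex[r1, c0]
  t01 <- tex[r0, c1]; t11 <- tex[r1, c1]
  (1 - fi) * (1 - fj) * t00 + fi * (1 - fj) * t10 +
    (1 - fi) * fj * t01 + fi * fj * t11
}

#' Simulate single-cell trajectories with known motion statistics
#'
#' Three motion models: `ballistic` (straight lines at constant speed,
#' random headings), `brownian` (Gaussian steps with mean squared
#' displacement `4 D dt`), and `prw` (persistent random walk: each velocity
#' component is an Ornstein-Uhlenbeck process with persistence time
#' `persistence_h`, scaled so the mean speed is `speed_um_h`; exact
#' discretization of the OU transition).
#'
#' @param n_cells number of trajectories.
#' @param model `"ballistic"`, `"brownian"` or `"prw"`.
#' @param speed_um_h mean speed, µm/h (ballistic, prw).
#' @param D_um2_h diffusion coefficient, µm²/h (brownian).
#' @param persistence_h persistence time, hours (prw).
#' @param duration_h track duration, hours.
#' @param dt_min sampling interval, minutes.
#' @param seed integer seed.
#' @return list with `tracks` (list of [trajectory()]) and `truth` (the
#'   model parameters).
#' @export
simulate_tracks <- function(n_cells = 20L,
                            model = c("ballistic", "brownian", "prw"),
                            speed_um_h = 20, D_um2_h = 50, persistence_h = 1,
                            duration_h = 25, dt_min = 10, seed = 1L) {
  model <- match.arg(model)
  dt <- dt_min / 60
  tt <- seq(0, duration_h, by = dt)
  n <- length(tt)
  withr::with_seed(seed, {
    tracks <- lapply(seq_len(n_cells), function(ci) {
      if (model == "ballistic") {
        th <- runif(1, 0, 2 * pi)
        x <- speed_um_h * cos(th) * tt
        y <- speed_um_h * sin(th) * tt
      } else if (model == "brownian") {
        s <- sqrt(2 * D_um2_h * dt)
        x <- cumsum(c(0, rnorm(n - 1, sd = s)))
        y <- cumsum(c(0, rnorm(n - 1, sd = s)))
      } else {
        sig <- speed_um_h * sqrt(2 / pi)       # per-component OU sd
        a <- exp(-dt / persistence_h)
        b <- sig * sqrt(1 - a^2)
        vx <- vy <- numeric(n)
        vx[1] <- rnorm(1, sd = sig); vy[1] <- rnorm(1, sd = sig)
        for (k in 2:n) {
          vx[k] <- a * vx[k - 1] + b * rnorm(1)
          vy[k] <- a * vy[k - 1] + b * rnorm(1)
        }
        x <- cumsum(c(0, vx[-n] * dt))
        y <- cumsum(c(0, vy[-n] * dt))
      }
      trajectory(tt, x, y, cell_id = paste0("cell", ci))
    })
    list(tracks = tracks,
         truth = list(model = model, speed_um_h = speed_um_h,
                      D_um2_h = D_um2_h, persistence_h = persistence_h,
                      dt_min = dt_min))
  })
}

#' Rasterized star-convex spheroid shapes with dense-polygon ground truth
#'
#' Shapes are defined by a polar radius function `r(theta)` around the
#' center: disk, square (rotatable), ellipse, k-armed star
#' `r0 (1 + amplitude cos(k theta))`, or a random Fourier boundary. The true
#' area and perimeter come from a dense polygon (default 2e4 vertices)
#' evaluated before rasterization.
#'
#' @param kind `"disk"`, `"square"`, `"ellipse"`, `"star"` or `"fourier"`.
#' @param r0_px base radius in px (for `square`, half the side; for
#'   `ellipse`, the semi-minor axis).
#' @param aspect ellipse a/b ratio.
#' @param k,amplitude star arm count and relative amplitude.
#' @param coeffs optional Fourier amplitudes (named by harmonic); drawn from
#'   the seed when absent.
#' @param rotation rotation angle, radians.
#' @param pixel_size µm per pixel.
#' @param n_vertices polygon density for the truth.
#' @param seed integer seed (fourier only).
#' @return list with `mask` ([binary_mask()]), `true_area` (µm², polygon),
#'   `true_perimeter` (µm, polygon), `true_ratio` (normalized perimeter of
#'   the continuous shape), `raster_area` (µm², pixel count).
#' @export
make_spheroid_shape <- function(kind = c("disk", "square", "ellipse", "star",
                                         "fourier"),
                                r0_px = 100, aspect = 2, k = 5L,
                                amplitude = 0.3, coeffs = NULL, rotation = 0,
                                pixel_size = 1, n_vertices = 20001L,
                                seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "fourier" && is.null(coeffs))
    coeffs <- withr::with_seed(seed, stats::setNames(runif(3, 0.05, 0.15), 2:4))
  rfun <- switch(kind,
    disk = function(th) rep(r0_px, length(th)),
    square = function(th) r0_px / pmax(abs(cos(th - rotation)),
                                       abs(sin(th - rotation))),
    ellipse = function(th) {
      a <- r0_px * aspect; b <- r0_px
      a * b / sqrt((b * cos(th - rotation))^2 + (a * sin(th - rotation))^2)
    },
    star = function(th) r0_px * (1 + amplitude * cos(k * (th - rotation))),
    fourier = function(th) {
      r <- rep(1, length(th))
      for (h in seq_along(coeffs))
        r <- r + coeffs[h] * cos(as.numeric(names(coeffs)[h]) * (th - rotation))
      r0_px * r
    })
  th <- seq(0, 2 * pi, length.out = n_vertices)
  rr <- rfun(th)
  px <- rr * cos(th); py <- rr * sin(th)
  true_per <- sum(sqrt(diff(px)^2 + diff(py)^2))
  true_area <- abs(sum(px[-1] * py[-length(py)] - px[-length(px)] * py[-1])) / 2
  rmax <- max(rr)
  half <- ceiling(rmax) + 10L
  n <- 2L * half + 1L
  cx <- half + 1
  rho <- outer(seq_len(n), seq_len(n),
               function(i, j) sqrt((i - cx)^2 + (j - cx)^2))
  ang <- outer(seq_len(n), seq_len(n), function(i, j) atan2(j - cx, i - cx))
  mask <- (rho <= rfun(ang)) * 1L
  list(mask = binary_mask(mask, pixel_size),
       true_area = true_area * pixel_size^2,
       true_perimeter = true_per * pixel_size,
       true_ratio = normalized_perimeter(true_area, true_per),
       raster_area = sum(mask) * pixel_size^2)
}

#' Synthetic invasion sequence with a known solitary-area schedule
#'
#' A fixed central disk aggregate plus square solitary blobs appearing
#' cumulatively over time at random non-touching positions. The ground-truth
#' invasion series is measured from the generator's own rasterized masks, so
#' recovery on the `"mask"` rendering is exact by construction.
#'
#' @param solitary_count_schedule cumulative number of detached blobs
#'   present at each frame (non-decreasing; length = number of frames).
#' @param central_radius_px central aggregate radius, px.
#' @param blob_side_px solitary blob side, px. The default (20 px, i.e.
#'   400 µm² at 1 µm/px) is the scale of a small multicellular cluster and
#'   lies inside the segmentation's guaranteed-accuracy regime.
#' @param frame_shape `c(rows, cols)` px.
#' @param pixel_size µm per pixel.
#' @param interval_min minutes between frames.
#' @param render `"mask"` (frames are the binary truth) or `"texture"`
#'   (frames rendered with [render_textured_frame()] noise statistics).
#' @param background_sd,variance_ratio texture rendering parameters.
#' @param seed integer seed.
#' @return list with `timelapse` (`"texture"` render), `masks` (list of
#'   truth [binary_mask()]s), `times` (hours) and `truth`
#'   (`InvasionSeries` computed from the truth masks).
#' @export
make_invasion_sequence <- function(solitary_count_schedule,
                                   central_radius_px = 40, blob_side_px = 20L,
                                   frame_shape = c(256L, 256L), pixel_size = 1,
                                   interval_min = 60,
                                   render = c("mask", "texture"),
                                   background_sd = 1, variance_ratio = 10,
                                   seed = 1L) {
  render <- match.arg(render)
  stop_if_not(all(diff(solitary_count_schedule) >= 0),
              "schedule must be non-decreasing")
  n_frames <- length(solitary_count_schedule)
  n_max <- solitary_count_schedule[n_frames]
  withr::with_seed(seed, {
    nr <- frame_shape[1]; nc <- frame_shape[2]
    cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
    central <- (outer(seq_len(nr), seq_len(nc), function(i, j)
      (i - cx)^2 + (j - cy)^2 <= central_radius_px^2)) * 1L
    occ <- bin_dilate(central, 2L)
    blob_pos <- vector("list", n_max)
    for (b in seq_len(n_max)) {
      pos <- place_rect(occ, blob_side_px, blob_side_px)
      blob_pos[[b]] <- pos
      occ[(pos[1] - 2L):(pos[1] + blob_side_px + 1L),
          (pos[2] - 2L):(pos[2] + blob_side_px + 1L)] <- 1L
    }
    masks <- lapply(seq_len(n_frames), function(f) {
      m <- central
      nb <- solitary_count_schedule[f]
      for (b in seq_len(nb)) {
        p <- blob_pos[[b]]
        m[p[1]:(p[1] + blob_side_px - 1L), p[2]:(p[2] + blob_side_px - 1L)] <- 1L
      }
      binary_mask(m, pixel_size)
    })
    times <- (seq_len(n_frames) - 1L) * interval_min / 60
    truth <- invasion_series(masks, times = times, min_area = 0)
    tl <- if (render == "texture") {
      frames <- lapply(seq_len(n_frames), function(f)
        calibrated_frame(render_texture(masks[[f]]$pixels, background_sd,
                                        variance_ratio),
                         pixel_size, time = times[f]))
      time_lapse(frames, interval_min)
    } else {
      time_lapse(lapply(seq_len(n_frames), function(f)
        calibrated_frame(masks[[f]]$pixels + 0, pixel_size,
                         time = times[f])), interval_min)
    }
    list(timelapse = tl, masks = masks, times = times, truth = truth)
  })
}

#' Synthetic two-channel co-localization scene
#'
#' Cells are rectangular ROIs tiled over the frame. Within cell `i`, channel
#' A is standard normal and channel B is
#' `rho_i A + sqrt(1 - rho_i^2) noise`, so the per-cell population Pearson
#' correlation is exactly `rho_i`. Background pixels carry independent
#' low-amplitude noise in both channels.
#'
#' @param rho population correlation; a scalar or one value per cell.
#' @param n_cells number of cell ROIs.
#' @param pixels_per_cell ROI size in pixels (realized exactly as a
#'   rectangle).
#' @param pixel_size µm per pixel.
#' @param background_sd background noise SD.
#' @param seed integer seed.
#' @return list with `chanA`, `chanB` ([calibrated_frame()]s), `cell_masks`
#'   (list of [binary_mask()]), `truth_rho` (per cell).
#' @export
make_coloc_pair <- function(rho, n_cells = 38L, pixels_per_cell = 2000L,
                            pixel_size = 1, background_sd = 0.05, seed = 1L) {
  rho <- rep_len(rho, n_cells)
  stop_if_not(all(abs(rho) <= 1), "rho must be in [-1, 1]")
  h <- max(floor(sqrt(pixels_per_cell)), 1L)
  w <- ceiling(pixels_per_cell / h)
  gap <- 4L
  per_row <- ceiling(sqrt(n_cells))
  nrows <- ceiling(n_cells / per_row)
  nr <- nrows * (h + gap) + gap
  nc <- per_row * (w + gap) + gap
  withr::with_seed(seed, {
    A <- matrix(rnorm(nr * nc, sd = background_sd), nr, nc)
    B <- matrix(rnorm(nr * nc, sd = background_sd), nr, nc)
    masks <- vector("list", n_cells)
    for (ci in seq_len(n_cells)) {
      ri <- (ci - 1L) %/% per_row; cj <- (ci - 1L) %% per_row
      i0 <- gap + ri * (h + gap) + 1L
      j0 <- gap + cj * (w + gap) + 1L
      m <- matrix(0L, nr, nc)
      block <- matrix(1L, h, w)
      extra <- h * w - pixels_per_cell
      if (extra > 0) block[1L, seq_len(extra)] <- 0L
      m[i0:(i0 + h - 1L), j0:(j0 + w - 1L)] <- block
      idx <- which(m == 1L)
      a <- rnorm(length(idx))
      b <- rho[ci] * a + sqrt(1 - rho[ci]^2) * rnorm(length(idx))
      A[idx] <- a; B[idx] <- b
      masks[[ci]] <- binary_mask(m, pixel_size)
    }
    list(chanA = calibrated_frame(A, pixel_size, channel = "A"),
         chanB = calibrated_frame(B, pixel_size, channel = "B"),
         cell_masks = masks, truth_rho = rho)
  })
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' The control sample expresses every gene at a baseline Ct; in each treated
#' sample the target-gene Ct is shifted by `-log2(fold)` relative to the
#' reference gene, so the true 2^-ddCt fold change is exactly the requested
#' value. Gaussian noise of SD `ct_noise_sd` is added to every Ct, and an
#' optional per-sample plate offset shifts all Cts of a sample equally
#' (which the ddCt analysis must cancel).
#'
#' @param fold_changes named numeric vector, true fold per target gene in
#'   the treated sample.
#' @param treated_sample,control_sample sample labels.
#' @param reference_gene housekeeping gene label.
#' @param base_ct baseline Ct of target genes in the control.
#' @param ref_ct Ct of the reference gene.
#' @param ct_noise_sd replicate noise SD in cycles (0 for exact tables).
#' @param n_replicates replicates per (sample, gene).
#' @param plate_offsets optional named numeric, per-sample additive offset.
#' @param seed integer seed.
#' @return list with `table` (`CtTable`) and `truth` (named fold changes).
#' @export
simulate_ct_table <- function(fold_changes, treated_sample = "KO",
                              control_sample = "WT", reference_gene = "ACTB",
                              base_ct = 25, ref_ct = 18, ct_noise_sd = 0.2,
                              n_replicates = 3L, plate_offsets = NULL,
                              seed = 1L) {
  stop_if_not(!is.null(names(fold_changes)) && all(nzchar(names(fold_changes))),
              "fold_changes must be named by gene")
  stop_if_not(all(fold_changes > 0), "fold changes must be > 0")
  samples <- c(control_sample, treated_sample)
  genes <- c(names(fold_changes), reference_gene)
  withr::with_seed(seed, {
    rows <- list()
    for (s in samples) for (g in genes) for (rep_i in seq_len(n_replicates)) {
      ct <- if (g == reference_gene) ref_ct
            else if (s == control_sample) base_ct
            else base_ct - log2(fold_changes[[g]])
      off <- if (!is.null(plate_offsets) && s %in% names(plate_offsets))
        plate_offsets[[s]] else 0
      ct <- ct + off +
        if (ct_noise_sd > 0) rnorm(1, sd = ct_noise_sd) else 0
      rows[[length(rows) + 1L]] <- data.frame(sample = s, gene = g,
                                              replicate = rep_i, ct = ct)
    }
    list(table = as_ct_table(do.call(rbind, rows)), truth = fold_changes)
  })
}
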