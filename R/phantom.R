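# Synthetic coronal knee phantoms: femur/tibia with cartilage rims, two thin
# wedge menisci near the joint-space margins, ligament-like distractor strips
# with meniscus-like intensity, intensity inhomogeneity, a smooth
# multiplicative bias field, additive noise and per-case affine + elastic
# shape jitter. Geometry is 2-d extruded with smooth z-modulation so per-slice
# extents vary (exercising the std-margin ROI rule).

#' Parameters of the knee phantom generator
#'
#' Defaults emulate the regime of high-resolution coronal knee MR at desk
#' scale: a thin meniscus occupying well under 2% of the pixels of
#' meniscus-bearing slices, adjacent ligament-like structures within
#' `distractor_contrast` of the meniscus intensity, within-meniscus intensity
#' inhomogeneity, per-patient shape variation, and z-score-normalized output.
#'
#' @param image_size In-plane size in pixels (128 at desk scale; 512 works).
#' @param n_slices Number of coronal slices.
#' @param pixel_size_mm,slice_thickness_mm Geometry metadata.
#' @param meniscus_thickness_px Range (min, max) of the peak meniscus
#'   thickness in pixels at `image_size = 128`; scaled proportionally.
#' @param shape_jitter Amplitude of the per-case elastic deformation as a
#'   fraction of `image_size`.
#' @param bias_field_strength Log-amplitude of the smooth multiplicative
#'   intensity bias field.
#' @param noise_sigma Additive Gaussian noise standard deviation on the raw
#'   intensity scale (structure intensities span about 0.05-0.85).
#' @param distractor_contrast Intensity offset of the ligament analogs from
#'   the meniscus, as a fraction of the raw dynamic range.
#' @param inhomogeneity Relative amplitude of the within-meniscus intensity
#'   modulation.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 128L, n_slices = 16L,
                           pixel_size_mm = 0.3125, slice_thickness_mm = 0.5,
                           meniscus_thickness_px = c(4, 6),
                           shape_jitter = 0.015, bias_field_strength = 0.1,
                           noise_sigma = 0.04, distractor_contrast = 0.05,
                           inhomogeneity = 0.25) {
  stopifnot(image_size >= 32, n_slices >= 4,
            length(meniscus_thickness_px) == 2,
            distractor_contrast >= 0, noise_sigma >= 0)
  structure(list(image_size = as.integer(image_size),
                 n_slices = as.integer(n_slices),
                 pixel_size_mm = pixel_size_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 meniscus_thickness_px = meniscus_thickness_px,
                 shape_jitter = shape_jitter,
                 bias_field_strength = bias_field_strength,
                 noise_sigma = noise_sigma,
                 distractor_contrast = distractor_contrast,
                 inhomogeneity = inhomogeneity),
            class = "phantom_params")
}

# raw-scale structure intensities; dynamic range spans bg to cartilage
PHANTOM_BASE <- c(bg = 0.05, femur = 0.55, fcart = 0.85, tibia = 0.55,
                  tcart = 0.85, meniscus = 0.35)
PHANTOM_RANGE <- 0.8

# run code under a seed without disturbing the caller's RNG stream
with_case_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# low-frequency random field: gh x gw x gz normal grid upsampled to (S, S, Z)
smooth_field3 <- function(S, Z, gh = 3L, gw = 3L, gz = 2L) {
  grid <- array(stats::rnorm(gh * gw * gz), c(gh, gw, gz))
  planes <- lapply(seq_len(gz), function(k) {
    cpp_resize_bilinear(grid[, , k, drop = TRUE] + 0, S, S)
  })
  out <- array(0, c(S, S, Z))
  zc <- (seq_len(Z) - 0.5) / Z * gz + 0.5   # pixel-centre mapping into grid
  for (k in seq_len(Z)) {
    z0 <- floor(zc[k])
    f <- zc[k] - z0
    a <- min(max(z0, 1), gz)
    b <- min(max(z0 + 1, 1), gz)
    out[, , k] <- (1 - f) * planes[[a]] + f * planes[[b]]
  }
  out
}

#' Generate one phantom case
#'
#' A deterministic function of `(params, case_seed)`: the same pair always
#' yields a bit-identical case, and the case RNG never leaks into the
#' caller's random stream.
#'
#' @param params A [phantom_params()].
#' @param case_seed Integer seed identifying the patient.
#' @return An object of class `phantom_case`: `volume` ([mr_volume()],
#'   z-score normalized), `labels6` ([label_volume()]), binary
#'   `distractor_mask`, and ground-truth `side_masks` (`medial`, `lateral`).
#' @export
generate_case <- function(params, case_seed) {
  stopifnot(inherits(params, "phantom_params"))
  with_case_seed(as.integer(case_seed), generate_case_impl(params, case_seed))
}

generate_case_impl <- function(params, case_seed) {
  S <- params$image_size
  Z <- params$n_slices
  sc <- S / 128                        # geometry scale relative to reference
  laterality <- sample(c("right", "left"), 1)

  # per-case affine + elastic jitter applied to all structures
  theta <- stats::rnorm(1, 0, 0.04)
  zoom <- exp(stats::rnorm(1, 0, 0.03))
  shift <- stats::rnorm(2, 0, 0.015 * S)
  ey <- smooth_field3(S, 1, 4, 4, 1)[, , 1] * params$shape_jitter * S
  ex <- smooth_field3(S, 1, 4, 4, 1)[, , 1] * params$shape_jitter * S
  yy <- matrix(seq_len(S), S, S)
  xx <- matrix(seq_len(S), S, S, byrow = TRUE)
  cy <- (S + 1) / 2
  cx <- (S + 1) / 2
  U <- cy + (cos(theta) * (yy - cy - shift[1]) - sin(theta) * (xx - cx - shift[2])) / zoom + ey
  V <- cx + (sin(theta) * (yy - cy - shift[1]) + cos(theta) * (xx - cx - shift[2])) / zoom + ex

  # anatomy layout (transformed coordinates)
  yj <- 0.55 * S                       # joint line
  fem_c <- c(0.29 * S, cx)
  fem_ab <- c(0.21 * S, 0.31 * S)
  tib_c <- c(0.78 * S, cx)
  tib_ab <- c(0.17 * S, 0.33 * S)
  cart_t <- max(2, round(3 * sc))

  femur <- ((U - fem_c[1]) / fem_ab[1])^2 + ((V - fem_c[2]) / fem_ab[2])^2 <= 1
  fcart <- !femur & U > fem_c[1] &
    ((U - fem_c[1]) / (fem_ab[1] + cart_t))^2 +
    ((V - fem_c[2]) / (fem_ab[2] + cart_t))^2 <= 1
  tibia <- ((U - tib_c[1]) / tib_ab[1])^4 + ((V - tib_c[2]) / tib_ab[2])^4 <= 1
  tcart <- !tibia & U < tib_c[1] &
    ((U - tib_c[1]) / (tib_ab[1] + cart_t))^4 +
    ((V - tib_c[2]) / (tib_ab[2] + cart_t))^4 <= 1

  # meniscus geometry: wedge cross-sections near the joint-space margins
  tk <- stats::runif(1, params$meniscus_thickness_px[1],
                     params$meniscus_thickness_px[2]) * sc
  w0 <- stats::runif(1, 0.10, 0.14) * S
  x_out <- c(left = cx - 0.33 * S + stats::rnorm(1, 0, 0.01 * S),
             right = cx + 0.33 * S + stats::rnorm(1, 0, 0.01 * S))
  zc_m <- (Z + 1) / 2 + stats::rnorm(1, 0, 0.05 * Z)
  zr_m <- 0.38 * Z * exp(stats::rnorm(1, 0, 0.1))
  zphase <- stats::runif(1, 0, 2 * pi)
  zamp <- stats::runif(1, 1, 2.5) * sc

  labels <- array(0L, c(S, S, Z))
  distractor <- array(FALSE, c(S, S, Z))
  img <- array(PHANTOM_BASE["bg"], c(S, S, Z))
  lig_w <- max(2, round(4 * sc))
  lig_off <- max(2, round(3 * sc))
  lig_int <- PHANTOM_BASE["meniscus"] +
    0.6 * params$distractor_contrast * PHANTOM_RANGE
  inhom <- smooth_field3(S, Z, 4, 4, 2)

  for (k in seq_len(Z)) {
    lab <- array(0L, c(S, S))
    lab[femur] <- 1L
    lab[fcart] <- 2L
    lab[tibia] <- 3L
    lab[tcart] <- 4L
    mz <- 1 - ((k - zc_m) / zr_m)^2
    mz <- if (mz > 0) sqrt(mz) else 0
    men <- array(FALSE, c(S, S))
    if (mz > 0) {
      wz <- w0 * mz
      tz <- tk * (0.7 + 0.3 * mz)
      sx <- zamp * sin(2 * pi * k / Z + zphase)
      if (wz >= 2 && tz >= 1) {
        for (side in c("left", "right")) {
          xo <- x_out[side] + sx
          # distance from the outer rim, increasing toward the knee centre
          din <- if (side == "left") V - xo else xo - V
          inside <- din >= 0 & din <= wz
          thick <- tz * (1 - din / wz)
          men_side <- inside & U <= yj & U > yj - pmax(thick, 0)
          men <- men | men_side
        }
      }
      lab[men] <- 5L   # meniscus overwrites whatever it overlaps
    }
    # ligament analogs flank each meniscus; cruciate analog sits centrally
    lig <- array(FALSE, c(S, S))
    sx <- zamp * sin(2 * pi * k / Z + zphase)
    for (side in c("left", "right")) {
      xo <- x_out[side] + sx
      band <- if (side == "left") {
        V <= xo - lig_off & V >= xo - lig_off - lig_w
      } else {
        V >= xo + lig_off & V <= xo + lig_off + lig_w
      }
      lig <- lig | (band & U >= yj - 0.18 * S & U <= yj + 0.14 * S)
    }
    if (k >= zc_m - 0.25 * Z && k <= zc_m + 0.25 * Z) {
      lig <- lig | (abs(V - cx) <= max(2, 3 * sc) &
                      U >= yj - 0.12 * S & U <= yj + 0.02 * S)
    }
    lig <- lig & lab == 0L
    sl <- array(PHANTOM_BASE["bg"], c(S, S))
    sl[lab == 1L] <- PHANTOM_BASE["femur"]
    sl[lab == 2L] <- PHANTOM_BASE["fcart"]
    sl[lab == 3L] <- PHANTOM_BASE["tibia"]
    sl[lab == 4L] <- PHANTOM_BASE["tcart"]
    sl[lab == 5L] <- PHANTOM_BASE["meniscus"] *
      (1 + params$inhomogeneity * inhom[, , k][lab == 5L])
    sl[lig] <- lig_int
    labels[, , k] <- lab
    distractor[, , k] <- lig
    img[, , k] <- sl
  }

  # thin wedge tips can shed 1-pixel diagonal slivers that are disconnected
  # under 6-connectivity; relabel anything beyond the two main components
  comp <- cpp_label3d(array(as.integer(labels == 5L), dim(labels)))
  n_comp <- max(comp)
  if (n_comp > 2) {
    keep <- order(tabulate(comp), decreasing = TRUE)[1:2]
    labels[labels == 5L & !(comp %in% keep)] <- 0L
  }

  bias <- smooth_field3(S, Z, 3, 3, 2)
  img <- img * exp(params$bias_field_strength * bias)
  if (params$noise_sigma > 0) {
    img <- img + stats::rnorm(length(img), 0, params$noise_sigma)
  }

  vol <- normalize_zscore(mr_volume(img, params$pixel_size_mm,
                                    params$slice_thickness_mm,
                                    patient_id = sprintf("case%06d", case_seed),
                                    laterality = laterality))
  lv <- label_volume(labels)
  sides <- split_meniscus(lv, laterality)
  structure(list(volume = vol, labels6 = lv, distractor_mask = distractor,
                 side_masks = sides, params = params,
                 case_seed = as.integer(case_seed)),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> seed %d, %s knee, %d meniscus voxels\n",
              x$case_seed, x$volume$laterality,
              sum(x$labels6$labels == MENISCUS_CLASS)))
  invisible(x)
}

# largest-remainder apportionment; ties resolved toward the later split
split_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- raw - base
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(rem, seq_along(rem), decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Generate a phantom dataset manifest
#'
#' Draws `n_patients` cases with deterministic per-patient seeds, assigns
#' train/validation/test splits by a seeded shuffle with largest-remainder
#' rounding, and (optionally) writes NIfTI volumes, label maps and a JSON
#' manifest to `out_dir`. Cases are always reproducible from the manifest
#' alone via [load_case()].
#'
#' @param n_patients Number of phantom patients.
#' @param params A [phantom_params()].
#' @param split Fractions (train, val, test); must sum to 1.
#' @param seed Dataset seed driving patient seeds and the split shuffle.
#' @param out_dir Optional directory for NIfTI + JSON output.
#' @return An object of class `phantom_manifest`: `params`, `seed` and a
#'   tibble `cases` with `patient_id`, `case_seed`, `split`.
#' @export
generate_dataset <- function(n_patients, params = phantom_params(),
                             split = c(train = 0.7, val = 0.15, test = 0.15),
                             seed = 1L, out_dir = NULL) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (n_patients < 3 && sum(split > 0) == 3) {
    stop("need at least 3 patients for a three-way split")
  }
  counts <- split_counts(n_patients, split)
  case_seeds <- (as.integer(seed) + 104729L * seq_len(n_patients)) %% 2147483647L
  assignment <- with_case_seed(as.integer(seed), {
    ord <- sample.int(n_patients)
    sp <- rep(c("train", "val", "test"), counts)
    sp[order(ord)]
  })
  cases <- tibble::tibble(
    patient_id = sprintf("case%06d", case_seeds),
    case_seed = as.integer(case_seeds),
    split = assignment
  )
  manifest <- structure(list(params = params, seed = as.integer(seed),
                             cases = cases),
                        class = "phantom_manifest")
  if (!is.null(out_dir)) write_dataset(manifest, out_dir)
  manifest
}

#' Regenerate a case listed in a manifest
#'
#' @param manifest A [generate_dataset()] manifest.
#' @param patient_id Patient identifier from `manifest$cases`.
#' @return The [generate_case()] result for that patient.
#' @export
load_case <- function(manifest, patient_id) {
  row <- manifest$cases[manifest$cases$patient_id == patient_id, ]
  if (nrow(row) != 1) stop("unknown patient_id: ", patient_id)
  generate_case(manifest$params, row$case_seed)
}

#' @export
print.phantom_manifest <- function(x, ...) {
  cat(sprintf("<phantom_manifest> %d patients (%s), seed %d, %dpx x %d slices\n",
              nrow(x$cases),
              paste(table(factor(x$cases$split, c("train", "val", "test"))),
                    collapse = "/"),
              x$seed, x$params$image_size, x$params$n_slices))
  invisible(x)
}

#' Plain intensity-window baseline segmenter
#'
#' Thresholds the volume inside the central intensity quantile band of a
#' reference mask (the over-segmentation-prone baseline that leaks into
#' ligament-like structures with meniscus-like intensity).
#'
#' @param volume An [mr_volume()].
#' @param reference_mask Binary mask whose intensities define the window.
#' @param probs Quantile pair defining the window.
#' @return Binary 3-d array.
#' @export
threshold_segment <- function(volume, reference_mask, probs = c(0.05, 0.95)) {
  vals <- volume$voxels[reference_mask != 0]
  if (!length(vals)) stop("reference mask is empty")
  q <- stats::quantile(vals, probs, names = FALSE)
  array(as.integer(volume$voxels >= q[1] & volume$voxels <= q[2]),
        dim(volume$voxels))
}
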