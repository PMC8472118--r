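# End-to-end experiment runner for the four-way ablation:
#   A  whole-image two-class U-Net
#   B  localized ROI + supervised U-Net
#   C  localized ROI + concatenation-conditioned cGAN
#   D  localized ROI + object-aware cGAN
# B, C and D share the stage-one localizer for a controlled comparison.

#' Configuration of one ablation run
#'
#' Sub-configuration seeds are derived deterministically from `seed`, so a
#' record's configuration alone reproduces the run. The stage-two seed is
#' shared across methods B/C/D: method D with `lambda_gan = 0` is exactly
#' method B.
#'
#' @param method `"A"`, `"B"`, `"C"` or `"D"`.
#' @param manifest A [generate_dataset()] manifest.
#' @param seed Global seed of the run.
#' @param base_width First-level channel width of every network in the run.
#' @param max_width Per-level width cap (see [seg_net_config()]).
#' @param loc_cfg,stage2_cfg,whole_cfg Optional overrides for the localizer
#'   training ([segmenter_train_config()]), stage-two training
#'   ([train_config()]) and whole-image training configurations.
#' @param d_cfg Discriminator architecture ([disc_net_config()]).
#' @param target_size Stage-two ROI resolution.
#' @param min_size Minimum in-plane ROI size before resampling.
#' @param margin_mode Margin rule variant for [compute_roi()].
#' @param threshold Probability threshold for final masks.
#' @param oracle_roi Debug flag: use ground-truth localization at test time.
#' @param out_dir Optional output directory for CSVs and checkpoints.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(method = c("D", "A", "B", "C"), manifest,
                              seed = 1L, base_width = 8L,
                              max_width = 2L * base_width,
                              loc_cfg = NULL, stage2_cfg = NULL,
                              whole_cfg = NULL, d_cfg = NULL,
                              target_size = 64L, min_size = 32L,
                              margin_mode = "population", threshold = 0.5,
                              oracle_roi = FALSE, out_dir = NULL) {
  method <- match.arg(method)
  seed <- as.integer(seed)
  loc_cfg <- loc_cfg %||% segmenter_train_config(
    epochs = 10L, batch_size = 8L, learning_rate = 3e-3,
    slices_per_epoch = 64L, validate_every = 2L, min_val_dsc = 10)
  whole_cfg <- whole_cfg %||% segmenter_train_config(
    epochs = 6L, batch_size = 8L, learning_rate = 3e-3,
    slices_per_epoch = 64L, validate_every = 2L)
  stage2_cfg <- stage2_cfg %||% train_config(
    epochs = 8L, batch_size = 16L, learning_rate_g = 3e-3,
    learning_rate_d = 3e-3, slices_per_epoch = 192L, min_val_dsc = 50)
  loc_cfg$seed <- seed + 11L
  whole_cfg$seed <- seed + 31L
  stage2_cfg$seed <- seed + 23L
  stage2_cfg$conditioning <- switch(method, C = "concat", "object_aware")
  if (method %in% c("A", "B")) stage2_cfg$lambda_gan <- 0
  d_cfg <- d_cfg %||% disc_net_config(base_width = base_width,
                                      max_width = max_width)
  structure(list(method = method, manifest = manifest, seed = seed,
                 base_width = as.integer(base_width),
                 max_width = max_width, loc_cfg = loc_cfg,
                 whole_cfg = whole_cfg, stage2_cfg = stage2_cfg, d_cfg = d_cfg,
                 target_size = as.integer(target_size),
                 min_size = as.integer(min_size), margin_mode = margin_mode,
                 threshold = threshold, oracle_roi = oracle_roi,
                 out_dir = out_dir),
            class = "experiment_config")
}

# image half belonging to one side, given knee laterality: the medial side of
# a right knee lies toward the body midline, i.e. the higher column indices
side_half_mask <- function(vol_dim, side, laterality) {
  W <- vol_dim[2]
  xx <- array(rep(seq_len(W), each = vol_dim[1]), vol_dim)
  hi <- xx > (W + 1) / 2
  if (xor(side == "medial", laterality == "left")) hi else !hi
}

#' Run one ablation method end to end
#'
#' Trains the method's stages on the manifest's train/validation splits,
#' predicts the held-out test volumes (ROI localization from *predicted*
#' labels unless `oracle_roi`), pastes stage-two masks back to full
#' resolution, and evaluates per patient per side.
#'
#' @param cfg An [experiment_config()].
#' @param localizer Optional pre-trained six-class localizer (shared across
#'   methods B/C/D); trained on the fly when absent.
#' @param cases Optional pre-generated named list of `phantom_case` objects.
#' @param shared Optional environment caching work that is identical across
#'   methods sharing a localizer and seed (ground-truth ROI stacks, test-time
#'   localizer predictions).
#' @return An object of class `run_record`: the resolved `config`, training
#'   histories, tibbles `per_patient` and `cohort`, and output paths.
#' @export
run_method <- function(cfg, localizer = NULL, cases = NULL, shared = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  manifest <- cfg$manifest
  cases <- cases %||% load_split_cases(manifest, c("train", "val", "test"))
  split_of <- stats::setNames(manifest$cases$split, manifest$cases$patient_id)
  ids <- list(train = names(split_of)[split_of == "train"],
              val = names(split_of)[split_of == "val"],
              test = names(split_of)[split_of == "test"])
  histories <- list()

  if (cfg$method == "A") {
    bin <- function(cs) array(as.integer(cs$labels6$labels == MENISCUS_CLASS),
                              dim(cs$labels6$labels))
    tr <- volumes_to_slices(lapply(cases[ids$train], function(cs) cs$volume$voxels),
                            lapply(cases[ids$train], bin))
    va <- volumes_to_slices(lapply(cases[ids$val], function(cs) cs$volume$voxels),
                            lapply(cases[ids$val], bin))
    net_cfg <- seg_net_config(1L, 2L, 4L, cfg$base_width, cfg$max_width)
    fit <- train_segmenter(tr, va, net_cfg, cfg$whole_cfg, fg_class = 1L)
    histories$whole <- fit$history
    predict_patient <- function(cs) {
      prob <- predict_prob_volume(fit$net, cs$volume$voxels)
      pred <- array(as.integer(prob[, , 2L, ] >= cfg$threshold),
                    dim(cs$volume$voxels))
      lapply(stats::setNames(c("medial", "lateral"), c("medial", "lateral")),
             function(side) {
               pred * side_half_mask(dim(pred), side, cs$volume$laterality)
             })
    }
    stage2 <- NULL
  } else {
    if (is.null(localizer)) {
      loc_net_cfg <- seg_net_config(1L, 6L, 4L, cfg$base_width, cfg$max_width)
      loc <- train_localizer(manifest, loc_net_cfg, cfg$loc_cfg, cases = cases)
      histories$localizer <- loc$history
      localizer <- loc$net
    }
    # training/validation ROIs come from ground-truth labels (stable targets)
    make_stacks <- function(id_set) {
      key <- paste0("stacks_", paste(range(id_set), collapse = "_"))
      if (!is.null(shared) && !is.null(shared[[key]])) return(shared[[key]])
      st <- unlist(lapply(cases[id_set], function(cs) {
        purrr::compact(
          extract_roi_stacks(cs$volume, cs$labels6, gt_labels = cs$labels6,
                             target_size = cfg$target_size,
                             min_size = cfg$min_size,
                             margin_mode = cfg$margin_mode))
      }), recursive = FALSE)
      if (!is.null(shared)) shared[[key]] <- st
      st
    }
    g_cfg <- seg_net_config(1L, 2L, 4L, cfg$base_width, cfg$max_width)
    stage2 <- train_adversarial(make_stacks(ids$train), make_stacks(ids$val),
                                g_cfg, cfg$d_cfg, cfg$stage2_cfg)
    histories$stage2 <- stage2$history
    predict_patient <- function(cs) {
      lkey <- paste0("loc_", cs$volume$patient_id)
      loc_labels <- if (cfg$oracle_roi) {
        cs$labels6
      } else if (!is.null(shared) && !is.null(shared[[lkey]])) {
        shared[[lkey]]
      } else {
        ll <- segment_multiclass(cs$volume, localizer)
        if (!is.null(shared)) shared[[lkey]] <- ll
        ll
      }
      empty <- array(0L, dim(cs$volume$voxels))
      stacks <- tryCatch(
        extract_roi_stacks(cs$volume, loc_labels, gt_labels = NULL,
                           target_size = cfg$target_size,
                           min_size = cfg$min_size,
                           margin_mode = cfg$margin_mode),
        error = function(e) {
          warning("localization found no meniscus for ", cs$volume$patient_id,
                  ": ", conditionMessage(e))
          list(medial = NULL, lateral = NULL)
        })
      lapply(stacks, function(st) {
        if (is.null(st)) return(empty)
        pm <- predict_mask(st, stage2$generator, cfg$threshold)
        paste_back(pm, st$roi, dim(cs$volume$voxels))
      })
    }
  }

  per_patient <- dplyr::bind_rows(lapply(ids$test, function(id) {
    cs <- cases[[id]]
    preds <- predict_patient(cs)
    dplyr::bind_rows(lapply(c("medial", "lateral"), function(side) {
      gt <- array(as.integer(cs$side_masks[[side]]), dim(cs$volume$voxels))
      dplyr::bind_cols(tibble::tibble(patient_id = id, side = side),
                       evaluate_masks(preds[[side]], gt))
    }))
  }))
  cohort <- dplyr::bind_rows(lapply(c("medial", "lateral"), function(s) {
    aggregate_cohort(per_patient[per_patient$side == s, ], side = s)
  }))

  record <- structure(list(method = cfg$method, config = cfg,
                           histories = histories, per_patient = per_patient,
                           cohort = cohort, paths = NULL),
                      class = "run_record")
  if (!is.null(cfg$out_dir)) record <- write_run_record(record, cfg$out_dir)
  record
}

write_run_record <- function(record, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tag <- paste0("method", record$method, "_seed", record$config$seed)
  paths <- list(
    per_patient = file.path(out_dir, paste0(tag, "_per_patient.csv")),
    cohort = file.path(out_dir, paste0(tag, "_cohort.csv"))
  )
  utils::write.csv(record$per_patient, paths$per_patient, row.names = FALSE)
  utils::write.csv(record$cohort, paths$cohort, row.names = FALSE)
  for (nm in names(record$histories)) {
    paths[[paste0("history_", nm)]] <-
      file.path(out_dir, paste0(tag, "_history_", nm, ".csv"))
    utils::write.csv(record$histories[[nm]], paths[[paste0("history_", nm)]],
                     row.names = FALSE)
  }
  record$paths <- paths
  record
}

#' Re-execute a run from its record
#'
#' A record's configuration fully determines the run, so this reproduces the
#' metrics (and any CSV outputs) exactly in the same environment.
#'
#' @param record A [run_method()] record.
#' @param localizer,cases Optional shared objects, as in [run_method()].
#' @return A fresh `run_record`.
#' @export
rerun_record <- function(record, localizer = NULL, cases = NULL) {
  run_method(record$config, localizer = localizer, cases = cases)
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> method %s, seed %d, %d test patients\n",
              x$method, x$config$seed, length(unique(x$per_patient$patient_id))))
  m <- x$cohort[x$cohort$metric == "dsc", ]
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %s DSC %.2f (±%.2f)\n", m$side[i], m$mean[i], m$sd[i]))
  }
  invisible(x)
}

#' Compare ablation runs on the same test split
#'
#' @param records List of [run_method()] records evaluated on identical test
#'   patients.
#' @return An object of class `method_comparison`: `table` (per side, metric
#'   and method: mean, sd, best flag) and `diffs` (pairwise mean differences
#'   in percentage points).
#' @export
compare_methods <- function(records) {
  if (length(records) < 2) stop("need at least two records to compare")
  splits <- lapply(records, function(r) sort(unique(r$per_patient$patient_id)))
  if (!all(vapply(splits[-1], identical, TRUE, splits[[1]]))) {
    stop("records were evaluated on different test splits")
  }
  table <- dplyr::bind_rows(lapply(records, function(r) {
    dplyr::mutate(r$cohort, method = r$method)
  })) %>%
    dplyr::mutate(metric = factor(.data$metric, METRIC_NAMES)) %>%
    dplyr::arrange(.data$side, .data$metric, .data$method) %>%
    dplyr::group_by(.data$side, .data$metric) %>%
    dplyr::mutate(best = .data$mean == max(.data$mean, na.rm = TRUE)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(metric = as.character(.data$metric))
  methods <- vapply(records, `[[`, "", "method")
  pairs <- utils::combn(seq_along(records), 2)
  diffs <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
    a <- records[[pairs[1, j]]]$cohort
    b <- records[[pairs[2, j]]]$cohort
    dplyr::bind_cols(a[, c("side", "metric")],
                     tibble::tibble(method_a = methods[pairs[1, j]],
                                    method_b = methods[pairs[2, j]],
                                    diff_pp = a$mean - b$mean))
  }))
  structure(list(table = table, diffs = diffs), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(x$table,
                  value = sprintf("%.2f (±%.2f)%s", .data$mean, .data$sd,
                                  ifelse(.data$best, "*", ""))),
    id_cols = c("side", "metric"), names_from = "method",
    values_from = "value")
  print(as.data.frame(wide), row.names = FALSE)
  cat("* best mean per side/metric\n")
  invisible(x)
}
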