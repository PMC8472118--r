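# broom-style accessors for fitted/evaluated objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-patient metrics of a run
#'
#' @param x A `run_record`.
#' @param ... Unused.
#' @return Tibble with one row per test patient and side.
#' @export
tidy.run_record <- function(x, ...) x$per_patient

#' One-row summary of a run
#'
#' @param x A `run_record`.
#' @param ... Unused.
#' @return Tibble with the method, seed and per-side mean DSC/PPV.
#' @export
glance.run_record <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$cohort[x$cohort$metric %in% c("dsc", "ppv"), c("side", "metric", "mean")],
    names_from = c("side", "metric"), values_from = "mean")
  dplyr::bind_cols(tibble::tibble(method = x$method, seed = x$config$seed),
                   wide)
}

#' Tidy a training history
#'
#' @param x A `train_history`.
#' @param ... Unused.
#' @return Long tibble: epoch, series, value.
#' @export
tidy.train_history <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"epoch",
                      names_to = "series", values_to = "value",
                      values_drop_na = TRUE)
}

#' Tidy a method comparison
#'
#' @param x A `method_comparison`.
#' @param ... Unused.
#' @return The per-side, per-metric, per-method table.
#' @export
tidy.method_comparison <- function(x, ...) x$table

#' Tidy a confusion-count object
#'
#' @param x A `confusion_counts`.
#' @param ... Unused.
#' @return One-row tibble of counts.
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble::tibble(TP = x[["TP"]], TN = x[["TN"]], FP = x[["FP"]], FN = x[["FN"]])
}
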