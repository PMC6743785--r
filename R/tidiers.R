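#' Tidy the receptive fields of a trained auditory map
#'
#' One row per receptive field: its center in the regression subspace, its
#' bandwidth, and the number of training samples inside one bandwidth
#' (the local-model diagnostics of the learner).
#'
#' @param x An `sfc_auditory_map`.
#' @param ... Unused.
#' @return A tibble with columns `rf`, `z1`..`zr`, `bandwidth`, `n_local`.
#' @export
tidy.sfc_auditory_map <- function(x, ...) {
  z <- as.data.frame(x$rf_centers)
  names(z) <- paste0("z", seq_len(ncol(z)))
  out <- tibble::as_tibble(z)
  tibble::add_column(out, rf = seq_len(nrow(out)), .before = 1) %>%
    dplyr::mutate(bandwidth = x$rf_bw, n_local = x$rf_counts)
}

#' One-row summary of a trained auditory map
#'
#' @param x An `sfc_auditory_map`.
#' @param ... Unused.
#' @return A tibble with the subspace dimension, number of receptive
#'   fields, training size and training mean absolute errors per formant.
#' @export
glance.sfc_auditory_map <- function(x, ...) {
  tibble::tibble(
    subspace_dim = x$r,
    n_receptive_fields = nrow(x$rf_centers),
    n_train = x$n_train,
    train_mae_F1 = x$train_mae[["F1"]],
    train_mae_F2 = x$train_mae[["F2"]],
    train_mae_F3 = x$train_mae[["F3"]]
  )
}

#' Tidy a gestural score
#'
#' @param x An `sfc_score`.
#' @param ... Unused.
#' @return The gesture tibble (one row per gesture).
#' @export
tidy.sfc_score <- function(x, ...) {
  x$gestures
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
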