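#' Multi-channel sEMG recording
#'
#' Container for one subject's perturbation session: a time-by-channel sample
#' matrix, the sampling rate, the perturbation-onset sample index of each
#' trial (time zero of the epoch definitions), the muscle label of each
#' channel, and subject metadata.
#'
#' @param samples numeric matrix, time in rows, one column per channel.
#' @param fs sampling rate in Hz (positive scalar).
#' @param onsets integer vector of perturbation-onset sample indices, one per
#'   trial, each in `[1, nrow(samples)]`.
#' @param muscles character vector of unique channel labels, typically from
#'   `c("TA", "GL", "GM", "SO")`; length must equal `ncol(samples)`.
#' @param meta named list of subject metadata. Recognised fields:
#'   `subject_id`, `group` (`"control"` or `"presarc"`), `sex`, `age` (years),
#'   `body_mass` (kg), `height` (m).
#'
#' @return An object of class `semg_recording`.
#' @export
semg_recording <- function(samples, fs, onsets, muscles, meta = list()) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || anyNA(samples)) {
    abort("`samples` must be a numeric matrix without missing values.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a positive scalar sampling rate in Hz.")
  }
  onsets <- as.integer(onsets)
  if (length(onsets) < 1L || anyNA(onsets) ||
      any(onsets < 1L) || any(onsets > nrow(samples))) {
    abort("`onsets` must be sample indices inside the recording.")
  }
  muscles <- as.character(muscles)
  if (length(muscles) != ncol(samples)) {
    abort("Number of muscle labels must equal the number of channels.")
  }
  if (anyDuplicated(muscles)) {
    abort("Muscle labels must be unique.")
  }
  colnames(samples) <- muscles
  structure(
    list(samples = samples, fs = fs, onsets = onsets,
         muscles = muscles, meta = meta),
    class = "semg_recording"
  )
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf(
    "<semg_recording> %d channels (%s), %d samples @ %g Hz, %d trial(s)\n",
    ncol(x$samples), paste(x$muscles, collapse = ", "),
    nrow(x$samples), x$fs, length(x$onsets)
  ))
  if (!is.null(x$meta$subject_id)) {
    cat(sprintf("  subject %s [%s]\n", x$meta$subject_id,
                x$meta$group %||% "?"))
  }
  invisible(x)
}

#' @export
as_tibble.semg_recording <- function(x, ...) {
  tibble(
    time_s = (seq_len(nrow(x$samples)) - 1) / x$fs,
    as_tibble(x$samples)
  ) %>%
    tidyr::pivot_longer(-"time_s", names_to = "muscle", values_to = "value")
}

#' Plot an sEMG recording
#'
#' Facets the channels and marks perturbation onsets with vertical lines.
#'
#' @param object an [semg_recording].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.semg_recording <- function(object, ...) {
  df <- as_tibble(object)
  df$muscle <- factor(df$muscle, levels = object$muscles)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::geom_vline(
      xintercept = (object$onsets - 1) / object$fs,
      colour = "red", linetype = "dashed", linewidth = 0.3
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$muscle)) +
    ggplot2::labs(x = "time (s)", y = "amplitude")
}
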