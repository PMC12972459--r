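#' Canonical perturbation-locked epoch definitions
#'
#' The five analysis windows, in milliseconds relative to perturbation onset
#' (time zero): a long preparatory window, a pre-voluntary adjustment window,
#' the automatic postural response, a short stabilisation window, and the long
#' post-perturbation stabilisation window. Adjacent boundaries
#' (-250 / -50 / 150 / 350 ms) partition without overlap because windows are
#' half-open.
#'
#' @return A tibble with columns `epoch`, `start_ms`, `end_ms`.
#' @examples
#' epoch_specs()
#' @export
epoch_specs <- function() {
  tibble(
    epoch = c("Pre-prep", "Pre-vol", "Auto-resp", "Stab", "Post-stab"),
    start_ms = c(-2250, -250, -50, 150, 350),
    end_ms = c(-250, -50, 150, 350, 2350)
  )
}

.check_epoch_specs <- function(specs) {
  stopifnot(is.data.frame(specs),
            all(c("epoch", "start_ms", "end_ms") %in% names(specs)))
  if (any(specs$start_ms >= specs$end_ms)) {
    .stop("config", "Epoch start_ms must be smaller than end_ms.")
  }
  specs
}

#' Cut perturbation-locked epoch segments from a recording
#'
#' For each requested trial, each channel and each epoch window, extracts the
#' half-open sample window
#' `[onset + round(start_ms * fs / 1000), onset + round(end_ms * fs / 1000))`
#' and attaches full provenance (subject, group, muscle, trial, epoch).
#'
#' @param recording an [semg_recording], normally already preprocessed with
#'   [preprocess_recording()].
#' @param specs epoch definition table as returned by [epoch_specs()].
#' @param trials integer trial indices to segment; default all trials.
#' @return A tibble with one row per (trial, channel, epoch): provenance
#'   columns `subject_id`, `group`, `muscle`, `trial`, `epoch`, the segment
#'   length `n`, and a list-column `samples` holding the numeric window.
#' @export
segment_epochs <- function(recording, specs = epoch_specs(), trials = NULL) {
  stopifnot(inherits(recording, "semg_recording"))
  specs <- .check_epoch_specs(specs)
  trials <- trials %||% seq_along(recording$onsets)
  if (any(trials < 1L | trials > length(recording$onsets))) {
    .stop("config", "Trial index outside the recording's onset list.")
  }
  fs <- recording$fs
  nt <- nrow(recording$samples)
  meta <- recording$meta

  grid <- tidyr::expand_grid(
    trial = trials,
    muscle = recording$muscles,
    specs
  )
  onset <- recording$onsets[grid$trial]
  i0 <- onset + round(grid$start_ms * fs / 1000)
  i1 <- onset + round(grid$end_ms * fs / 1000) # exclusive
  bad <- which(i0 < 1L | (i1 - 1L) > nt)
  if (length(bad)) {
    .stop("truncated_trial",
          "Epoch '%s' of trial %d falls outside the recording.",
          grid$epoch[bad[1]], grid$trial[bad[1]])
  }
  grid %>%
    mutate(
      subject_id = meta$subject_id %||% NA_character_,
      group = meta$group %||% NA_character_,
      fs = fs,
      n = i1 - i0,
      samples = purrr::pmap(
        list(i0, i1, .data$muscle),
        function(a, b, m) recording$samples[a:(b - 1L), m]
      )
    ) %>%
    select("subject_id", "group", "muscle", "trial", "epoch",
           "start_ms", "end_ms", "fs", "n", "samples")
}
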