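#' Write a recording as delimited text plus a metadata sidecar
#'
#' The signal file is a CSV with one column per channel (header = muscle
#' labels); the sidecar is a key-value text file carrying `fs`, the
#' per-trial `onsets` list, the muscle order and the subject fields, keeping
#' everything human-auditable.
#'
#' @param recording an [semg_recording].
#' @param signal_path,meta_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_recording <- function(recording, signal_path, meta_path) {
  stopifnot(inherits(recording, "semg_recording"))
  readr::write_csv(as_tibble(recording$samples), signal_path)
  m <- recording$meta
  lines <- c(
    paste0("fs: ", format(recording$fs, digits = 15)),
    paste0("onsets: ", paste(recording$onsets, collapse = ",")),
    paste0("muscles: ", paste(recording$muscles, collapse = ",")),
    purrr::imap_chr(m, function(v, k) {
      paste0(k, ": ", format(v, digits = 15))
    })
  )
  writeLines(lines, meta_path)
  invisible(c(signal_path, meta_path))
}

.parse_sidecar <- function(meta_path) {
  lines <- readLines(meta_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(x) if (length(x) > 1) x[[2]] else "", ""))
  setNames(as.list(vals), keys)
}

#' Read a recording from delimited text plus its metadata sidecar
#'
#' Validates on the way in: numeric signal columns, channel count matching
#' the sidecar's muscle list, onsets inside the recording.
#'
#' @param signal_path,meta_path file paths written by [write_recording()].
#' @return An [semg_recording].
#' @export
read_recording <- function(signal_path, meta_path) {
  if (!file.exists(signal_path) || !file.exists(meta_path)) {
    .stop("parse", "Missing input file: %s",
          if (file.exists(signal_path)) meta_path else signal_path)
  }
  sig <- tryCatch(
    suppressWarnings(readr::read_csv(
      signal_path, show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(.default = readr::col_double())
    )),
    error = function(e) .stop("parse", "Cannot parse %s: %s",
                              signal_path, conditionMessage(e))
  )
  if (!nrow(sig) || !ncol(sig)) {
    .stop("parse", "Empty signal file %s.", signal_path)
  }
  bad <- which(!stats::complete.cases(sig))
  if (length(bad)) {
    .stop("parse", "Non-numeric or missing value in %s at data line %d.",
          signal_path, bad[1])
  }
  meta <- .parse_sidecar(meta_path)
  for (k in c("fs", "onsets", "muscles")) {
    if (is.null(meta[[k]])) {
      .stop("parse", "Sidecar %s is missing required key '%s'.", meta_path, k)
    }
  }
  muscles <- strsplit(meta$muscles, ",")[[1]] |> trimws()
  if (length(muscles) != ncol(sig)) {
    .stop("parse",
          "Sidecar %s lists %d muscle labels but %s has %d channels.",
          meta_path, length(muscles), signal_path, ncol(sig))
  }
  onsets <- suppressWarnings(as.integer(strsplit(meta$onsets, ",")[[1]]))
  if (anyNA(onsets) || any(onsets < 1) || any(onsets > nrow(sig))) {
    .stop("parse", "Sidecar %s: onsets must be indices inside the recording.",
          meta_path)
  }
  subject <- meta[setdiff(names(meta), c("fs", "onsets", "muscles"))]
  for (k in intersect(names(subject), c("age", "body_mass", "height"))) {
    subject[[k]] <- as.numeric(subject[[k]])
  }
  semg_recording(as.matrix(sig), fs = as.numeric(meta$fs), onsets = onsets,
                 muscles = muscles, meta = subject)
}

#' Write / read a long feature table
#'
#' Plain-CSV round trip of the long feature table (one row per segment and
#' feature).
#'
#' @param table long feature tibble.
#' @param path CSV path.
#' @return `write_feature_table()`: the path, invisibly;
#'   `read_feature_table()`: the tibble.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  # sex codes "F"/"T"-like strings must not be guessed as logicals
  suppressWarnings(readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      subject_id = readr::col_character(), group = readr::col_character(),
      muscle = readr::col_character(), epoch = readr::col_character(),
      feature = readr::col_character(), sex = readr::col_character(),
      .default = readr::col_guess()
    )
  ))
}

#' Load a (muscle, epoch) x feature p-value table
#'
#' Reads one of the wide p-value matrices (e.g. the fixture tables shipped
#' in `inst/extdata`, transcribed digit-for-digit from the published
#' interaction and group-effect results) and validates it: columns `muscle`
#' and `epoch` plus the six feature columns, every value in `[0, 1]`, no
#' missing cells, complete 4-muscle x 5-epoch grid.
#'
#' @param path CSV path; see also [semgadapt_fixture()].
#' @return Tibble with columns `muscle`, `epoch`, `RMS`, `MDF`, `SAMPEN`,
#'   `CSD`, `RSD`, `LSD`.
#' @export
load_pvalue_fixture <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("muscle", "epoch", .features)
  if (!all(need %in% names(tab))) {
    .stop("validation", "P-value table %s must have columns %s.",
          path, paste(need, collapse = ", "))
  }
  vals <- as.matrix(tab[.features])
  if (anyNA(vals)) .stop("validation", "Missing p-value cell in %s.", path)
  if (any(vals < 0 | vals > 1)) {
    .stop("validation", "P-value outside [0, 1] in %s.", path)
  }
  if (nrow(distinct(tab, .data$muscle, .data$epoch)) != nrow(tab) ||
      nrow(tab) != 20) {
    .stop("validation", "%s must be a complete 20-row (muscle, epoch) grid.",
          path)
  }
  tab
}

#' Path to a shipped fixture file
#'
#' @param name fixture file name, e.g. `"table3_interaction.csv"` or
#'   `"table4_group.csv"`.
#' @return Absolute path to the installed fixture.
#' @export
semgadapt_fixture <- function(name) {
  p <- system.file("extdata", name, package = "semgadapt")
  if (p == "") .stop("parse", "No fixture named '%s'.", name)
  p
}
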