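# Plain-text serialization. Numeric values are written with 17 significant
# digits, which round-trips IEEE doubles bit-exactly through as.numeric().

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.bundle_schema <- "senphys-bundle-1"

#' Read a pupil marker CSV
#'
#' Expects one header row with a \code{frame} column and, for each of the
#' eight pupil markers (top, top_right, right, bottom_right, bottom,
#' bottom_left, left, top_left) and the static \code{ref} marker, columns
#' \code{<name>_x}, \code{<name>_y} and \code{<name>_likelihood}. An
#' optional \code{t_s} column carries frame timestamps; otherwise frames
#' are stamped at the nominal rate.
#'
#' @param path CSV file path.
#' @param fps nominal frame rate used when no \code{t_s} column is present.
#' @return a \code{\link{pupil_frames}} object; likelihoods are retained as
#'   optional weights.
#' @export
read_marker_csv <- function(path, fps = 20) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("read_marker_csv: no frames")
  all_names <- c(.marker_names, "ref")
  want <- c("frame", as.vector(t(outer(all_names, c("x", "y", "likelihood"),
                                       paste, sep = "_"))))
  missing <- setdiff(setdiff(want, "ref_likelihood"), names(df))
  if (length(missing))
    stop("read_marker_csv: missing columns: ", paste(missing, collapse = ", "))
  if (any(diff(df$frame) <= 0))
    stop("read_marker_csv: frame index must be strictly increasing")
  n <- nrow(df)
  markers <- array(NA_real_, c(n, 8L, 2L))
  lik <- matrix(NA_real_, n, 8L)
  for (k in seq_len(8L)) {
    nm <- .marker_names[k]
    markers[, k, 1] <- df[[paste0(nm, "_x")]]
    markers[, k, 2] <- df[[paste0(nm, "_y")]]
    lik[, k] <- df[[paste0(nm, "_likelihood")]]
  }
  ref <- cbind(df$ref_x, df$ref_y)
  t_s <- if ("t_s" %in% names(df)) df$t_s else (df$frame - df$frame[1]) / fps
  pupil_frames(t_s, markers, ref, likelihood = lik)
}

#' Write a pupil marker CSV
#'
#' Inverse of \code{\link{read_marker_csv}}; coordinates survive the
#' round trip bit-exactly.
#'
#' @param frames a \code{pupil_frames} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_marker_csv <- function(frames, path) {
  n <- length(frames$t_s)
  out <- data.frame(frame = seq_len(n) - 1L, t_s = .fmt_num(frames$t_s))
  for (k in seq_len(8L)) {
    nm <- .marker_names[k]
    out[[paste0(nm, "_x")]] <- .fmt_num(frames$markers[, k, 1])
    out[[paste0(nm, "_y")]] <- .fmt_num(frames$markers[, k, 2])
    lk <- if (is.null(frames$likelihood)) rep(1, n) else frames$likelihood[, k]
    out[[paste0(nm, "_likelihood")]] <- .fmt_num(lk)
  }
  out$ref_x <- .fmt_num(frames$ref_marker[, 1])
  out$ref_y <- .fmt_num(frames$ref_marker[, 2])
  out$ref_likelihood <- .fmt_num(rep(1, n))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundle the pieces of one recording session
#'
#' @param trials optional \code{trial_table}.
#' @param traces named list of \code{time_series}.
#' @param sweeps named list of \code{sweep_set}.
#' @param params list of free-form parameters (JSON-serializable).
#' @return list of class \code{session_bundle}.
#' @export
session_bundle <- function(trials = NULL, traces = list(), sweeps = list(),
                           params = list()) {
  structure(list(trials = trials, traces = traces, sweeps = sweeps,
                 params = params),
            class = "session_bundle")
}

#' Write a session bundle to disk
#'
#' Serializes a \code{\link{session_bundle}} as a directory of plain-text
#' members: a JSON manifest with a schema version, the trial table as CSV,
#' every trace and sweep matrix as full-precision CSV, and the parameter
#' list as JSON. \code{read_session(write_session(x))} reproduces every
#' field, floating-point values bit-exactly.
#'
#' @param bundle a \code{session_bundle}.
#' @param path directory to create (overwritten if it exists).
#' @return \code{path}, invisibly.
#' @export
write_session <- function(bundle, path) {
  stopifnot(inherits(bundle, "session_bundle"))
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)
  manifest <- list(schema_version = .bundle_schema,
                   has_trials = !is.null(bundle$trials),
                   traces = lapply(bundle$traces, function(ts)
                     list(rate_hz = ts$rate_hz, t0_s = ts$t0_s,
                          n = length(ts$values))),
                   sweeps = lapply(bundle$sweeps, function(sw)
                     list(rate_hz = sw$rate_hz, protocol = sw$protocol,
                          stim_times_s = I(.fmt_num(sw$stim_times_s)),
                          step_currents_pa =
                            if (is.null(sw$step_currents_pa)) NULL
                            else I(.fmt_num(sw$step_currents_pa)),
                          n_sweeps = nrow(sw$sweeps),
                          n_samples = ncol(sw$sweeps))))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  jsonlite::write_json(bundle$params, file.path(path, "params.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(bundle$trials)) {
    tr <- bundle$trials
    df <- data.frame(trial_index = tr$trial_index, texture = tr$texture,
                     t_cue_s = .fmt_num(tr$t_cue_s),
                     t_pt_start_s = .fmt_num(tr$t_pt_start_s),
                     t_pt_end_s = .fmt_num(tr$t_pt_end_s),
                     outcome = tr$outcome, rt_s = .fmt_num(tr$rt_s),
                     lick_times_s = vapply(tr$lick_times_s, function(v)
                       paste(.fmt_num(v), collapse = ";"), character(1)),
                     stringsAsFactors = FALSE)
    utils::write.csv(df, file.path(path, "trials.csv"),
                     row.names = FALSE, quote = TRUE)
  }
  if (length(bundle$traces)) {
    dir.create(file.path(path, "traces"))
    for (nm in names(bundle$traces))
      writeLines(.fmt_num(bundle$traces[[nm]]$values),
                 file.path(path, "traces", paste0(nm, ".csv")))
  }
  if (length(bundle$sweeps)) {
    dir.create(file.path(path, "sweeps"))
    for (nm in names(bundle$sweeps)) {
      m <- bundle$sweeps[[nm]]$sweeps
      lines <- apply(m, 1L, function(row) paste(.fmt_num(row), collapse = ","))
      writeLines(lines, file.path(path, "sweeps", paste0(nm, ".csv")))
    }
  }
  invisible(path)
}

#' Read a session bundle from disk
#'
#' @param path directory written by \code{\link{write_session}}.
#' @return a \code{\link{session_bundle}}.
#' @export
read_session <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("read_session: no manifest.json in ", path)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  if (!identical(manifest$schema_version, .bundle_schema))
    stop("read_session: unsupported schema version '",
         manifest$schema_version, "' (expected '", .bundle_schema, "')")
  params <- jsonlite::read_json(file.path(path, "params.json"),
                                simplifyVector = TRUE)
  trials <- NULL
  if (isTRUE(manifest$has_trials)) {
    df <- utils::read.csv(file.path(path, "trials.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(t_cue_s = "character",
                                         t_pt_start_s = "character",
                                         t_pt_end_s = "character",
                                         rt_s = "character",
                                         lick_times_s = "character"))
    licks <- lapply(strsplit(df$lick_times_s, ";", fixed = TRUE),
                    function(v) as.numeric(v[nzchar(v)]))
    trials <- trial_table(df$trial_index, df$texture,
                          as.numeric(df$t_cue_s),
                          as.numeric(df$t_pt_start_s),
                          as.numeric(df$t_pt_end_s),
                          lick_times_s = licks, outcome = df$outcome,
                          rt_s = suppressWarnings(as.numeric(df$rt_s)))
  }
  traces <- list()
  for (nm in names(manifest$traces)) {
    meta <- manifest$traces[[nm]]
    vals <- as.numeric(readLines(file.path(path, "traces", paste0(nm, ".csv"))))
    traces[[nm]] <- time_series(vals, meta$rate_hz, meta$t0_s)
  }
  sweeps <- list()
  for (nm in names(manifest$sweeps)) {
    meta <- manifest$sweeps[[nm]]
    lines <- readLines(file.path(path, "sweeps", paste0(nm, ".csv")))
    m <- do.call(rbind, lapply(strsplit(lines, ",", fixed = TRUE), as.numeric))
    sweeps[[nm]] <- sweep_set(m,
                              stim_times_s = as.numeric(unlist(meta$stim_times_s)),
                              protocol = meta$protocol, rate_hz = meta$rate_hz,
                              step_currents_pa =
                                if (is.null(meta$step_currents_pa)) NULL
                                else as.numeric(unlist(meta$step_currents_pa)))
  }
  session_bundle(trials = trials, traces = traces, sweeps = sweeps,
                 params = params)
}
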