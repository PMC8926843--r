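# Small FNV-1a hash for run manifests (no external digest dependency).
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)  # xor touches the low byte only
    # 32-bit multiply by the FNV prime 16777619 = 2^24 + 403, split so
    # every intermediate stays exactly representable in double precision
    h <- ((h * 403) %% 4294967296 + (h %% 256) * 16777216) %% 4294967296
  }
  # render as hex from the high nibble down (h is a double, not an int)
  digits <- integer(8)
  for (i in 8:1) { digits[i] <- h %% 16; h <- h %/% 16 }
  paste(substring("0123456789abcdef", digits + 1, digits + 1),
        collapse = "")
}

# CSV with provenance header lines ("# key: value"), readable back with
# comment.char = "#".
write_csv_header <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_header <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read trial tables
#'
#' Trial tables are plain CSV, one row per trial, with the fixed column
#' schema of [simulate_agent()] and optional provenance comment lines
#' (`# key: value`) at the top.
#'
#' @param trials Trial `data.frame`.
#' @param path File path.
#' @param meta Named list of provenance entries (e.g. seed, config hash).
#' @return `path` (write) or the trial `data.frame` (read).
#' @export
write_trials <- function(trials, path, meta = list()) {
  cols <- c("session_id", "subject_id", "trial_index", "design",
            "intervention", "dose_phase", "experiment", "reward_mag",
            "dot_speed_ms", "iti_s", "responded", "act_time_dots",
            "reward_outcome", "onset_s", "response_s", "outcome_s")
  missing_cols <- setdiff(cols, names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  write_csv_header(trials[, cols], path, meta)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- read_csv_header(path)
  tr$responded <- as.logical(tr$responded)
  tr
}

#' Write / read ROI channel tables
#'
#' ROI BOLD channels at the TR grid: columns `volume_index`, `time_s`,
#' then one column per channel.
#'
#' @param channels Channel `data.frame` from [simulate_bold()].
#' @param path File path.
#' @param meta Named provenance entries.
#' @return `path` (write) or the channel `data.frame` (read).
#' @export
write_roi_channels <- function(channels, path, meta = list()) {
  stopifnot(all(c("volume_index", "time_s") %in% names(channels)))
  write_csv_header(as.data.frame(channels), path, meta)
}

#' @rdname write_roi_channels
#' @export
read_roi_channels <- function(path) {
  read_csv_header(path)
}

#' Extract an ROI time series from a NIfTI volume and binary mask
#'
#' Averages, at each volume, the voxels of a 4-D NIfTI image lying inside
#' a binary mask (mask > 0). Requires the RNifti package.
#'
#' @param image_path Path to a 4-D NIfTI image.
#' @param mask_path Path to a 3-D binary mask in the same grid.
#' @return Numeric vector, one value per volume.
#' @export
extract_roi_nifti <- function(image_path, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI extraction")
  }
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  dimg <- dim(img)
  if (length(dimg) != 4) stop("image must be 4-D")
  if (!all(dim(msk)[1:3] == dimg[1:3])) stop("mask grid does not match image")
  sel <- which(as.array(msk) > 0)
  if (!length(sel)) stop("mask selects no voxels")
  arr <- array(img, dim = c(prod(dimg[1:3]), dimg[4]))
  colMeans(arr[sel, , drop = FALSE])
}
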