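## Minimal C3D motion-capture file I/O in base R.
##
## Supports the common modern subset: Intel (PC) processor type,
## floating-point 3D point data, POINT and EVENT parameter groups. This is
## sufficient to round-trip files written by write_trial_c3d() and to read
## typical Vicon-style exports carrying heel/toe/ankle markers and
## Foot Strike / Foot Off events.

#' Default marker label aliases
#'
#' Maps each canonical marker name to label spellings found in clinic
#' files (e.g. Plug-in-Gait style `LHEE`, `RTOE`). Extend or override via
#' the `aliases` argument of [read_c3d()].
#' @return named list of character vectors.
#' @export
default_marker_aliases <- function() {
  list(
    L_HEEL = c("L_HEEL", "LHEE", "LHEEL"),
    L_TOE = c("L_TOE", "LTOE"),
    L_ANKLE = c("L_ANKLE", "LANK", "LANKLE"),
    R_HEEL = c("R_HEEL", "RHEE", "RHEEL"),
    R_TOE = c("R_TOE", "RTOE"),
    R_ANKLE = c("R_ANKLE", "RANK", "RANKLE")
  )
}

#' Write a trial to a C3D file
#'
#' Emits an Intel-format floating-point C3D with the six marker
#' trajectories (mm), the sampling rate and the trial's events encoded in
#' the standard EVENT group (`Foot Strike` / `Foot Off` with `Left` /
#' `Right` contexts, times in seconds).
#'
#' @param trial a `gait_trial` (validated, finite coordinates).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_c3d <- function(trial, path) {
  validate_trial(trial)
  T_ <- n_frames(trial)
  n_pts <- length(MARKER_NAMES)
  ev <- trial$events
  n_ev <- nrow(ev)

  param <- c3d_param_section(trial, n_ev)
  n_param_blocks <- length(param) / 512L
  data_start <- 2L + n_param_blocks

  con <- file(path, "wb")
  on.exit(close(con))
  # --- header block (512 bytes)
  writeBin(as.raw(c(2L, 0x50)), con)
  wi2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wf4 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi2(n_pts)           # points per frame
  wi2(0L)              # analog samples per frame
  wi2(1L)              # first frame
  wi2(T_)              # last frame
  wi2(0L)              # max interpolation gap
  wf4(-1)              # scale; negative = floating point data
  wi2(data_start)      # data start block
  wi2(0L)              # analog frames per video frame
  wf4(trial$fs)        # frame rate
  writeBin(raw(512L - 24L), con)
  # --- parameter section
  writeBin(param, con)
  # --- point data: per frame, per point: x, y, z, residual
  dat <- array(0, dim = c(4L, n_pts, T_))
  for (k in seq_len(n_pts)) {
    dat[1:3, k, ] <- t(trial$markers[[MARKER_NAMES[k]]])
  }
  writeBin(as.numeric(dat), con, size = 4L, endian = "little")
  n_written <- 4L * n_pts * T_ * 4L
  pad <- (512L - n_written %% 512L) %% 512L
  if (pad > 0L) writeBin(raw(pad), con)
  invisible(path)
}

## Build the raw parameter section (padded to whole 512-byte blocks).
c3d_param_section <- function(trial, n_ev) {
  ev <- trial$events
  entries <- list(
    c3d_group(1L, "POINT", "3D point data"),
    c3d_param(1L, "USED", 2L, length(MARKER_NAMES)),
    c3d_param(1L, "FRAMES", 2L, n_frames(trial)),
    c3d_param(1L, "SCALE", 4L, -1),
    c3d_param(1L, "RATE", 4L, trial$fs),
    c3d_param(1L, "UNITS", -1L, "mm"),
    c3d_param(1L, "LABELS", -1L, MARKER_NAMES),
    c3d_group(2L, "EVENT", "gait events"),
    c3d_param(2L, "USED", 2L, n_ev)
  )
  if (n_ev > 0L) {
    etype_label <- ifelse(ev$etype == "IC", "Foot Strike", "Foot Off")
    context <- ifelse(ev$side == "L", "Left", "Right")
    times <- rbind(0, ev$frame / trial$fs)  # row 1: minutes, row 2: seconds
    entries <- c(entries, list(
      c3d_param(2L, "LABELS", -1L, etype_label),
      c3d_param(2L, "CONTEXTS", -1L, context),
      c3d_param(2L, "TIMES", 4L, times, dims = dim(times))
    ))
  }
  body <- c3d_link_entries(entries)
  head <- as.raw(c(0x01, 0x50, 0x00, 84L))  # 84 = Intel processor type
  out <- c(head, body)
  n_blocks <- ceiling(length(out) / 512)
  out <- c(out, raw(n_blocks * 512L - length(out)))
  out[3L] <- as.raw(n_blocks)
  out
}

c3d_group <- function(id, name, desc = "") {
  list(kind = "group", id = id, name = name, desc = desc)
}

c3d_param <- function(group_id, name, type, value, dims = NULL) {
  list(kind = "param", id = group_id, name = name, type = type,
       value = value, dims = dims, desc = "")
}

## Serialize entries, fixing up the 2-byte offsets that chain them.
c3d_link_entries <- function(entries) {
  pieces <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    last <- i == length(entries)
    nm <- charToRaw(e$name)
    if (e$kind == "group") {
      desc <- charToRaw(e$desc)
      tail_ <- c(as.raw(length(desc)), desc)
      id <- -e$id
    } else {
      tail_ <- c3d_param_payload(e)
      id <- e$id
    }
    offset <- if (last) 0L else length(tail_)
    c(writeBin(c(length(nm), id), raw(), size = 1L),
      nm,
      writeBin(as.integer(offset), raw(), size = 2L, endian = "little"),
      tail_)
  })
  do.call(c, pieces)
}

c3d_param_payload <- function(e) {
  type <- e$type
  if (type == -1L) {                      # character data
    vals <- as.character(e$value)
    if (length(vals) == 1L && is.null(e$dims)) {
      dims <- length(charToRaw(vals))
      data <- charToRaw(vals)
      nd <- 1L
    } else {
      width <- max(nchar(vals))
      padded <- formatC(vals, width = width, flag = "-")
      data <- do.call(c, lapply(padded, charToRaw))
      dims <- c(width, length(vals))
      nd <- 2L
    }
    dim_bytes <- writeBin(as.integer(dims), raw(), size = 1L)
  } else {
    dims <- if (is.null(e$dims)) {
      if (length(e$value) == 1L) integer(0) else length(e$value)
    } else e$dims
    nd <- length(dims)
    dim_bytes <- if (nd) writeBin(as.integer(dims), raw(), size = 1L) else raw(0)
    data <- if (type == 2L) {
      writeBin(as.integer(e$value), raw(), size = 2L, endian = "little")
    } else {
      writeBin(as.numeric(e$value), raw(), size = 4L, endian = "little")
    }
  }
  c(writeBin(as.integer(type), raw(), size = 1L),
    as.raw(nd), dim_bytes, data, as.raw(0L))   # trailing 0: no description
}

#' Read a trial from a C3D file
#'
#' Parses the header and parameter section (Intel processor type,
#' floating-point or integer point data), extracts the six required
#' markers via the alias table, converts units to mm, and maps EVENT
#' group annotations (`Foot Strike`/`Foot Off`, `Left`/`Right`) to TRUTH
#' gait events with 0-based frames at the file's sampling rate.
#'
#' @param path C3D file path.
#' @param aliases marker alias table, see [default_marker_aliases()].
#' @param subject_id,trial_id,pathology metadata for the returned trial;
#'   `trial_id` defaults to the file name.
#' @return a `gait_trial`.
#' @export
read_c3d <- function(path, aliases = default_marker_aliases(),
                     subject_id = "subject", trial_id = NULL,
                     pathology = "HC") {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 1024L) stop_fmt("not a C3D file (too short): %s", path)
  ri2 <- function(at) readBin(raw_all[at:(at + 1L)], "integer", size = 2L, endian = "little")
  rf4 <- function(at) readBin(raw_all[at:(at + 3L)], "numeric", size = 4L, endian = "little")
  param_block <- as.integer(raw_all[1L])
  if (as.integer(raw_all[2L]) != 0x50) stop_fmt("not a C3D file: %s", path)
  n_pts <- ri2(3L)
  first_frame <- ri2(7L)
  last_frame <- ri2(9L)
  scale <- rf4(13L)
  data_start <- ri2(17L)
  fs <- rf4(21L)
  T_ <- last_frame - first_frame + 1L

  poff <- (param_block - 1L) * 512L
  proc <- as.integer(raw_all[poff + 4L])
  if (proc != 84L) stop_fmt("unsupported C3D processor type %d (only Intel/PC supported)", proc)
  groups <- c3d_parse_params(raw_all, poff + 5L)

  point <- groups[["POINT"]]
  labels <- toupper(trimws(point[["LABELS"]]))
  unit <- if (!is.null(point[["UNITS"]])) tolower(trimws(point[["UNITS"]])[1L]) else "mm"
  unit_scale <- switch(unit, mm = 1, cm = 10, m = 1000, 1)
  if (!is.null(point[["DATA_START"]])) data_start <- point[["DATA_START"]]
  if (!is.null(point[["SCALE"]])) scale <- point[["SCALE"]]

  doff <- (data_start - 1L) * 512L
  n_vals <- 4L * n_pts * T_
  if (scale < 0) {
    vals <- readBin(raw_all[(doff + 1L):length(raw_all)], "numeric",
                    n = n_vals, size = 4L, endian = "little")
  } else {
    ints <- readBin(raw_all[(doff + 1L):length(raw_all)], "integer",
                    n = n_vals, size = 2L, endian = "little")
    vals <- as.numeric(ints)
    idx <- rep(rep(c(TRUE, TRUE, TRUE, FALSE), n_pts), T_)
    vals[idx] <- vals[idx] * scale
  }
  arr <- array(vals, dim = c(4L, n_pts, T_))

  markers <- list()
  for (nm in MARKER_NAMES) {
    hit <- which(labels %in% toupper(aliases[[nm]]))
    if (length(hit) == 0L) stop_fmt("missing marker %s", nm)
    markers[[nm]] <- t(arr[1:3, hit[1L], , drop = TRUE]) * unit_scale
  }

  evg <- groups[["EVENT"]]
  events <- gait_events()
  if (!is.null(evg) && !is.null(evg[["USED"]]) && evg[["USED"]] > 0L) {
    n_ev <- evg[["USED"]]
    lab <- trimws(evg[["LABELS"]])[seq_len(n_ev)]
    ctx <- trimws(evg[["CONTEXTS"]])[seq_len(n_ev)]
    tm <- matrix(evg[["TIMES"]], nrow = 2L)[, seq_len(n_ev), drop = FALSE]
    secs <- 60 * tm[1L, ] + tm[2L, ]
    keep <- lab %in% c("Foot Strike", "Foot Off") & ctx %in% c("Left", "Right")
    if (any(keep)) {
      events <- gait_events(
        etype = ifelse(lab[keep] == "Foot Strike", "IC", "FO"),
        side = ifelse(ctx[keep] == "Left", "L", "R"),
        frame = round(secs[keep] * fs) - (first_frame - 1L),
        source = "TRUTH"
      )
    }
  }
  if (is.null(trial_id)) trial_id <- sub("\\.c3d$", "", basename(path), ignore.case = TRUE)
  gait_trial(markers, fs = fs, events = events, trial_id = trial_id,
             subject_id = subject_id, pathology = pathology)
}

## Parse the chained group/parameter entries into groups[[name]][[param]].
c3d_parse_params <- function(raw_all, pos) {
  group_names <- character(0)
  out <- list()
  repeat {
    if (pos + 1L > length(raw_all)) break
    n_name <- readBin(raw_all[pos], "integer", size = 1L)
    id <- readBin(raw_all[pos + 1L], "integer", size = 1L)
    n_name_abs <- abs(n_name)
    if (n_name_abs == 0L) break
    name <- rawToChar(raw_all[(pos + 2L):(pos + 1L + n_name_abs)])
    p <- pos + 2L + n_name_abs
    offset <- readBin(raw_all[p:(p + 1L)], "integer", size = 2L, endian = "little")
    next_pos <- p + 2L + offset
    body <- p + 2L
    if (id < 0L) {
      group_names[as.character(-id)] <- toupper(name)
      if (is.null(out[[toupper(name)]])) out[[toupper(name)]] <- list()
    } else {
      type <- readBin(raw_all[body], "integer", size = 1L)
      nd <- as.integer(raw_all[body + 1L])
      dims <- if (nd > 0L) as.integer(raw_all[(body + 2L):(body + 1L + nd)]) else integer(0)
      dpos <- body + 2L + nd
      n_el <- if (nd > 0L) prod(dims) else 1L
      value <- if (type == -1L) {
        chars <- rawToChar(raw_all[dpos:(dpos + max(n_el, 0L) - 1L)], multiple = FALSE)
        if (nd >= 2L) {
          width <- dims[1L]
          substring(chars, seq(1L, n_el, by = width), seq(width, n_el, by = width))
        } else chars
      } else if (type == 1L) {
        as.integer(raw_all[dpos:(dpos + n_el - 1L)])
      } else if (type == 2L) {
        readBin(raw_all[dpos:(dpos + 2L * n_el - 1L)], "integer", n = n_el,
                size = 2L, endian = "little")
      } else {
        readBin(raw_all[dpos:(dpos + 4L * n_el - 1L)], "numeric", n = n_el,
                size = 4L, endian = "little")
      }
      gname <- group_names[as.character(id)]
      if (!is.na(gname)) out[[gname]][[toupper(name)]] <- value
    }
    if (offset == 0L) break
    pos <- next_pos
  }
  out
}
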