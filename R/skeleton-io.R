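#' Construct a posture sequence
#'
#' A posture sequence is an ordered set of skeleton frames: each frame is one
#' feature vector of 3-D keypoint coordinates, `D = 3 * n_joints` (19 joints,
#' so `D = 57`, for the default skeleton). Frames are in temporal order at a
#' fixed frame rate.
#'
#' @param frames Numeric `T x D` matrix, one row per frame, `D` divisible by 3.
#' @param fps Frames per second (default 15).
#' @param joint_names Optional character vector of joint labels, length `D/3`.
#' @param segment_labels Optional per-frame ground-truth posture labels
#'   (length `T`), used by the synthetic generator and boundary-tolerance
#'   checks.
#' @return An object of class `posture_sequence`.
#' @export
posture_sequence <- function(frames, fps = 15, joint_names = NULL,
                             segment_labels = NULL) {
  frames <- as.matrix(frames)
  if (nrow(frames) > 0 && (!is.numeric(frames) || anyNA(frames) ||
                           !all(is.finite(frames)))) {
    stop("frames must be finite numeric values (no NA: missing joints are ",
         "rejected, not imputed)", call. = FALSE)
  }
  if (ncol(frames) %% 3 != 0) {
    stop("frame dimension must be divisible by 3 (x,y,z per joint)",
         call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0) {
    stop("fps must be a positive number", call. = FALSE)
  }
  nj <- ncol(frames) %/% 3
  if (is.null(joint_names)) joint_names <- sprintf("j%02d", seq_len(nj) - 1L)
  if (length(joint_names) != nj) {
    stop("joint_names must have length ", nj, call. = FALSE)
  }
  if (!is.null(segment_labels) && length(segment_labels) != nrow(frames)) {
    stop("segment_labels must have one entry per frame", call. = FALSE)
  }
  structure(
    list(frames = frames, fps = fps, joint_names = joint_names,
         segment_labels = segment_labels),
    class = "posture_sequence"
  )
}

#' @export
print.posture_sequence <- function(x, ...) {
  cat("Posture sequence: ", nrow(x$frames), " frames x ",
      length(x$joint_names), " joints (D = ", ncol(x$frames), "), ",
      x$fps, " fps", sep = "")
  if (!is.null(x$segment_labels)) {
    cat(", ", length(unique(x$segment_labels)), " labelled segments", sep = "")
  }
  cat("\n")
  invisible(x)
}

.seq_colnames <- function(joint_names) {
  c("frame", paste0(rep(joint_names, each = 3), "_", c("x", "y", "z")))
}

#' Read a skeleton sequence from disk
#'
#' Two plain-text dialects are supported. `csv_wide`: a header
#' `frame,j00_x,j00_y,j00_z,...` and one row per frame. `jsonl`: one JSON
#' object per line, `{"frame": i, "joints": [[x,y,z], ...]}`. The joint count
#' is inferred from the file; malformed rows are reported with their line
#' number. Rows containing non-numeric or missing coordinates are rejected
#' (occluded joints are not imputed).
#'
#' @param path File path.
#' @param format `"csv_wide"` or `"jsonl"`.
#' @param fps Frame rate to attach (the files do not store it; default 15).
#' @return A [posture_sequence()].
#' @seealso [write_sequence()]
#' @export
read_sequence <- function(path, format = c("csv_wide", "jsonl"), fps = 15) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv_wide") .read_csv_wide(path, fps) else .read_jsonl(path, fps)
}

.read_csv_wide <- function(path, fps) {
  nf <- count.fields(path, sep = ",", quote = "")
  if (length(nf) == 0) stop("empty file: ", path, call. = FALSE)
  expected <- nf[1]
  if ((expected - 1) %% 3 != 0 || expected < 4) {
    stop("parse error at line 1: header must be 'frame' plus 3 columns per ",
         "joint, got ", expected, " fields", call. = FALSE)
  }
  bad <- which(nf != expected)
  if (length(bad) > 0) {
    stop("parse error at line ", bad[1], ": expected ", expected,
         " fields, got ", nf[bad[1]], call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (header[1] != "frame") {
    stop("parse error at line 1: first column must be 'frame'", call. = FALSE)
  }
  df <- read.csv(path, header = TRUE, colClasses = "character",
                 check.names = FALSE)
  nj <- (expected - 1) %/% 3
  joint_names <- unique(sub("_[xyz]$", "", header[-1]))
  if (length(joint_names) != nj) joint_names <- NULL
  if (nrow(df) == 0) {
    return(posture_sequence(matrix(numeric(0), 0, expected - 1), fps = fps,
                            joint_names = joint_names))
  }
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df))
  if (anyNA(vals)) {
    bad_row <- which(apply(vals, 1, anyNA))[1]
    stop("parse error at line ", bad_row + 1,
         ": non-numeric or missing coordinate", call. = FALSE)
  }
  posture_sequence(vals, fps = fps, joint_names = joint_names)
}

.read_jsonl <- function(path, fps) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(posture_sequence(matrix(numeric(0), 0, 0), fps = fps))
  }
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(obj) || is.null(obj$joints)) {
      stop("parse error at line ", i, ": invalid frame object", call. = FALSE)
    }
    j <- as.matrix(obj$joints)
    if (ncol(j) != 3 || anyNA(j) || !is.numeric(j)) {
      stop("parse error at line ", i, ": joints must be an array of [x,y,z]",
           call. = FALSE)
    }
    rows[[i]] <- as.numeric(t(j))
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) {
    stop("parse error at line ", which(lens != lens[1])[1],
         ": inconsistent joint count", call. = FALSE)
  }
  posture_sequence(do.call(rbind, rows), fps = fps)
}

#' Write a skeleton sequence to disk
#'
#' Writes the `csv_wide` or `jsonl` dialect of [read_sequence()] with full
#' double precision (`%.17g`), so `read_sequence(write_sequence(x))`
#' round-trips bit-for-bit.
#'
#' @param seq A [posture_sequence()].
#' @param path Output file path.
#' @param format `"csv_wide"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, format = c("csv_wide", "jsonl")) {
  format <- match.arg(format)
  stopifnot(inherits(seq, "posture_sequence"))
  X <- seq$frames
  if (format == "csv_wide") {
    header <- paste(.seq_colnames(seq$joint_names), collapse = ",")
    if (nrow(X) == 0) {
      writeLines(header, path)
      return(invisible(path))
    }
    body <- vapply(seq_len(nrow(X)), function(i) {
      paste(c(as.character(i), sprintf("%.17g", X[i, ])), collapse = ",")
    }, character(1))
    writeLines(c(header, body), path)
  } else {
    lines <- vapply(seq_len(nrow(X)), function(i) {
      joints <- matrix(X[i, ], ncol = 3, byrow = TRUE)
      sprintf('{"frame": %d, "joints": [%s]}', i,
              paste(apply(joints, 1, function(p) {
                sprintf("[%s]", paste(sprintf("%.17g", p), collapse = ", "))
              }), collapse = ", "))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Flatten a posture sequence into a data matrix
#'
#' `mode = "none"` (the default) leaves coordinates untouched, so every
#' downstream score acts on the raw skeleton exactly as recorded.
#' `mode = "center_root"` subtracts the root joint's `(x, y, z)` from every
#' joint of each frame, making the representation invariant to where the
#' subject stands in the room.
#'
#' @param seq A [posture_sequence()].
#' @param mode `"none"` or `"center_root"`.
#' @param root_joint 1-based joint index used as the root (default 1).
#' @return A numeric `T x D` matrix.
#' @export
preprocess <- function(seq, mode = c("none", "center_root"), root_joint = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(seq, "posture_sequence"))
  X <- seq$frames
  if (mode == "none") return(X)
  nj <- ncol(X) %/% 3
  if (root_joint < 1 || root_joint > nj) {
    stop("root_joint must be in 1..", nj, call. = FALSE)
  }
  idx <- (root_joint - 1) * 3 + 1:3
  root <- X[, idx, drop = FALSE]
  X - root[, rep(1:3, nj), drop = FALSE]
}
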