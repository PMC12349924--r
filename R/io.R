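#' Write a system or trajectory as extended XYZ
#'
#' One frame per block: a bead-count line, a comment line carrying
#' `step=`, `time=` and `box="Lx Ly Lz"`, then one `kind x y z mol` line
#' per bead. Coordinates are stored with 6 decimals (sigma); analysis
#' runs on full precision in memory.
#'
#' @param x a [particle_system()] or trajectory.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(pos, kinds, mol, box, step, time) {
    writeLines(as.character(nrow(pos)), con)
    writeLines(sprintf('step=%d time=%.6f box="%.6f %.6f %.6f"',
                       step, time, box[1], box[2], box[3]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f %d", kinds,
                       pos[, 1], pos[, 2], pos[, 3], mol), con)
  }
  if (inherits(x, "particle_system")) {
    emit(x$positions, x$kinds, x$molecule_id, x$box, 0L, 0)
  } else if (inherits(x, "trajectory")) {
    for (i in seq_len(n_frames(x)))
      emit(frame_positions(x, i), x$kinds, x$molecule_id,
           x$frame_box[i, ], x$frame_step[i], x$frame_time[i])
  } else stop("write_xyz: expected a particle_system or trajectory")
  invisible(path)
}

#' Read an extended-XYZ file
#'
#' @param path input file written by [write_xyz()] (or compatible).
#' @return a list of frames, each
#'   `list(positions, kinds, molecule_id, box, step, time)`. Malformed
#'   input raises an error naming the offending line or frame.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  ln <- 1L
  frame_no <- 0L
  while (ln <= length(lines)) {
    if (trimws(lines[ln]) == "") { ln <- ln + 1L; next }
    frame_no <- frame_no + 1L
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 0)
      stop(sprintf("read_xyz: invalid bead count at line %d (frame %d)", ln, frame_no))
    if (ln + 1L + n > length(lines))
      stop(sprintf("read_xyz: truncated frame %d starting at line %d", frame_no, ln))
    comment <- lines[ln + 1L]
    grab <- function(key, quoted = FALSE) {
      pat <- if (quoted) sprintf('%s="([^"]*)"', key) else sprintf("%s=([^ ]+)", key)
      m <- regmatches(comment, regexec(pat, comment))[[1]]
      if (length(m) < 2) stop(sprintf("read_xyz: frame %d comment lacks %s=", frame_no, key))
      m[2]
    }
    step <- as.integer(grab("step"))
    time <- as.numeric(grab("time"))
    box <- as.numeric(strsplit(grab("box", quoted = TRUE), " +")[[1]])
    if (length(box) != 3 || anyNA(box))
      stop(sprintf("read_xyz: frame %d has a malformed box", frame_no))
    body <- lines[ln + 1L + seq_len(n)]
    toks <- strsplit(trimws(body), " +")
    bad <- which(lengths(toks) != 5)
    if (length(bad))
      stop(sprintf("read_xyz: malformed bead line %d (frame %d)", ln + 1L + bad[1], frame_no))
    tk <- matrix(unlist(toks), ncol = 5, byrow = TRUE)
    pos <- matrix(as.numeric(tk[, 2:4]), ncol = 3)
    if (anyNA(pos))
      stop(sprintf("read_xyz: non-numeric coordinate in frame %d", frame_no))
    frames[[frame_no]] <- list(positions = pos, kinds = tk[, 1],
                               molecule_id = as.integer(tk[, 5]),
                               box = box, step = step, time = time)
    ln <- ln + 2L + n
  }
  frames
}
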