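#' Read an MSR-Action3D-style plain-text skeleton file
#'
#' Parses the whitespace-separated skeleton dialect used by the
#' MSR-Action3D family of corpora: a fixed number of numeric rows per
#' frame (default 40 = 20 joints x \{world, screen\} blocks), each row
#' `x y z [confidence]`.  Only one block per frame is kept (default the
#' first, i.e. world coordinates).  The dialect actually parsed is
#' recorded in the sequence metadata.  Rows are never silently dropped:
#' a file whose row count is not a multiple of `rows_per_frame` is a
#' parse error naming the first surplus row.
#'
#' @param path path to the `.txt` skeleton file.
#' @param topology a [skeleton_topology()]; its joint count must equal
#'   `rows_per_frame / blocks`.
#' @param rows_per_frame rows making up one frame (default 40).
#' @param block which within-frame block of `rows_per_frame / blocks`
#'   rows to keep: 1 = first (world), 2 = second (screen).
#' @param blocks number of stacked coordinate blocks per frame.
#' @return A [skeleton_sequence()]; the per-row 4th column, when present,
#'   is stored as joint confidence.
#' @export
read_msr_skeleton <- function(path, topology = default_topology(),
                              rows_per_frame = 40L, block = 1L,
                              blocks = 2L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("parse error: empty skeleton file ", path)
  joints_per_frame <- rows_per_frame %/% blocks
  if (joints_per_frame != n_joints(topology))
    stop("rows_per_frame/blocks = ", joints_per_frame,
         " joints per frame, but topology has ", n_joints(topology))
  if (length(lines) %% rows_per_frame != 0L) {
    bad <- (length(lines) %/% rows_per_frame) * rows_per_frame + 1L
    stop("parse error in ", path, ": ", length(lines),
         " rows is not a multiple of ", rows_per_frame,
         " rows/frame; incomplete frame starts at row ", bad)
  }
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  ncol <- lengths(toks)
  if (any(ncol < 3L | ncol > 4L))
    stop("parse error: row ", which(ncol < 3L | ncol > 4L)[1L],
         " does not have 3 or 4 fields")
  vals <- suppressWarnings(lapply(toks, as.numeric))
  badnum <- which(vapply(vals, anyNA, logical(1)))
  if (length(badnum))
    stop("parse error: non-numeric token on row ", badnum[1L])
  nf <- length(lines) %/% rows_per_frame
  frame_of <- rep(seq_len(nf), each = rows_per_frame)
  row_in_frame <- rep(seq_len(rows_per_frame), nf)
  keep_rows <- row_in_frame > (block - 1L) * joints_per_frame &
    row_in_frame <= block * joints_per_frame
  kept <- vals[keep_rows]
  coords <- array(NA_real_, c(nf, joints_per_frame, 3L))
  conf <- matrix(1, nf, joints_per_frame)
  has_conf <- all(lengths(kept) == 4L)
  kmat <- do.call(rbind, lapply(kept, function(v) v[1:4][1:4]))
  jf <- rep(seq_len(joints_per_frame), nf)
  ff <- rep(seq_len(nf), each = joints_per_frame)
  for (d in 1:3) coords[cbind(ff, jf, d)] <- kmat[, d]
  if (has_conf) conf[cbind(ff, jf)] <- kmat[, 4L]
  skeleton_sequence(
    coords, topology,
    confidence = if (has_conf) pmin(pmax(conf, 0), 1) else NULL,
    sequence_id = sub("\\.[^.]*$", "", basename(path)),
    meta = list(dialect = list(rows_per_frame = rows_per_frame,
                               blocks = blocks, block_kept = block,
                               has_confidence = has_conf)))
}

.canonical_header <- c("sequence_id", "frame", "joint", "x", "y", "z",
                       "confidence")

#' Read / write the canonical skeleton CSV
#'
#' The canonical interchange format is a long CSV with header
#' `sequence_id,frame,joint,x,y,z,confidence`; frame indices are 0-based
#' and contiguous, joints are identified by topology name, and rows are
#' written frame-major in topology joint order at full double precision,
#' so two writes of the same sequence are byte-identical and a
#' write/read round trip is lossless.
#'
#' @param path CSV file path.
#' @param topology a [skeleton_topology()] naming the expected joints.
#' @return `read_canonical()` returns a [skeleton_sequence()];
#'   `write_canonical()` returns `path` invisibly.
#' @export
read_canonical <- function(path, topology = default_topology()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sequence_id = "character",
                                       joint = "character"))
  if (!identical(names(df), .canonical_header))
    stop("canonical CSV must have header ",
         paste(.canonical_header, collapse = ","))
  if (nrow(df) == 0L)
    return(skeleton_sequence(array(0, c(0L, n_joints(topology), 3L)),
                             topology))
  unknown <- setdiff(unique(df$joint), topology$joint_names)
  if (length(unknown))
    stop("unknown joint name(s) in CSV: ", paste(unknown, collapse = ", "))
  frames <- sort(unique(df$frame))
  nf <- length(frames)
  if (!identical(as.integer(frames), seq_len(nf) - 1L))
    stop("frame indices must be contiguous and 0-based ",
         "(found ", frames[1L], "..", frames[nf], ")")
  n <- n_joints(topology)
  ji <- joint_index(topology, df$joint)
  cell <- df$frame * n + ji  # 1..nf*n when complete
  if (anyDuplicated(cell))
    stop("duplicate (frame, joint) rows in CSV")
  missing <- setdiff(seq_len(nf * n), cell)
  if (length(missing)) {
    mf <- (missing[1L] - 1L) %/% n
    mj <- topology$joint_names[(missing[1L] - 1L) %% n + 1L]
    stop("missing (frame, joint) cell: frame ", mf, ", joint ", mj,
         " (", length(missing), " cell(s) absent)")
  }
  coords <- array(NA_real_, c(nf, n, 3L))
  conf <- matrix(NA_real_, nf, n)
  fr <- df$frame + 1L
  coords[cbind(fr, ji, 1L)] <- df$x
  coords[cbind(fr, ji, 2L)] <- df$y
  coords[cbind(fr, ji, 3L)] <- df$z
  conf[cbind(fr, ji)] <- df$confidence
  skeleton_sequence(coords, topology, confidence = conf,
                    sequence_id = df$sequence_id[1L])
}

#' @rdname read_canonical
#' @param seq a [skeleton_sequence()] to write.
#' @export
write_canonical <- function(seq, path) {
  nf <- n_frames(seq)
  n <- n_joints(seq$topology)
  conf <- seq$confidence
  if (is.null(conf)) conf <- matrix(1, nf, n)
  sid <- if (is.na(seq$sequence_id)) "seq" else seq$sequence_id
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(.canonical_header, collapse = ","), con)
  if (nf == 0L) return(invisible(path))
  fr <- rep(seq_len(nf) - 1L, each = n)
  ji <- rep(seq_len(n), nf)
  num <- function(v) formatC(v, format = "g", digits = 17)
  rows <- paste(sid, fr, seq$topology$joint_names[ji],
                num(seq$coords[cbind(fr + 1L, ji, 1L)]),
                num(seq$coords[cbind(fr + 1L, ji, 2L)]),
                num(seq$coords[cbind(fr + 1L, ji, 3L)]),
                num(conf[cbind(fr + 1L, ji)]),
                sep = ",")
  writeLines(rows, con)
  invisible(path)
}

#' Read / write a topology definition file
#'
#' Topologies are stored in a DCF (Debian-control-style key:value) file
#' with fields `Joints`, `Parents` (comma-separated, parent named per
#' joint, root naming itself), `HipCenter`, `BoneLengths` (optional) and
#' `HipSegmentJoint`.
#'
#' @param path file path.
#' @return `read_topology()` returns a [skeleton_topology()].
#' @export
read_topology <- function(path) {
  f <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  splt <- function(x) trimws(strsplit(x, ",")[[1L]])
  joints <- splt(f$Joints)
  parents <- match(splt(f$Parents), joints)
  # the root's bone length is written as NA; coercion is intentional
  bl <- if (!is.null(f$BoneLengths))
    suppressWarnings(as.numeric(splt(f$BoneLengths))) else NULL
  if (!is.null(bl)) bl[match(f$HipCenter, joints)] <- NA_real_
  skeleton_topology(joints, parents, hip_center = f$HipCenter,
                    bone_lengths = bl,
                    hip_segment_joint = f$HipSegmentJoint)
}

#' @rdname read_topology
#' @param topology a [skeleton_topology()] to write.
#' @export
write_topology <- function(topology, path) {
  m <- cbind(
    Joints = paste(topology$joint_names, collapse = ","),
    Parents = paste(topology$joint_names[topology$parents], collapse = ","),
    HipCenter = topology$joint_names[topology$hip_center],
    HipSegmentJoint = topology$hip_segment_joint)
  if (!is.null(topology$bone_lengths))
    m <- cbind(m, BoneLengths = paste(
      formatC(topology$bone_lengths, format = "g", digits = 17),
      collapse = ","))
  write.dcf(m, path)
  invisible(path)
}
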