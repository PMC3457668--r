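#' Read a coordinate trajectory from disk
#'
#' Supports multi-model PDB (models delimited by `MODEL`/`ENDMDL`; a
#' missing final `ENDMDL` is tolerated) and multi-frame XYZ. PDB files
#' carry no frame times, so `frame_spacing_ps` is required for them; XYZ
#' comment lines of the form `t= <time> ps` (as written by
#' [write_trajectory()]) are parsed when present.
#'
#' @param path path to the trajectory file.
#' @param format one of `"pdb"`, `"xyz"` or `"auto"` (by file extension).
#' @param selection optional character vector of atom labels to keep (PDB
#'   atom names / XYZ element symbols); applied identically to every
#'   frame. A selection matching no atom is an error.
#' @param frame_spacing_ps optional uniform frame spacing in ps; required
#'   when the format carries no times.
#' @param unit length-unit tag to record (coordinates are not rescaled).
#' @return an [new_trajectory()] object.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz"),
                            selection = NULL, frame_spacing_ps = NULL,
                            unit = "A") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read trajectory file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", xyz = "xyz",
                     stop("cannot infer trajectory format from extension '",
                          ext, "'; pass format="))
  }
  traj <- switch(format,
                 pdb = read_trajectory_pdb(path, frame_spacing_ps, unit),
                 xyz = read_trajectory_xyz(path, frame_spacing_ps, unit))
  if (!is.null(selection)) {
    keep <- traj$atom_labels %in% selection
    if (!any(keep)) stop("selection matches no atoms")
    traj <- new_trajectory(traj$coords[, keep, , drop = FALSE],
                           times = traj$times,
                           atom_labels = traj$atom_labels[keep],
                           weights = traj$weights[keep], unit = traj$unit)
  }
  traj
}

## cheap structural pre-scan so that malformed multi-model files produce
## an error naming the offending frame, before bio3d parses the rest
scan_pdb_models <- function(lines) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(sum(is_atom))
  ends <- grep("^ENDMDL", lines)
  counts <- integer(length(starts))
  for (i in seq_along(starts)) {
    to <- c(ends[ends > starts[i]], length(lines) + 1L)[1L] - 1L
    counts[i] <- sum(is_atom[starts[i]:to])
  }
  counts
}

read_trajectory_pdb <- function(path, frame_spacing_ps, unit) {
  if (is.null(frame_spacing_ps))
    stop("PDB carries no frame times: frame_spacing_ps is required")
  lines <- readLines(path, warn = FALSE)
  counts <- scan_pdb_models(lines)
  if (length(counts) > 1L && length(unique(counts)) != 1L) {
    bad <- which(counts != counts[1L])[1L]
    stop("format error in frame ", bad, ": atom count ", counts[bad],
         " differs from frame 1 (", counts[1L], ")")
  }
  if (any(counts == 0L)) stop("PDB file contains a model with no atoms")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                       # models x (3 N), per-atom triplets
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  n <- nrow(xyz)
  na <- ncol(xyz) / 3L
  coords <- array(0, c(n, na, 3L))
  for (i in seq_len(n))
    coords[i, , ] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  new_trajectory(coords, frame_spacing_ps = frame_spacing_ps,
                 atom_labels = trimws(pdb$atom$elety), unit = unit)
}

read_trajectory_xyz <- function(path, frame_spacing_ps, unit) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  labels0 <- NULL
  times <- numeric(0)
  i <- 1L
  fr <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    fr <- fr + 1L
    if (is.na(na) || na < 1L)
      stop("format error in frame ", fr, ": bad atom count line '",
           lines[i], "'")
    if (i + 1L + na > length(lines))
      stop("format error in frame ", fr, ": truncated file")
    comment <- lines[i + 1L]
    m <- regmatches(comment,
                    regexec("t=\\s*([-+0-9.eE]+)", comment))[[1L]]
    times <- c(times, if (length(m) == 2L) as.numeric(m[2L]) else NA_real_)
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + na)]), "\\s+")
    if (any(lengths(rows) < 4L))
      stop("format error in frame ", fr, ": atom line with fewer than 4 fields")
    labels <- vapply(rows, `[`, "", 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3L)))
    if (any(!is.finite(xyz)))
      stop("format error in frame ", fr, ": non-numeric coordinate")
    if (is.null(labels0)) labels0 <- labels
    else if (length(labels) != length(labels0))
      stop("format error in frame ", fr, ": atom count ", length(labels),
           " differs from frame 1 (", length(labels0), ")")
    frames[[fr]] <- xyz
    i <- i + 2L + na
  }
  if (length(frames) == 0L) stop("no frames found in XYZ file")
  if (!is.null(frame_spacing_ps)) times <- NULL
  else if (anyNA(times))
    stop("XYZ comments carry no parseable times: frame_spacing_ps is required")
  new_trajectory(frames, times = times, frame_spacing_ps = frame_spacing_ps,
                 atom_labels = labels0, unit = unit)
}

#' Write a trajectory to disk
#'
#' XYZ output stores coordinates at 17 significant digits (bit-exact
#' round-trip through [read_trajectory()]) and records frame times in the
#' comment line. PDB output goes through [bio3d::write.pdb()] and is
#' limited to the fixed-width 3-decimal PDB coordinate precision.
#'
#' @param traj an [new_trajectory()] object.
#' @param path output path.
#' @param format `"xyz"`, `"pdb"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", xyz = "xyz",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  n <- n_frames(traj)
  na <- n_atoms(traj)
  if (format == "xyz") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(n)) {
      writeLines(c(as.character(na),
                   sprintf("t= %.17g ps", traj$times[i])), con)
      writeLines(sprintf("%s %.17g %.17g %.17g", traj$atom_labels,
                         traj$coords[i, , 1L], traj$coords[i, , 2L],
                         traj$coords[i, , 3L]), con)
    }
  } else {
    xyz <- matrix(aperm(traj$coords, c(3L, 2L, 1L)), nrow = n, byrow = TRUE)
    bio3d::write.pdb(file = path, xyz = xyz,
                     elety = traj$atom_labels,
                     resno = seq_len(na), resid = rep("ALA", na))
  }
  invisible(path)
}

#' Read a precomputed square RMSD matrix
#'
#' Accepts a whitespace- or comma-delimited square numeric matrix, e.g. as
#' exported by an external RMSD engine. Asymmetries up to `1e-6` relative
#' are symmetrized by averaging; larger ones, negative entries, a nonzero
#' diagonal (beyond `1e-9` of the matrix scale) or a non-square layout are
#' errors.
#'
#' @param path file path.
#' @param frame_spacing_ps positive frame spacing in ps used to synthesize
#'   frame times.
#' @param unit length-unit tag of the stored distances.
#' @return an [new_rmsd_matrix()] object.
#' @export
read_rmsd_matrix <- function(path, frame_spacing_ps, unit = "A") {
  if (!file.exists(path)) stop("cannot read matrix file: ", path)
  if (!is.numeric(frame_spacing_ps) || frame_spacing_ps <= 0)
    stop("frame_spacing_ps must be a positive scalar")
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  vals <- utils::read.table(path, sep = sep, header = FALSE,
                            strip.white = TRUE)
  vals <- as.matrix(vals)
  if (!is.numeric(vals)) stop("matrix file contains non-numeric entries")
  if (nrow(vals) != ncol(vals))
    stop("matrix is not square: ", nrow(vals), " x ", ncol(vals))
  if (any(vals < 0)) stop("matrix contains negative entries")
  scale <- max(vals, 1e-300)
  asym <- max(abs(vals - t(vals)))
  if (asym > 1e-6 * scale)
    stop("matrix is asymmetric beyond tolerance (max |M - t(M)| = ",
         format(asym), ")")
  vals <- (vals + t(vals)) / 2
  if (max(abs(diag(vals))) > 1e-9 * max(scale, 1))
    stop("matrix diagonal is not zero")
  diag(vals) <- 0
  dimnames(vals) <- NULL
  new_rmsd_matrix(vals, times = (seq_len(nrow(vals)) - 1) * frame_spacing_ps,
                  unit = unit)
}

#' Write keyed numeric records as TSV or JSON
#'
#' Columns are emitted in sorted key order and floating-point values at 17
#' significant digits, so that [read_table()] round-trips every finite
#' double bit-exactly.
#'
#' @param records a data frame, or a list of named lists sharing a key set.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(records)) {
    if (length(records) == 0L) records <- data.frame()
    else {
      keys <- sort(names(records[[1L]]))
      for (r in records)
        if (!setequal(names(r), keys))
          stop("records do not share a key set")
      records <- do.call(rbind, lapply(records, function(r)
        as.data.frame(r[keys], stringsAsFactors = FALSE)))
    }
  }
  if (ncol(records) > 0L)
    records <- records[, sort(names(records)), drop = FALSE]
  if (format == "tsv") {
    fmt_col <- function(x)
      if (is.double(x)) sprintf("%.17g", x) else as.character(x)
    body <- if (nrow(records) == 0L) character(0)
            else do.call(paste, c(lapply(records, fmt_col), sep = "\t"))
    writeLines(c(paste(names(records), collapse = "\t"), body), path)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows",
                         digits = I(17), na = "null")
  }
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path file path.
#' @param format `"tsv"`, `"json"` or `"auto"` (by extension).
#' @return a data frame.
#' @export
read_table <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json" else "tsv"
  }
  if (format == "tsv")
    utils::read.delim(path, check.names = FALSE)
  else
    as.data.frame(jsonlite::fromJSON(path))
}
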