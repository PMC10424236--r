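# Plain-text I/O: PDB/XYZ structures, multi-frame XYZ trajectories, window
# time-series files in the two-column layout consumed by standard WHAM
# tools, and TSV tables. All numeric payloads round-trip at full precision
# (9 significant digits in text).

fmt_num <- function(x) formatC(x, digits = 9, format = "g")

#' Write a system as a PDB file
#'
#' One bead per residue; chain A and B for the two molecules, chain I for
#' the ions. Coordinates are converted nm -> Angstrom with fixed 3-decimal
#' formatting (the PDB column convention).
#'
#' @param state A `system_state`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(state, path) {
  stopifnot(inherits(state, "system_state"))
  lines <- character(0)
  serial <- 0L
  emit <- function(pos, q, chain, resname, atname) {
    vapply(seq_len(nrow(pos)), function(i) {
      serial <<- serial + 1L
      sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
              serial, atname, resname, chain, i,
              pos[i, 1] * 10, pos[i, 2] * 10, pos[i, 3] * 10, 1, q[i])
    }, character(1))
  }
  lines <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
            state$box$edge * 10, state$box$edge * 10, state$box$edge * 10),
    emit(state$molecule_a$positions, state$molecule_a$charges, "A", "DNA", "CG"),
    emit(state$molecule_b$positions, state$molecule_b$charges, "B", "DNA", "CG"),
    if (length(state$ion_charges) > 0)
      emit(state$ion_positions, state$ion_charges, "I", "ION", "IO"),
    "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write coordinate frames as multi-frame XYZ
#'
#' Standard XYZ layout: atom count, then a comment line carrying the box
#' edge (`box <edge_nm>`), then one `SITE x y z` line per particle in nm at
#' 9 significant digits.
#'
#' @param frames A single coordinate matrix or a list of them.
#' @param path Output file path.
#' @param box Optional [simulation_box()] recorded on the comment line.
#' @param labels Optional per-particle labels (default `"A"`/`"B"`/`"I"`
#'   cannot be inferred here, so plain `"S"` is used).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, box = NULL, labels = NULL) {
  if (is.matrix(frames) || is.data.frame(frames)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    f <- as.matrix(f)
    lab <- if (is.null(labels)) rep("S", nrow(f)) else labels
    writeLines(as.character(nrow(f)), con)
    writeLines(if (is.null(box)) "frame" else
               sprintf("box %s", fmt_num(box$edge)), con)
    writeLines(paste(lab, fmt_num(f[, 1]), fmt_num(f[, 2]), fmt_num(f[, 3])),
               con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path Input file path.
#' @return A list with `frames` (list of coordinate matrices), `labels`
#'   (from the first frame) and `box_edge` (NA when absent).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); labels <- NULL; box_edge <- NA_real_
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(sprintf("%s: expected an atom count at line %d", path, i))
    n <- as.integer(lines[i])
    comment <- lines[i + 1]
    if (grepl("^box ", comment))
      box_edge <- as.numeric(sub("^box ", "", comment))
    if (i + 1 + n > length(lines))
      stop(sprintf("%s: truncated frame starting at line %d", path, i))
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "\\s+")
    if (any(lengths(parts) != 4))
      stop(sprintf("%s: malformed coordinate line in frame at line %d",
                   path, i))
    m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[2:4])))
    if (is.null(labels)) labels <- vapply(parts, `[`, "", 1)
    frames[[length(frames) + 1]] <- m
    i <- i + 2L + n
  }
  list(frames = frames, labels = labels, box_edge = box_edge)
}

#' Write a window time series
#'
#' Two whitespace-separated columns (sample index, reaction coordinate in
#' nm) preceded by a '#' header recording the window centre and force
#' constant — the layout consumed by standard WHAM command-line tools.
#'
#' @param record A [window_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_window_series <- function(record, path) {
  stopifnot(inherits(record, "window_record"))
  writeLines(c(
    sprintf("# center %s force_k %s", fmt_num(record$window$center),
            fmt_num(record$window$force_k)),
    paste(seq_along(record$rc_series), fmt_num(record$rc_series))), path)
  invisible(path)
}

#' Read a window time series
#'
#' @param path Input file path written by [write_window_series()].
#' @return A [window_record()].
#' @export
read_window_series <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^# *center ", lines[1]))
    stop(sprintf("%s: line 1: missing '# center <c> force_k <k>' header",
                 path))
  m <- regmatches(lines[1],
                  regexec("center\\s+(\\S+)\\s+force_k\\s+(\\S+)", lines[1]))[[1]]
  if (length(m) != 3)
    stop(sprintf("%s: line 1: malformed header", path))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0)
    stop(sprintf("%s: line %d: expected two columns", path, bad[1] + 1L))
  rc <- vapply(parts, function(p) as.numeric(p[2]), 0)
  window_record(umbrella_window(as.numeric(m[2]), as.numeric(m[3])), rc)
}

#' Read a set of window series via a metadata list file
#'
#' Each non-comment line of the list file names one series file and its
#' window: `filename center force_k` (whitespace separated, filename
#' relative to the list file). The in-file header must agree with the list
#' entry.
#'
#' @param list_path Path to the metadata list file.
#' @return List of [window_record()] objects.
#' @export
read_window_set <- function(list_path) {
  lines <- readLines(list_path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  base <- dirname(list_path)
  lapply(seq_along(lines), function(k) {
    p <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(p) != 3)
      stop(sprintf("%s: line %d: expected 'filename center force_k'",
                   list_path, k))
    rec <- read_window_series(file.path(base, p[1]))
    if (abs(rec$window$center - as.numeric(p[2])) > 1e-9 ||
        abs(rec$window$force_k - as.numeric(p[3])) > 1e-9)
      stop(sprintf("%s: line %d: window metadata disagrees with file header",
                   list_path, k))
    rec
  })
}

#' Write an effective potential as TSV
#'
#' Columns `r_nm`, `v_eff_kJ_mol`, `stderr` (NA where unavailable).
#'
#' @param profile A `pmf_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pmf_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "pmf_profile"))
  df <- data.frame(r_nm = profile$bin_centers,
                   v_eff_kJ_mol = profile$v_eff,
                   stderr = if (is.null(profile$stderr)) NA_real_
                            else profile$stderr)
  utils::write.table(format(df, digits = 9, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an effective potential TSV
#'
#' @param path File written by [write_pmf_tsv()].
#' @param reference_r Reference separation recorded in the profile.
#' @return A `pmf_profile`.
#' @export
read_pmf_tsv <- function(path, reference_r = 7.0) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", ""))
  need <- c("r_nm", "v_eff_kJ_mol")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: missing required columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  structure(list(bin_centers = df$r_nm, v_eff = df$v_eff_kJ_mol,
                 stderr = if ("stderr" %in% names(df)) df$stderr else NULL,
                 reference_r = reference_r),
            class = "pmf_profile")
}
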