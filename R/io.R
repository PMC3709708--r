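# File formats. All in-memory coordinates are nm; the PDB boundary is the
# only Angstrom <-> nm conversion site (PDB files carry Angstroms).

BACKBONE_NAMES <- c("N", "H", "CA", "C", "O")

#' Read a structure file into a topology and a one-frame trajectory
#'
#' Parses a PDB file (via bio3d), extracts the backbone topology with
#' 1-based residue numbering and returns the first model as a single-frame
#' trajectory in nm. Missing amide hydrogens are reconstructed geometrically
#' (0.1 nm from N, anti to the carbonyl O of the preceding residue, in the
#' peptide plane). Non-backbone atoms are not part of the coordinate frame;
#' they are returned, flagged, in `other_atoms`.
#'
#' @param path Path to a PDB file.
#' @param protonation Protonation label recorded on the topology.
#' @return A list with `topology` (a [peptide_topology()]), `frame` (a
#'   one-frame [trajectory()]) and `other_atoms` (tibble of retained
#'   non-backbone records).
#' @export
read_structure <- function(path, protonation = "physiological") {
  if (!file.exists(path)) abort(paste("file not found:", path))
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (nrow(at) == 0) abort("no ATOM records: zero residues parsed")
  resnos <- unique(at$resno)
  seq1 <- vapply(resnos, function(r) {
    r3 <- at$resid[at$resno == r][1]
    if (!r3 %in% names(AA3)) abort(paste("unknown residue", r3))
    AA3[[r3]]
  }, character(1))
  topo <- peptide_topology(paste(seq1, collapse = ""), protonation = protonation)
  coords <- matrix(NA_real_, nrow(topo$atoms), 3)
  missing <- character(0)
  for (k in seq_len(nrow(topo$atoms))) {
    r <- topo$atoms$resno[k]
    nm <- topo$atoms$name[k]
    hit <- which(at$resno == resnos[r] & at$elety == nm)
    if (length(hit) >= 1) {
      coords[k, ] <- as.numeric(at[hit[1], c("x", "y", "z")]) / 10  # A -> nm
    } else if (nm != "H") {
      missing <- c(missing, sprintf("residue %d atom %s", r, nm))
    }
  }
  if (length(missing)) {
    abort(paste("missing backbone atom(s):", paste(missing, collapse = "; ")))
  }
  # reconstruct absent amide hydrogens from the preceding peptide plane
  for (r in 2:n_residues(topo)) {
    hI <- atom_index(topo, r, "H")
    if (is.na(hI) || !anyNA(coords[hI, ])) next
    coords[hI, ] <- reconstruct_amide_h(
      coords[atom_index(topo, r - 1, "O"), ],
      coords[atom_index(topo, r - 1, "C"), ],
      coords[atom_index(topo, r, "N"), ])
  }
  other <- at[!(at$elety %in% BACKBONE_NAMES), , drop = FALSE]
  other_atoms <- tibble(resno = match(other$resno, resnos),
                        name = other$elety,
                        x = other$x / 10, y = other$y / 10, z = other$z / 10,
                        flagged = TRUE)
  list(topology = topo,
       frame = trajectory(topo, coords, source_label = basename(path)),
       other_atoms = other_atoms)
}

#' Read a coordinate trajectory
#'
#' Two dialects: multi-model PDB (`"pdb"`; frames ordered by MODEL number,
#' coordinates converted to nm) and the package's plain-text frame-array
#' format (`"frame_array"`; see [write_trajectory()]). The dialect is
#' guessed from the file content when `"auto"`.
#'
#' @param path Path to the trajectory file.
#' @param topology The [peptide_topology()] the frames must match.
#' @param dialect `"auto"`, `"pdb"` or `"frame_array"`.
#' @param times Optional frame times (ns); defaults to file metadata
#'   (frame-array) or uniform 0.05 ns spacing.
#' @return A [trajectory()] object.
#' @export
read_trajectory <- function(path, topology, dialect = c("auto", "pdb", "frame_array"),
                            times = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste("file not found:", path))
  first <- readLines(path, n = 1)
  if (length(first) == 0) abort(paste("empty trajectory file:", path))
  if (dialect == "auto") {
    dialect <- if (grepl("frame-array", first, fixed = TRUE)) "frame_array" else "pdb"
  }
  if (dialect == "frame_array") {
    read_frame_array(path, topology, times)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, 1)
    natoms_file <- ncol(xyz) / 3
    sel <- which(pdb$atom$elety %in% BACKBONE_NAMES & pdb$atom$type == "ATOM")
    order_key <- order(match(paste(pdb$atom$resno[sel], pdb$atom$elety[sel]),
                             paste(topology$atoms$resno, topology$atoms$name)))
    sel <- sel[order_key]
    if (length(sel) != nrow(topology$atoms)) {
      abort(sprintf("atom-count mismatch: file has %d matching backbone atoms, topology needs %d (frame 1)",
                    length(sel), nrow(topology$atoms)))
    }
    nf <- nrow(xyz)
    coords <- array(0, c(nf, nrow(topology$atoms), 3))
    for (f in seq_len(nf)) {
      m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      coords[f, , ] <- m[sel, ] / 10
    }
    trajectory(topology, coords, times = times, source_label = basename(path))
  }
}

read_frame_array <- function(path, topology, times = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (!length(hdr) || !grepl("frame-array", hdr[1])) {
    abort(paste("not a frame-array file:", path))
  }
  getval <- function(key) {
    h <- hdr[grepl(paste0("^# ", key, " "), hdr)]
    if (!length(h)) return(NULL)
    strsplit(sub(paste0("^# ", key, " "), "", h[1]), " ")[[1]]
  }
  natoms <- as.integer(getval("natoms")[1])
  nframes <- as.integer(getval("nframes")[1])
  tmeta <- getval("times")
  if (is.null(times) && !is.null(tmeta)) times <- as.numeric(tmeta)
  if (natoms != nrow(topology$atoms)) {
    abort(sprintf("atom-count mismatch: file has %d atoms, topology needs %d",
                  natoms, nrow(topology$atoms)))
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) != nframes) {
    abort(sprintf("frame-count mismatch: header says %d frames, body has %d",
                  nframes, length(body)))
  }
  coords <- array(0, c(nframes, natoms, 3))
  for (f in seq_len(nframes)) {
    v <- as.numeric(strsplit(body[f], " +")[[1]])
    if (length(v) != 3 * natoms) {
      abort(sprintf("frame %d has %d values, expected %d", f, length(v), 3 * natoms))
    }
    coords[f, , ] <- matrix(v, ncol = 3, byrow = TRUE)
  }
  trajectory(topology, coords, times = times, source_label = basename(path))
}

#' Write a trajectory to disk
#'
#' The `"pdb"` dialect emits standard multi-model ATOM records in Angstroms
#' (one MODEL/ENDMDL block per frame, via bio3d); coordinates round-trip to
#' PDB precision (1e-3 nm). The `"frame_array"` dialect is a plain-text
#' format (header lines `# turnpath-frame-array v1`, `# natoms`,
#' `# nframes`, `# times`, then one whitespace-separated row of
#' `3 * natoms` nm coordinates per frame, full double precision) that
#' round-trips bit-exactly.
#'
#' @param trj A [trajectory()] object.
#' @param path Output path.
#' @param dialect `"pdb"` or `"frame_array"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trj, path, dialect = c("frame_array", "pdb")) {
  dialect <- match.arg(dialect)
  nf <- n_frames(trj)
  natoms <- nrow(trj$topology$atoms)
  if (dialect == "frame_array") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# turnpath-frame-array v1",
                 paste("# natoms", natoms),
                 paste("# nframes", nf),
                 paste("# times", paste(sprintf("%.17g", trj$times), collapse = " "))),
               con)
    for (f in seq_len(nf)) {
      writeLines(paste(sprintf("%.17g", t(trj$coords[f, , ])), collapse = " "), con)
    }
  } else {
    xyz <- matrix(0, nf, 3 * natoms)
    for (f in seq_len(nf)) xyz[f, ] <- as.vector(t(trj$coords[f, , ])) * 10
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = trj$topology$atoms$resno,
                     resid = trj$topology$atoms$resid,
                     eleno = trj$topology$atoms$atom,
                     elety = trj$topology$atoms$name,
                     chain = rep("A", natoms))
  }
  invisible(path)
}

STRIDE_MAP <- c(H = "H", G = "H", I = "H", E = "E", B = "E", b = "E",
                T = "T", C = "C")
DSSP_MAP <- c(H = "H", G = "H", I = "H", E = "E", B = "E", T = "T",
              S = "C", P = "C", "." = "C", " " = "C", "-" = "C", C = "C")

#' Read a per-residue secondary-structure assignment
#'
#' Three dialects: the package's csv-track format (columns
#' `frame,residue,code`, multi-frame), STRIDE detailed output (`ASG` lines,
#' one snapshot) and DSSP output (one snapshot). Codes are mapped onto
#' \{H, E, T, C\}; DSSP bend codes (S) map to C and are counted in the
#' `bend_count` attribute. Unknown codes raise an error naming the symbol.
#'
#' @param path Path to the assignment file.
#' @param dialect `"csv"`, `"stride"` or `"dssp"`.
#' @return An `ss_assignment` character matrix (frames x residues) with
#'   attribute `bend_count`.
#' @export
read_ss_assignment <- function(path, dialect = c("csv", "stride", "dssp")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste("file not found:", path))
  bend <- 0L
  if (dialect == "csv") {
    df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("frame", "residue", "code")
    if (!all(need %in% names(df))) abort("csv-track needs columns frame,residue,code")
    bad <- setdiff(unique(df$code), c("H", "E", "T", "C"))
    if (length(bad)) abort(paste("unknown code(s):", paste(bad, collapse = ", ")))
    frames <- sort(unique(df$frame))
    res <- sort(unique(df$residue))
    if (nrow(df) != length(frames) * length(res)) {
      abort("csv-track rows do not map 1:1 to (frame, residue)")
    }
    m <- matrix("C", length(frames), length(res))
    m[cbind(match(df$frame, frames), match(df$residue, res))] <- df$code
  } else if (dialect == "stride") {
    lines <- grep("^ASG ", readLines(path), value = TRUE)
    if (!length(lines)) abort("no ASG records in STRIDE output")
    fields <- strsplit(trimws(lines), " +")
    code <- vapply(fields, `[[`, "", 6)
    bad <- setdiff(unique(code), names(STRIDE_MAP))
    if (length(bad)) abort(paste("unknown STRIDE code(s):", paste(bad, collapse = ", ")))
    m <- matrix(unname(STRIDE_MAP[code]), 1)
  } else {
    lines <- readLines(path)
    start <- grep("^  #  RESIDUE", lines)
    if (!length(start)) abort("no residue table in DSSP output")
    rows <- lines[(start[1] + 1):length(lines)]
    rows <- rows[nchar(rows) >= 17 & !grepl("^\\s*$", rows)]
    rows <- rows[substr(rows, 14, 14) != "!"]   # chain breaks
    code <- substr(rows, 17, 17)
    bad <- setdiff(unique(code), names(DSSP_MAP))
    if (length(bad)) abort(paste("unknown DSSP code(s):", paste(bad, collapse = ", ")))
    bend <- sum(code == "S")
    m <- matrix(unname(DSSP_MAP[code]), 1)
  }
  structure(m, bend_count = bend, class = c("ss_assignment", "matrix", "array"))
}

#' Write a secondary-structure assignment as a csv-track
#'
#' @param ss An `ss_assignment` matrix.
#' @param path Output path.
#' @return `path`, invisibly. [read_ss_assignment()] of the result is the
#'   identity.
#' @export
write_ss_assignment <- function(ss, path) {
  df <- data.frame(frame = rep(seq_len(nrow(ss)), times = ncol(ss)),
                   residue = rep(seq_len(ncol(ss)), each = nrow(ss)),
                   code = as.vector(unclass(ss)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read boolean annotation tracks (csv-track format)
#'
#' Long-format CSV with columns `frame,track,value`; `read_tracks()` of a
#' written file reproduces the wide tibble exactly.
#'
#' @param tracks A tibble with `frame` plus logical track columns.
#' @param path File path.
#' @return `write_tracks()` returns `path` invisibly; `read_tracks()`
#'   returns the wide tibble.
#' @export
write_tracks <- function(tracks, path) {
  labs <- setdiff(names(tracks), "frame")
  df <- data.frame(frame = rep(tracks$frame, times = length(labs)),
                   track = rep(labs, each = nrow(tracks)),
                   value = unlist(lapply(labs, function(l) tracks[[l]]),
                                  use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- tibble(frame = sort(unique(df$frame)))
  for (l in unique(df$track)) {
    sub <- df[df$track == l, ]
    out[[l]] <- as.logical(sub$value[match(out$frame, sub$frame)])
  }
  out
}
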