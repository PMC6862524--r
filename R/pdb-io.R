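# Multi-model PDB trajectory input/output.
#
# One MODEL per frame; CRYST1 carries the box; frame time stamps are stored
# in "REMARK 250 FRAME <i> TIME_NS <t>" header records so that they round-trip
# exactly (printed with full double precision). Coordinates convert between
# the package's nm convention and the PDB Angstrom convention and therefore
# round-trip to 1e-3 Angstrom, the format's fixed-point resolution.

.AA1 <- stats::setNames(names(.AA3), unname(.AA3))  # three- to one-letter

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a \code{trajectory}.
#' @param path output file path.
#' @param deterministic if TRUE (default) no timestamp or other
#'   run-dependent header is written, so identical trajectories produce
#'   byte-identical files.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path, deterministic = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  atoms <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  out <- character(0)
  out <- c(out, "REMARK 250 MULTI-MODEL PEPTIDE TRAJECTORY")
  if (!deterministic) {
    out <- c(out, paste("REMARK 250 WRITTEN", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  }
  out <- c(out, sprintf("REMARK 250 FRAME %d TIME_NS %.17g",
                        seq_len(nf), traj$times))
  out <- c(out, sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    traj$box[1] * 10, traj$box[2] * 10, traj$box[3] * 10, 90, 90, 90))
  element <- substr(atoms$name, 1, 1)
  name_field <- ifelse(nchar(atoms$name) < 4L,
                       sprintf(" %-3s", atoms$name), atoms$name)
  res3 <- .AA3[atoms$resname]
  writeLines(out, con)
  serial <- seq_len(nrow(atoms))
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f] * 10
    lines <- sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial %% 100000L, name_field, res3, atoms$chain, atoms$residue,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, element)
    writeLines(c(sprintf("MODEL %8d", f), lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Accepts files written by \code{\link{write_trajectory}} and generic
#' multi-model PDB files (one MODEL per frame, chains distinguished by the
#' chain identifier column). Frame times are taken from
#' \code{REMARK 250 FRAME ... TIME_NS ...} records when present, else set to
#' 0, 1, 2, ... ns. The box is read from CRYST1 (15 nm cubic fallback).
#'
#' @param path PDB file path.
#' @return a \code{trajectory}.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty trajectory file: ", path)
  rec <- substr(lines, 1, 6)

  box <- c(15, 15, 15)
  cryst <- which(rec == "CRYST1")
  if (length(cryst) > 0L) {
    l <- lines[cryst[1]]
    box <- as.numeric(c(substr(l, 7, 15), substr(l, 16, 24),
                        substr(l, 25, 33))) / 10
  }

  tm <- regmatches(lines, regexec(
    "^REMARK 250 FRAME ([0-9]+) TIME_NS ([-0-9.eE+]+)", lines))
  tm <- tm[lengths(tm) == 3L]
  times_map <- NULL
  if (length(tm) > 0L) {
    times_map <- stats::setNames(
      vapply(tm, function(x) as.numeric(x[3]), 0),
      vapply(tm, function(x) x[2], ""))
  }

  model_open <- which(rec == "MODEL ")
  model_close <- which(rec == "ENDMDL")
  atom_rows <- which(rec == "ATOM  " | rec == "HETATM")
  if (length(atom_rows) == 0L) stop("no ATOM records in ", path)
  if (length(model_open) == 0L) {
    # single implicit model
    model_open <- 0L; model_close <- length(lines) + 1L
  }
  if (length(model_open) != length(model_close) ||
      any(model_close < model_open)) {
    stop("malformed MODEL/ENDMDL nesting in ", path)
  }
  if (length(model_open) > 1L &&
      any(model_open[-1] < model_close[-length(model_close)])) {
    stop("malformed MODEL/ENDMDL nesting in ", path)
  }

  nf <- length(model_open)
  parse_atoms <- function(rows) {
    l <- lines[rows]
    data.frame(
      name = trimws(substr(l, 13, 16)),
      resname3 = trimws(substr(l, 18, 20)),
      chain = substr(l, 22, 22),
      residue = as.integer(substr(l, 23, 26)),
      x = as.numeric(substr(l, 31, 38)),
      y = as.numeric(substr(l, 39, 46)),
      z = as.numeric(substr(l, 47, 54)),
      stringsAsFactors = FALSE
    )
  }

  per_model <- lapply(seq_len(nf), function(f) {
    rows <- atom_rows[atom_rows > model_open[f] & atom_rows < model_close[f]]
    rows
  })
  counts <- lengths(per_model)
  if (any(counts == 0L)) stop("model without ATOM records (model ",
                              which(counts == 0L)[1], ")")
  if (length(unique(counts)) != 1L) {
    stop("inconsistent atom counts between models: ",
         paste(unique(counts), collapse = ", "))
  }

  first <- parse_atoms(per_model[[1]])
  unknown <- setdiff(unique(first$resname3), names(.AA1))
  if (length(unknown) > 0L) {
    stop("non-standard residue name(s): ", paste(unknown, collapse = ", "))
  }
  first$resname <- .AA1[first$resname3]

  # sequence from the first chain
  ch1 <- first[first$chain == first$chain[1], ]
  seq_codes <- ch1$resname[!duplicated(ch1$residue)]
  pseq <- parse_sequence(paste(seq_codes, collapse = ""))

  nat <- nrow(first)
  coords <- array(NA_real_, c(nat, 3L, nf))
  coords[, , 1] <- as.matrix(first[, c("x", "y", "z")]) / 10
  if (nf > 1L) {
    for (f in 2:nf) {
      a <- parse_atoms(per_model[[f]])
      if (!identical(a$name, first$name) ||
          !identical(a$chain, first$chain) ||
          !identical(a$residue, first$residue)) {
        stop("atom table differs between models (model ", f, ")")
      }
      coords[, , f] <- as.matrix(a[, c("x", "y", "z")]) / 10
    }
  }

  atoms <- data.frame(
    chain = first$chain, residue = first$residue, resname = first$resname,
    name = first$name,
    mass = ifelse(first$name == "CB",
                  .SIDECHAIN_MASS[first$resname],
                  .BACKBONE_MASS[first$name]),
    stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL

  times <- if (!is.null(times_map)) {
    tt <- times_map[as.character(seq_len(nf))]
    if (anyNA(tt)) seq_len(nf) - 1 else unname(tt)
  } else {
    seq_len(nf) - 1
  }
  trajectory(coords, atoms, times, box, pseq)
}

#' Write a ground-truth event ledger as TSV
#' @param traj a generated \code{trajectory} (with a \code{ledger} attribute)
#'   or a ledger data.frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_ledger <- function(traj, path) {
  ledger <- if (inherits(traj, "trajectory")) attr(traj, "ledger") else traj
  if (is.null(ledger)) stop("no ground-truth ledger available")
  utils::write.table(ledger, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
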