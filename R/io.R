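#' Guess species from residue names
#'
#' Water residues (SOL, WAT, HOH, TIP3, SPC) map to "water"; common
#' cosolvent residue names (TFE, URE, URA, UREA, CSL) map to "cosolvent";
#' everything else is assumed protein. Override with `species_map`.
#'
#' @param residue_name character vector of residue names.
#' @param species_map optional named character vector residue -> species.
#' @return Character vector of species labels.
#' @export
species_from_residue <- function(residue_name, species_map = NULL) {
  water <- c("SOL", "WAT", "HOH", "TIP3", "SPC", "T3P")
  cosol <- c("TFE", "URE", "URA", "UREA", "CSL")
  out <- ifelse(toupper(residue_name) %in% water, "water",
                ifelse(toupper(residue_name) %in% cosol, "cosolvent", "protein"))
  if (!is.null(species_map)) {
    hit <- match(residue_name, names(species_map))
    out[!is.na(hit)] <- unname(species_map[hit[!is.na(hit)]])
  }
  out
}

#' Read a single structure file
#'
#' Reads a PDB (via bio3d, coordinates converted from Angstrom to nm, box
#' taken from the CRYST1 record) or a GRO file (native nm, box on the last
#' line) into a topology + frame pair.
#'
#' @param path file path.
#' @param format "pdb" or "gro"; default guessed from the extension.
#' @param box optional length-3 box edge lengths (nm) if the file lacks one.
#' @param species_map optional residue -> species map
#'   (see [species_from_residue()]).
#' @return List with `topology` and `frame` (list of `box`, `coords`).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           box = NULL, species_map = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") .read_pdb_structure(path, box, species_map)
  else .read_gro_structure(path, box, species_map)
}

.read_pdb_structure <- function(path, box = NULL, species_map = NULL,
                                multi = FALSE) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = multi, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse PDB file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  topology <- kb_topology(data.frame(
    atom_id = seq_len(nrow(at)),
    name = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(at$elety, 1, 1), at$elesy),
    residue_name = at$resid,
    residue_index = at$resno,
    chain_id = ifelse(is.na(at$chain), "A", at$chain),
    species = species_from_residue(at$resid, species_map),
    stringsAsFactors = FALSE))
  if (is.null(box)) {
    cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
    if (length(cl)) {
      abc <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                          substr(cl[1], 25, 33)))
      ang <- as.numeric(c(substr(cl[1], 34, 40), substr(cl[1], 41, 47),
                          substr(cl[1], 48, 54)))
      if (any(abs(ang - 90) > 1e-3))
        stop("triclinic boxes are not supported (CRYST1 angles != 90)")
      box <- nm_from_angstrom(abc)
    } else {
      stop("no CRYST1 box in ", path, "; supply box= explicitly")
    }
  }
  xyz <- pdb$xyz
  n_fr <- if (is.matrix(xyz)) nrow(xyz) else 1L
  coords <- array(NA_real_, dim = c(nrow(at), 3L, n_fr))
  for (i in seq_len(n_fr)) {
    row <- if (is.matrix(xyz)) xyz[i, ] else as.numeric(xyz)
    coords[, , i] <- nm_from_angstrom(matrix(row, ncol = 3L, byrow = TRUE))
  }
  list(topology = topology,
       frame = list(box = box, coords = matrix(coords[, , 1], ncol = 3L)),
       coords = coords, box = box)
}

.read_gro_structure <- function(path, box = NULL, species_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("malformed GRO file ", path, ": too few lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 1L)
    stop("malformed GRO file ", path, ": bad atom count on line 2")
  if (length(lines) < 2L + n + 1L)
    stop("malformed GRO file ", path, ": expected ", n, " atom lines")
  al <- lines[3:(2 + n)]
  num <- function(s, from, to) suppressWarnings(as.numeric(substr(s, from, to)))
  resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resnm <- trimws(substr(al, 6, 10))
  atnm <- trimws(substr(al, 11, 15))
  x <- num(al, 21, 28); y <- num(al, 29, 36); z <- num(al, 37, 44)
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed GRO record in ", path, " at line ", 2L + bad[1])
  if (is.null(box)) {
    bx <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]),
                                               "\\s+")[[1]]))
    if (length(bx) < 3L || any(is.na(bx[1:3])))
      stop("missing or malformed box line in ", path,
           "; supply box= explicitly")
    if (length(bx) > 3L && any(abs(bx[4:length(bx)]) > 1e-9))
      stop("triclinic boxes are not supported")
    box <- bx[1:3]
  }
  topology <- kb_topology(data.frame(
    atom_id = seq_len(n), name = atnm,
    residue_name = resnm, residue_index = resid,
    species = species_from_residue(resnm, species_map),
    stringsAsFactors = FALSE))
  list(topology = topology,
       frame = list(box = box, coords = cbind(x, y, z, deparse.level = 0)))
}

#' Write a single-frame GRO file
#'
#' @param topology topology data frame.
#' @param frame frame list (`box`, `coords` in nm).
#' @param path output path.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(topology, frame, path, title = "kbsolv") {
  topology <- kb_topology(topology)
  n <- nrow(topology)
  stopifnot(nrow(frame$coords) == n)
  lines <- c(title, sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     topology$residue_index %% 100000L,
                     substr(topology$residue_name, 1, 5),
                     substr(topology$name, 1, 5),
                     topology$atom_id %% 100000L,
                     frame$coords[, 1], frame$coords[, 2], frame$coords[, 3]),
             sprintf("%10.5f%10.5f%10.5f",
                     frame$box[1], frame$box[2], frame$box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a multi-frame trajectory
#'
#' Supported formats: a multi-model PDB (`MODEL`/`ENDMDL`), a sequence of
#' GRO files (one frame each), or the package's plain-text columnar format
#' (see [write_columnar_trajectory()]).
#'
#' @param paths file path (single file formats) or character vector of GRO
#'   paths for `gro_sequence`.
#' @param format one of "multi_model_pdb", "gro_sequence", "columnar".
#' @param box optional box override (length 3, nm).
#' @param species_map optional residue -> species map.
#' @return A [kb_trajectory()].
#' @export
read_trajectory <- function(paths,
                            format = c("multi_model_pdb", "gro_sequence",
                                       "columnar"),
                            box = NULL, species_map = NULL) {
  format <- match.arg(format)
  switch(format,
    multi_model_pdb = {
      s <- .read_pdb_structure(paths[1], box, species_map, multi = TRUE)
      kb_trajectory(s$topology, s$coords, s$box)
    },
    gro_sequence = {
      if (!length(paths)) stop("no GRO files given")
      frames <- lapply(paths, .read_gro_structure, box = box,
                       species_map = species_map)
      n0 <- nrow(frames[[1]]$topology)
      for (i in seq_along(frames))
        if (nrow(frames[[i]]$topology) != n0)
          stop(sprintf("atom-count mismatch at frame %d: %d atoms, expected %d",
                       i, nrow(frames[[i]]$topology), n0))
      coords <- array(NA_real_, dim = c(n0, 3L, length(frames)))
      bx <- matrix(NA_real_, length(frames), 3L)
      for (i in seq_along(frames)) {
        coords[, , i] <- frames[[i]]$frame$coords
        bx[i, ] <- frames[[i]]$frame$box
      }
      kb_trajectory(frames[[1]]$topology, coords, bx)
    },
    columnar = read_columnar_trajectory(paths[1])
  )
}

#' Write / read the internal columnar trajectory format
#'
#' A diffable plain-text format: a header (`#kbtraj 1`, `natoms N`, an
#' `atoms` table with one row per atom: id, name, element, residue name,
#' residue index, chain, molecule id, species, role, charge, lj sigma,
#' lj epsilon), then per frame a `frame k` line, a `box bx by bz` line
#' (nm) and N lines `id x y z` (nm).
#'
#' @param traj a [kb_trajectory()].
#' @param path file path.
#' @return `write_columnar_trajectory()` returns `path` invisibly;
#'   `read_columnar_trajectory()` returns a `kb_trajectory`.
#' @export
write_columnar_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "kb_trajectory"))
  top <- traj$topology
  n <- nrow(top)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("#kbtraj 1", paste("natoms", n), "atoms"), con)
  writeLines(sprintf("%d %s %s %s %d %s %d %s %s %.10g %.10g %.10g",
                     top$atom_id, top$name, top$element, top$residue_name,
                     top$residue_index, top$chain_id, top$molecule_id,
                     top$species, top$role, top$charge, top$lj_sigma,
                     top$lj_epsilon), con)
  for (i in seq_len(n_frames(traj))) {
    writeLines(paste("frame", i), con)
    writeLines(sprintf("box %.10g %.10g %.10g", traj$box[i, 1],
                       traj$box[i, 2], traj$box[i, 3]), con)
    fr <- traj$coords[, , i]
    writeLines(sprintf("%d %.10g %.10g %.10g", top$atom_id,
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_columnar_trajectory
#' @export
read_columnar_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "#kbtraj"))
    stop("not a columnar trajectory (missing #kbtraj header): ", path)
  n <- as.integer(strsplit(lines[2], "\\s+")[[1]][2])
  if (is.na(n) || n < 1L) stop("malformed natoms line in ", path)
  if (!identical(lines[3], "atoms")) stop("malformed header in ", path)
  atom_lines <- lines[4:(3 + n)]
  fields <- strsplit(atom_lines, "\\s+")
  if (any(lengths(fields) != 12L))
    stop("malformed atom record at line ",
         3L + which(lengths(fields) != 12L)[1], " in ", path)
  m <- do.call(rbind, fields)
  topology <- kb_topology(data.frame(
    atom_id = as.integer(m[, 1]), name = m[, 2], element = m[, 3],
    residue_name = m[, 4], residue_index = as.integer(m[, 5]),
    chain_id = m[, 6], molecule_id = as.integer(m[, 7]),
    species = m[, 8], role = m[, 9],
    charge = as.numeric(m[, 10]), lj_sigma = as.numeric(m[, 11]),
    lj_epsilon = as.numeric(m[, 12]), stringsAsFactors = FALSE))
  pos <- 4L + n
  frames <- list(); boxes <- list(); k <- 0L
  while (pos <= length(lines)) {
    if (!grepl("^frame", lines[pos])) break
    k <- k + 1L
    bx <- as.numeric(strsplit(lines[pos + 1L], "\\s+")[[1]][2:4])
    if (any(is.na(bx))) stop("malformed box line for frame ", k, " in ", path)
    block <- lines[(pos + 2L):(pos + 1L + n)]
    vals <- matrix(as.numeric(unlist(strsplit(block, "\\s+"))),
                   ncol = 4L, byrow = TRUE)
    if (nrow(vals) != n || any(is.na(vals)))
      stop("atom-count mismatch or malformed coordinates at frame ", k,
           " in ", path)
    frames[[k]] <- vals[, 2:4]
    boxes[[k]] <- bx
    pos <- pos + 2L + n
  }
  if (!k) stop("no frames found in ", path)
  coords <- array(NA_real_, dim = c(n, 3L, k))
  for (i in seq_len(k)) coords[, , i] <- frames[[i]]
  kb_trajectory(topology, coords, do.call(rbind, boxes))
}

#' Read a flat interaction-parameter table
#'
#' Whitespace-separated columns `residue atom charge sigma_nm epsilon_kcal`
#' (header line required). Charges in e, LJ sigma in nm, epsilon in
#' kcal/mol.
#'
#' @param path file path.
#' @return Data frame with those five columns.
#' @export
read_parameter_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("residue", "atom", "charge", "sigma_nm", "epsilon_kcal")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("parameter table missing columns: ", paste(miss, collapse = ", "))
  tab
}

#' Attach charges and LJ parameters to a topology
#'
#' Looks up each atom by (residue_name, name) in a parameter table.
#'
#' @param topology topology data frame.
#' @param table parameter table (see [read_parameter_table()]).
#' @param strict error on atoms with no table entry (default TRUE); with
#'   FALSE, unmatched atoms keep their current parameters.
#' @return Topology with `charge`, `lj_sigma`, `lj_epsilon` filled.
#' @export
apply_parameters <- function(topology, table, strict = TRUE) {
  topology <- kb_topology(topology)
  key <- paste(topology$residue_name, topology$name)
  tkey <- paste(table$residue, table$atom)
  hit <- match(key, tkey)
  if (strict && anyNA(hit))
    stop("no parameters for atoms: ",
         paste(unique(key[is.na(hit)]), collapse = ", "))
  ok <- !is.na(hit)
  topology$charge[ok] <- table$charge[hit[ok]]
  topology$lj_sigma[ok] <- table$sigma_nm[hit[ok]]
  topology$lj_epsilon[ok] <- table$epsilon_kcal[hit[ok]]
  topology
}
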