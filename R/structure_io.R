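#' Reference structure container
#'
#' A `nap_reference` holds the fixed reference positions \eqn{R_i} against
#' which all displacements are measured, together with per-atom metadata.
#' The reference is typically the ligand-free (apo) native structure; a
#' time-averaged structure can be supplied instead via [as_reference()].
#'
#' @param xyz numeric N x 3 matrix of coordinates in Angstrom.
#' @param element character vector of chemical element symbols.
#' @param atom_name per-atom names (e.g. "CA"); defaults to element symbols.
#' @param resid integer residue ids as in the source file.
#' @param resname residue names; default "UNK".
#' @param chain chain ids; default "A".
#' @param source character tag recorded in output metadata ("crystal" or
#'   "averaged"); default "crystal".
#'
#' @return An object of class `nap_reference`: a list with components
#'   `xyz`, `element`, `atom_name`, `resid`, `resname`, `chain`, `heavy`
#'   (logical mask, element not hydrogen/deuterium) and `natoms`.
#' @export
as_reference <- function(xyz, element, atom_name = element,
                         resid = rep(1L, nrow(xyz)),
                         resname = rep("UNK", nrow(xyz)),
                         chain = rep("A", nrow(xyz)),
                         source = "crystal") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must be an N x 3 matrix")
  n <- nrow(xyz)
  if (n < 1L) stop("reference must contain at least one atom")
  if (!all(is.finite(xyz))) stop("reference coordinates must be finite")
  stopifnot(length(element) == n, length(atom_name) == n,
            length(resid) == n, length(resname) == n, length(chain) == n)
  element <- toupper(trimws(as.character(element)))
  ref <- list(
    xyz = unname(xyz),
    element = element,
    atom_name = as.character(atom_name),
    resid = as.integer(resid),
    resname = as.character(resname),
    chain = as.character(chain),
    heavy = !(element %in% c("H", "D")),
    natoms = n,
    source = source
  )
  class(ref) <- "nap_reference"
  ref
}

#' @export
print.nap_reference <- function(x, ...) {
  cat("nap_reference:", x$natoms, "atoms (", sum(x$heavy), "heavy ),",
      length(unique(paste(x$chain, x$resid))), "residues,",
      length(unique(x$chain)), "chain(s); source:", x$source, "\n")
  invisible(x)
}

# Element from an atom name when the element column is blank. PDB names put
# remoteness digits first for hydrogens ("1HB2"); otherwise the leading
# letters carry the element, with 2-letter elements occupying column 13.
.guess_element <- function(name) {
  name <- trimws(name)
  out <- character(length(name))
  for (k in seq_along(name)) {
    nm <- name[k]
    if (grepl("^[0-9]", nm)) nm <- sub("^[0-9]+", "", nm)
    out[k] <- if (grepl("^H", nm)) "H" else substr(nm, 1L, 1L)
  }
  toupper(out)
}

.read_pdb_checked <- function(path, multi = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- try(bio3d::read.pdb(path, multi = multi, verbose = FALSE),
             silent = TRUE)
  if (inherits(pdb, "try-error")) {
    stop("not a parseable PDB file: ", path)
  }
  pdb
}

#' Read a reference structure from a PDB file
#'
#' @param path path to a PDB file.
#' @param model 1-based model number for multi-model files.
#' @param source metadata tag, see [as_reference()].
#' @return A [as_reference()] object. Coordinates are in Angstrom as stored.
#' @export
read_reference <- function(path, model = 1L, source = "crystal") {
  pdb <- .read_pdb_checked(path, multi = TRUE)
  nmod <- nrow(pdb$xyz)
  if (model < 1L || model > nmod) {
    stop("model ", model, " not present (file has ", nmod, " model(s))")
  }
  at <- pdb$atom
  ele <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  blank <- !nzchar(ele)
  if (any(blank)) ele[blank] <- .guess_element(at$elety[blank])
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  as_reference(xyz,
               element = ele,
               atom_name = trimws(at$elety),
               resid = at$resno,
               resname = trimws(at$resid),
               chain = ifelse(is.na(at$chain), "A", at$chain),
               source = source)
}

#' Conformational ensemble container
#'
#' @param frames numeric T x N x 3 array of positions (Angstrom), atom order
#'   identical to the associated reference.
#' @param times optional per-frame time stamps (ns).
#' @return An object of class `nap_ensemble` with components `frames`,
#'   `times`, `nframes`, `natoms`.
#' @export
as_ensemble <- function(frames, times = NULL) {
  if (length(dim(frames)) != 3L || dim(frames)[3] != 3L) {
    stop("frames must be a T x N x 3 array")
  }
  if (dim(frames)[1] < 1L) stop("ensemble must contain at least one frame")
  if (!all(is.finite(frames))) stop("frame coordinates must be finite")
  if (!is.null(times) && length(times) != dim(frames)[1]) {
    stop("times must have one entry per frame")
  }
  ens <- list(frames = unname(frames), times = times,
              nframes = dim(frames)[1], natoms = dim(frames)[2])
  class(ens) <- "nap_ensemble"
  ens
}

#' @export
print.nap_ensemble <- function(x, ...) {
  cat("nap_ensemble:", x$nframes, "frames x", x$natoms, "atoms\n")
  invisible(x)
}

#' Extract one frame as an N x 3 coordinate matrix
#' @param ens a [as_ensemble()] object.
#' @param t 1-based frame index.
#' @export
frame_coords <- function(ens, t) {
  ens$frames[t, , , drop = TRUE]
}

#' Read a conformational ensemble
#'
#' Reads a trajectory and checks its atom count against the topology.
#' Supported trajectory formats: multi-model PDB (Angstrom), CHARMM/NAMD
#' DCD (Angstrom, via bio3d), and GROMACS GRO (nm, converted to Angstrom
#' on read). Atom order must match the topology/reference order.
#'
#' @param topology path to the topology/reference PDB (used for the atom
#'   count and, for `check_order`, atom names).
#' @param trajectory path to the trajectory; if `NULL`, `topology` itself is
#'   read as a multi-model PDB ensemble.
#' @return A [as_ensemble()] object, coordinates in Angstrom.
#' @export
read_ensemble <- function(topology, trajectory = NULL) {
  ref <- read_reference(topology)
  if (is.null(trajectory)) trajectory <- topology
  ext <- tolower(tools::file_ext(trajectory))
  if (ext %in% c("pdb", "ent")) {
    pdb <- .read_pdb_checked(trajectory, multi = TRUE)
    nat <- nrow(pdb$atom)
    frames <- aperm(array(t(pdb$xyz), dim = c(3L, nat, nrow(pdb$xyz))),
                    c(3L, 2L, 1L))
    times <- NULL
  } else if (ext == "dcd") {
    xyz <- bio3d::read.dcd(trajectory, verbose = FALSE)
    nat <- ncol(xyz) / 3L
    frames <- aperm(array(t(xyz), dim = c(3L, nat, nrow(xyz))), c(3L, 2L, 1L))
    times <- NULL
  } else if (ext == "gro") {
    g <- read_gro(trajectory)
    frames <- g$frames
    nat <- dim(frames)[2]
    times <- g$times
  } else {
    stop("unsupported trajectory format: .", ext,
         " (supported: pdb, dcd, gro)")
  }
  if (nat != ref$natoms) {
    stop("atom-count mismatch: topology has ", ref$natoms,
         " atoms but trajectory has ", nat)
  }
  as_ensemble(frames, times)
}

#' Read a (possibly multi-frame) GROMACS GRO file
#'
#' GRO stores coordinates in nm; they are converted to Angstrom. Frames are
#' concatenated blocks of title / atom-count / atoms / box line.
#'
#' @param path path to a .gro file.
#' @return list with `frames` (T x N x 3, Angstrom) and `times` (ns, parsed
#'   from `t=` in title lines when present, else NULL).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  times <- numeric(0)
  have_time <- TRUE
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    title <- lines[pos]
    nat <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(nat)) stop("malformed GRO file at line ", pos + 1L)
    body <- lines[pos + 1L + seq_len(nat)]
    # fixed columns: resno(1-5) resname(6-10) name(11-15) atomno(16-20),
    # then coordinates in free-ish %8.3f fields
    xyz <- t(vapply(body, function(l) {
      as.numeric(c(substr(l, 21L, 28L), substr(l, 29L, 36L),
                   substr(l, 37L, 44L)))
    }, numeric(3), USE.NAMES = FALSE))
    if (any(is.na(xyz))) stop("malformed GRO coordinate record")
    frames[[length(frames) + 1L]] <- xyz * 10  # nm -> Angstrom
    tm <- regmatches(title, regexec("t=\\s*([0-9.eE+-]+)", title))[[1]]
    if (length(tm) == 2L) times <- c(times, as.numeric(tm[2]) / 1000)
    else have_time <- FALSE
    pos <- pos + nat + 3L  # title + count + atoms + box
  }
  if (!length(frames)) stop("no frames found in GRO file: ", path)
  arr <- aperm(array(unlist(frames),
                     dim = c(nrow(frames[[1]]), 3L, length(frames))),
               c(3L, 1L, 2L))
  list(frames = arr, times = if (have_time) times else NULL)
}

#' Write a reference + ensemble as a multi-frame GRO file (nm)
#'
#' @param ref a [as_reference()] object supplying atom metadata.
#' @param ens a [as_ensemble()] object (Angstrom; written as nm).
#' @param path output path.
#' @export
write_gro <- function(ref, ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(ens$nframes)) {
    tm <- if (!is.null(ens$times)) ens$times[t] * 1000 else t - 1
    writeLines(sprintf("nonaffine ensemble, t= %.3f", tm), con)
    writeLines(sprintf("%5d", ref$natoms), con)
    xyz <- frame_coords(ens, t) / 10  # Angstrom -> nm
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       ref$resid %% 100000L,
                       substr(ref$resname, 1L, 5L),
                       substr(ref$atom_name, 1L, 5L),
                       seq_len(ref$natoms) %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("  0.00000  0.00000  0.00000", con)
  }
  invisible(path)
}

#' Write a reference (or ensemble) as a (multi-model) PDB file
#'
#' @param ref a [as_reference()] object.
#' @param path output path.
#' @param ens optional [as_ensemble()]; if given, one MODEL per frame.
#' @param b optional per-atom B-factor column values.
#' @export
write_structure <- function(ref, path, ens = NULL, b = NULL) {
  xyz <- if (is.null(ens)) {
    matrix(as.vector(t(ref$xyz)), nrow = 1L)
  } else {
    t(apply(ens$frames, 1L, function(fr) as.vector(t(fr))))
  }
  if (is.null(b)) b <- rep(0, ref$natoms)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = ref$resid, resid = ref$resname,
                   eleno = seq_len(ref$natoms), elety = ref$atom_name,
                   chain = ref$chain, elesy = ref$element,
                   b = round(b, 2))
  invisible(path)
}

#' Select atoms of a reference structure
#'
#' A small selection language: clauses joined by `" and "`, each clause one
#' of `all`, `heavy` (element not H/D), `resid 10-12` or `resid 10,14`,
#' `chain A[,B]`, `name CA[,CB]`, `elem C[,N]`. Residue ids are those of the
#' source file.
#'
#' @param ref a [as_reference()] object.
#' @param query selection string, e.g. `"resid 10-12 and heavy"`.
#' @return sorted, duplicate-free 1-based atom indices.
#' @export
select_atoms <- function(ref, query) {
  keep <- rep(TRUE, ref$natoms)
  clauses <- strsplit(query, "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    cl <- trimws(cl)
    if (cl == "" || cl == "all") next
    if (cl %in% c("heavy", "noh")) { keep <- keep & ref$heavy; next }
    parts <- regmatches(cl, regexec("^(resid|chain|name|elem)\\s+(\\S+)$", cl))[[1]]
    if (length(parts) != 3L) stop("cannot parse selection clause: '", cl, "'")
    key <- parts[2]; val <- parts[3]
    if (key == "resid") {
      ids <- integer(0)
      for (tok in strsplit(val, ",")[[1]]) {
        if (grepl("-", tok)) {
          rng <- as.integer(strsplit(tok, "-")[[1]])
          ids <- c(ids, seq(rng[1], rng[2]))
        } else ids <- c(ids, as.integer(tok))
      }
      if (!any(ref$resid %in% ids)) {
        stop("selection matches no atoms: no residues ", val)
      }
      keep <- keep & ref$resid %in% ids
    } else if (key == "chain") {
      ch <- strsplit(val, ",")[[1]]
      if (!any(ref$chain %in% ch)) stop("selection matches no atoms: no chain ", val)
      keep <- keep & ref$chain %in% ch
    } else if (key == "name") {
      keep <- keep & ref$atom_name %in% strsplit(val, ",")[[1]]
    } else if (key == "elem") {
      keep <- keep & ref$element %in% toupper(strsplit(val, ",")[[1]])
    }
  }
  idx <- which(keep)
  if (!length(idx)) stop("empty selection: '", query, "'")
  idx
}
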