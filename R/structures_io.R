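# Structural data model and file I/O.
#
# The shared containers are deliberately light: a receptor is an atom table
# (one row per atom, grouped by chain/residue), a pose is an atom table plus
# a bond table. All coordinates are in Angstrom, in the receptor frame.

VALID_ELEMENTS <- c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I")

#' Construct a receptor object
#'
#' @param atoms data.frame with columns `chain`, `resnum`, `resname`,
#'   `name` (PDB atom name, unique within a residue), `element`, `x`, `y`,
#'   `z`.
#' @param model_id character label, e.g. `"3G5U_Pgp"`.
#' @param state_label one of `"apo"` or `"nucleotide_bound"` — the catalytic
#'   state the model represents.
#' @return an object of class `receptor`.
#' @export
receptor <- function(atoms, model_id = "receptor", state_label = c("apo", "nucleotide_bound")) {
  state_label <- match.arg(state_label)
  req <- c("chain", "resnum", "resname", "name", "element", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    stop("receptor atoms need columns: ", paste(setdiff(req, names(atoms)), collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty structure")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in receptor")
  }
  atoms$element <- toupper(atoms$element)
  bad <- setdiff(unique(atoms$element), VALID_ELEMENTS)
  if (length(bad)) stop("invalid element symbol(s): ", paste(bad, collapse = ", "))
  if (any(atoms$resnum < 1)) stop("residue numbers must be >= 1")
  key <- paste(atoms$chain, atoms$resnum, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resnum, atom name): ", key[duplicated(key)][1])
  }
  atoms$is_heavy <- atoms$element != "H"
  rownames(atoms) <- NULL
  structure(list(model_id = model_id, state_label = state_label, atoms = atoms),
            class = "receptor")
}

#' @export
print.receptor <- function(x, ...) {
  res <- unique(paste(x$atoms$chain, x$atoms$resnum))
  cat(sprintf("<receptor '%s' (%s): %d residues, %d atoms>\n",
              x$model_id, x$state_label, length(res), nrow(x$atoms)))
  invisible(x)
}

#' Residue table of a receptor
#'
#' @param rec a [receptor].
#' @return data.frame with one row per residue (`chain`, `resnum`,
#'   `resname`), in order of first appearance.
#' @export
receptor_residues <- function(rec) {
  a <- rec$atoms
  u <- !duplicated(paste(a$chain, a$resnum))
  out <- a[u, c("chain", "resnum", "resname")]
  rownames(out) <- NULL
  out
}

#' Extract one residue from a receptor
#'
#' @param rec a [receptor].
#' @param chain chain identifier.
#' @param resnum residue number (as printed in the PDB; human P-gp
#'   numbering in the packaged scenes, e.g. 307 for Y307).
#' @return data.frame of the residue's atoms.
#' @export
residue_atoms <- function(rec, chain, resnum) {
  sel <- rec$atoms$chain == chain & rec$atoms$resnum == resnum
  if (!any(sel)) stop(sprintf("residue (%s, %d) not found", chain, resnum))
  out <- rec$atoms[sel, ]
  rownames(out) <- NULL
  out
}

#' Construct a ligand pose
#'
#' @param ligand_id ligand identifier (e.g. `"GPV062"`).
#' @param pose_id integer pose identifier, unique within a ligand.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `name` (defaults to element + index).
#' @param bonds data.frame with columns `from`, `to` (1-based atom indices)
#'   and `order` (1, 2, 3).
#' @param protonation `"neutral"` or `"ionized"` — an input tag, never
#'   computed (ionisation states are docked separately upstream).
#' @return an object of class `pose`.
#' @export
pose <- function(ligand_id, pose_id, atoms, bonds,
                 protonation = c("neutral", "ionized")) {
  protonation <- match.arg(protonation)
  atoms <- as.data.frame(atoms)
  atoms$element <- toupper(atoms$element)
  bad <- setdiff(unique(atoms$element), VALID_ELEMENTS)
  if (length(bad)) stop("invalid element symbol(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in pose ", ligand_id, "/", pose_id)
  }
  atoms$is_heavy <- atoms$element != "H"
  if (!any(atoms$is_heavy)) stop("pose must contain at least one heavy atom")
  if (is.null(atoms$name)) atoms$name <- paste0(atoms$element, seq_len(nrow(atoms)))
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0) {
    idx <- c(bonds$from, bonds$to)
    if (any(idx < 1 | idx > nrow(atoms))) stop("bond index out of range")
  }
  rownames(atoms) <- NULL
  structure(list(ligand_id = ligand_id, pose_id = as.integer(pose_id),
                 atoms = atoms, bonds = bonds, protonation = protonation),
            class = "pose")
}

#' Coordinates of a pose as a matrix
#'
#' @param p a [pose].
#' @param heavy_only drop hydrogens (default TRUE).
#' @return numeric matrix, one row per atom, columns x/y/z.
#' @export
pose_coords <- function(p, heavy_only = FALSE) {
  a <- p$atoms
  if (heavy_only) a <- a[a$is_heavy, ]
  as.matrix(a[, c("x", "y", "z")])
}

#' Construct a pose ensemble
#'
#' The clustering input: all poses of all ligands of one docking run, in a
#' common receptor frame.
#'
#' @param poses list of [pose] objects.
#' @param receptor_ref model_id of the receptor the poses were docked into.
#' @return an object of class `pose_ensemble`.
#' @export
pose_ensemble <- function(poses, receptor_ref = "receptor") {
  key <- vapply(poses, function(p) paste(p$ligand_id, p$pose_id), "")
  if (anyDuplicated(key)) {
    stop("duplicate (ligand_id, pose_id): ", key[duplicated(key)][1])
  }
  structure(list(poses = poses, receptor_ref = receptor_ref),
            class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  lig <- ensemble_ligands(x)
  cat(sprintf("<pose_ensemble: %d poses, %d ligands (%s), frame '%s'>\n",
              length(x$poses), length(lig), paste(lig, collapse = ", "),
              x$receptor_ref))
  invisible(x)
}

#' Ligand ids present in an ensemble
#' @param ens a [pose_ensemble].
#' @return character vector of distinct ligand ids, in order of appearance.
#' @export
ensemble_ligands <- function(ens) {
  unique(vapply(ens$poses, function(p) p$ligand_id, ""))
}

#' Poses of one ligand
#' @param ens a [pose_ensemble].
#' @param ligand_id ligand identifier.
#' @return list of [pose] objects.
#' @export
ligand_poses <- function(ens, ligand_id) {
  Filter(function(p) p$ligand_id == ligand_id, ens$poses)
}

# ---------------------------------------------------------------- PDB I/O

#' Read a receptor from a PDB file
#'
#' ATOM records only; HETATM (waters, ligands, ions) are excluded unless
#' `include_het = TRUE`. Insertion codes are rejected — the pipeline
#' addresses residues by plain (chain, resnum), as printed in the human
#' P-gp numbering. Alternate locations: altloc A (or blank) kept, others
#' dropped with a message.
#'
#' @param path PDB file.
#' @param model_id label stored on the receptor; default the file name.
#' @param state_label catalytic state of the model.
#' @param include_het keep HETATM records (default FALSE).
#' @return a [receptor].
#' @export
read_receptor <- function(path, model_id = NULL,
                          state_label = c("apo", "nucleotide_bound"),
                          include_het = FALSE) {
  state_label <- match.arg(state_label)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("malformed PDB file '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (!include_het) at <- at[at$type == "ATOM", ]
  at <- at[!(at$resid %in% c("HOH", "WAT")), ]
  if (nrow(at) == 0) stop("empty structure: no ATOM records in ", path)
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported (found in ", path, ")")
  }
  alt_drop <- !is.na(at$alt) & !(at$alt %in% c("", "A"))
  if (any(alt_drop)) {
    message(sum(alt_drop), " alternate-location atoms dropped (kept altloc A)")
    at <- at[!alt_drop, ]
  }
  elem <- at$elesy
  miss <- is.na(elem) | elem == ""
  if (any(miss)) elem[miss] <- guess_element(at$elety[miss])
  receptor(data.frame(chain = at$chain, resnum = at$resno, resname = at$resid,
                      name = at$elety, element = toupper(elem),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE),
           model_id = model_id %||% sub("\\.pdb$", "", basename(path)),
           state_label = state_label)
}

# Infer the element from a PDB atom name (fallback when columns 77-78 are
# blank): strip digits, two-letter halogens first.
guess_element <- function(name) {
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR"), two, substr(nm, 1, 1))
}

#' Write a receptor to a PDB file
#'
#' @param rec a [receptor].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_receptor <- function(rec, path) {
  a <- rec$atoms
  n <- nrow(a)
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resnum, chain = a$chain, resid = a$resname,
                   elety = a$name, elesy = a$element,
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

# ---------------------------------------------------------------- SDF I/O

# ChemmineR native block shapes (atomblock: 15 numeric columns named
# C1,C2,C3,C5..C16 with x,y,z first; bondblock: 7 columns C1..C7).
.AB_COLS <- c("C1", "C2", "C3", paste0("C", 5:16))
.BB_COLS <- paste0("C", 1:7)

pose_to_sdf <- function(p) {
  a <- p$atoms
  n <- nrow(a)
  ab <- matrix(0, nrow = n, ncol = length(.AB_COLS),
               dimnames = list(paste(elem_title(a$element), seq_len(n), sep = "_"),
                               .AB_COLS))
  ab[, 1:3] <- as.matrix(a[, c("x", "y", "z")])
  b <- p$bonds
  bb <- matrix(0, nrow = nrow(b), ncol = 7,
               dimnames = list(if (nrow(b)) as.character(seq_len(nrow(b))) else NULL,
                               .BB_COLS))
  if (nrow(b)) {
    bb[, 1] <- b$from; bb[, 2] <- b$to; bb[, 3] <- b$order
  }
  nm <- paste(p$ligand_id, p$pose_id, sep = "_")
  methods::new("SDF",
               header = c(Molecule_Name = nm, Source = "  -sarpose-", Comment = "",
                          Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                                n, nrow(b))),
               atomblock = ab, bondblock = bb,
               datablock = c(ligand_id = p$ligand_id,
                             pose_id = as.character(p$pose_id),
                             protonation = p$protonation))
}

elem_title <- function(e) {
  paste0(substr(e, 1, 1), tolower(substr(e, 2, nchar(e))))
}

#' Write a pose ensemble to a multi-record SDF file
#'
#' Each record carries the data tags `ligand_id`, `pose_id` and
#' `protonation`.
#'
#' @param ens a [pose_ensemble].
#' @param path output SDF file.
#' @return `path`, invisibly.
#' @export
write_pose_ensemble <- function(ens, path) {
  sdfs <- lapply(ens$poses, pose_to_sdf)
  ids <- vapply(ens$poses, function(p) paste(p$ligand_id, p$pose_id, sep = "_"), "")
  set <- methods::new("SDFset", SDF = sdfs, ID = ids)
  ChemmineR::write.SDF(set, file = path, cid = TRUE)
  invisible(path)
}

#' Read a pose ensemble from SDF files
#'
#' Every record must carry the configured ligand-id and pose-id tags.
#' Records whose coordinates are all-zero in z with more than three atoms
#' are treated as 2D depictions: they are rejected with a warning and
#' recorded in the `rejected` attribute of the result.
#'
#' @param paths one or more SDF files.
#' @param tags names of the SDF data tags holding ligand id, pose id and
#'   protonation state.
#' @param receptor_ref model_id of the receptor frame.
#' @return a [pose_ensemble]; rejected records (if any) in
#'   `attr(, "rejected")`.
#' @export
read_pose_ensemble <- function(paths,
                               tags = list(ligand_id = "ligand_id",
                                           pose_id = "pose_id",
                                           protonation = "protonation"),
                               receptor_ref = "receptor") {
  poses <- list()
  rejected <- data.frame(path = character(), record = integer(),
                         reason = character())
  warned_empty <- FALSE
  for (path in paths) {
    if (!file.exists(path)) stop("file not found: ", path)
    set <- tryCatch(ChemmineR::read.SDFset(path),
                    error = function(e) NULL)
    if (is.null(set) || length(set) == 0) {
      warning("no SDF records read from ", path)
      warned_empty <- TRUE
      next
    }
    for (i in seq_along(set)) {
      sdf <- set[[i]]
      db <- ChemmineR::datablock(sdf)
      for (tg in c(tags$ligand_id, tags$pose_id)) {
        if (!tg %in% names(db) || is.na(db[[tg]])) {
          stop(sprintf("record %d of %s lacks tag '%s'", i, path, tg))
        }
      }
      lid <- db[[tags$ligand_id]]
      pid <- db[[tags$pose_id]]
      prot <- if (tags$protonation %in% names(db) &&
                    !is.na(db[[tags$protonation]])) db[[tags$protonation]]
              else "neutral"
      ab <- ChemmineR::atomblock(sdf)
      bb <- ChemmineR::bondblock(sdf)
      elem <- toupper(sub("_.*$", "", rownames(ab)))
      atoms <- data.frame(element = elem, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                          stringsAsFactors = FALSE)
      if (nrow(atoms) > 3 && all(abs(atoms$z) < 1e-9)) {
        warning(sprintf("record %d of %s looks 2D (all z = 0); rejected", i, path))
        rejected <- rbind(rejected,
                          data.frame(path = path, record = i, reason = "2D coordinates"))
        next
      }
      bonds <- data.frame(from = integer(), to = integer(), order = integer())
      if (!is.null(bb) && nrow(bb) > 0) {
        bonds <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                            order = as.integer(bb[, 3]))
      }
      poses[[length(poses) + 1]] <- pose(lid, as.integer(pid), atoms, bonds,
                                         protonation = prot)
    }
  }
  if (length(poses) == 0 && nrow(rejected) == 0 && !warned_empty) {
    warning("empty pose ensemble")
  }
  ens <- pose_ensemble(poses, receptor_ref = receptor_ref)
  attr(ens, "rejected") <- rejected
  ens
}
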