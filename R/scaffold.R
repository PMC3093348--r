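# Common-scaffold matching.
#
# The ligand series shares one scaffold (for propafenone-type inhibitors:
# the aryloxy ring bearing a phenyl ketone, with the two-carbon ether
# linker to the amine nitrogen). Each pose's atoms are mapped onto the
# scaffold's canonical atom order by labelled subgraph matching; all
# symmetry-equivalent matches (e.g. flips of a monosubstituted phenyl) are
# enumerated so that RMSD can later minimise over them.

#' Define a scaffold
#'
#' A scaffold is a heavy-atom molecular graph: element labels in canonical
#' order plus a bond list. Matching is by element + connectivity
#' (non-induced subgraph isomorphism); bond orders are ignored, hydrogens
#' are excluded throughout.
#'
#' @param elements character vector of element symbols, one per scaffold
#'   atom, in canonical order.
#' @param bonds two-column matrix/data.frame of 1-based atom index pairs.
#' @param labels optional atom labels (default element + index).
#' @return an object of class `scaffold_spec`, with the scaffold's graph
#'   automorphisms enumerated in `$symmetry_maps` (identity always first).
#' @export
scaffold_spec <- function(elements, bonds, labels = NULL) {
  elements <- toupper(elements)
  if (any(elements == "H")) stop("scaffold atoms must be heavy atoms")
  bonds <- as.matrix(bonds)[, 1:2, drop = FALSE]
  if (any(bonds < 1 | bonds > length(elements))) stop("scaffold bond index out of range")
  labels <- labels %||% paste0(elements, seq_along(elements))
  sp <- structure(list(elements = elements, bonds = bonds,
                       canonical_order = labels),
                  class = "scaffold_spec")
  auto <- match_subgraph(elements, bonds, elements, bonds)
  # put identity first for determinism
  is_id <- vapply(auto, function(m) all(m == seq_along(elements)), TRUE)
  sp$symmetry_maps <- c(auto[is_id], auto[!is_id])
  sp
}

#' The packaged default scaffold
#'
#' An arylketone scaffold: a central benzene ring carrying (ortho) a phenyl
#' ketone and an aryl ether, with a two-carbon linker from the ether oxygen
#' to an amine nitrogen — 18 heavy atoms. The pendant (monosubstituted)
#' phenyl ring contributes a twofold ring-flip symmetry, so the scaffold
#' has two automorphisms.
#'
#' @return a [scaffold_spec].
#' @export
default_scaffold <- function() {
  # atoms: 1-6 ring A; 7 carbonyl C; 8 carbonyl O; 9-14 ring B (9 bonded
  # to 7); 15 ether O (on ring atom 2); 16,17 linker C; 18 amine N
  elements <- c(rep("C", 6), "C", "O", rep("C", 6), "O", "C", "C", "N")
  bonds <- rbind(
    c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1),  # ring A
    c(1, 7), c(7, 8),                                       # ketone
    c(7, 9), c(9, 10), c(10, 11), c(11, 12), c(12, 13), c(13, 14), c(14, 9),
    c(2, 15), c(15, 16), c(16, 17), c(17, 18)               # ether + linker
  )
  scaffold_spec(elements, bonds)
}

# Non-induced labelled subgraph matching via igraph's LAD solver.
# Element compatibility is enforced through per-vertex domains (same
# element, target degree >= pattern degree). Returns a list of integer
# vectors: position i = target atom matched to pattern atom i.
match_subgraph <- function(pat_elem, pat_bonds, tgt_elem, tgt_bonds) {
  gp <- igraph::make_graph(t(pat_bonds), n = length(pat_elem), directed = FALSE)
  gt <- igraph::make_graph(t(tgt_bonds), n = length(tgt_elem), directed = FALSE)
  dp <- igraph::degree(gp)
  dt <- igraph::degree(gt)
  domains <- lapply(seq_along(pat_elem), function(i) {
    cand <- which(tgt_elem == pat_elem[i] & dt >= dp[i])
    if (length(cand) == 0) return(integer(0))
    cand
  })
  if (any(lengths(domains) == 0)) return(list())
  res <- igraph::subgraph_isomorphisms(gp, gt, method = "lad",
                                       induced = FALSE, domains = domains)
  lapply(res, as.integer)
}

#' Map every ligand of an ensemble onto a scaffold
#'
#' Matching uses topology only, so it is computed once per ligand (on its
#' first pose) and shared by all poses of that ligand.
#'
#' @param ens a [pose_ensemble].
#' @param spec a [scaffold_spec], or a named list
#'   `list(ligand_id = c(indices...))` of explicit 1-based heavy-atom maps.
#' @param max_matches combinatorial guard; more matches for one ligand is
#'   an error (default 64).
#' @return named list: ligand_id -> `scaffold_map` with element
#'   `$mappings` (list of integer vectors in canonical scaffold order).
#' @export
build_scaffold_maps <- function(ens, spec = default_scaffold(), max_matches = 64) {
  ligs <- ensemble_ligands(ens)
  if (!inherits(spec, "scaffold_spec")) {
    # explicit per-ligand atom index lists
    maps <- lapply(ligs, function(l) {
      m <- spec[[l]]
      if (is.null(m)) stop("no scaffold atom map for ligand ", l)
      structure(list(ligand_id = l, mappings = list(as.integer(m))),
                class = "scaffold_map")
    })
    names(maps) <- ligs
    return(maps)
  }
  maps <- lapply(ligs, function(l) {
    p <- ligand_poses(ens, l)[[1]]
    heavy <- which(p$atoms$is_heavy)
    # reindex bonds to the heavy-atom subgraph
    hidx <- match(seq_len(nrow(p$atoms)), heavy)
    b <- as.matrix(p$bonds[, c("from", "to"), drop = FALSE])
    b <- b[p$atoms$is_heavy[b[, 1]] & p$atoms$is_heavy[b[, 2]], , drop = FALSE]
    b <- cbind(hidx[b[, 1]], hidx[b[, 2]])
    m <- match_subgraph(spec$elements, spec$bonds,
                        p$atoms$element[heavy], b)
    if (length(m) == 0) stop("ligand ", l, " does not match the scaffold")
    if (length(m) > max_matches) {
      stop("ligand ", l, " has ", length(m), " scaffold matches (> ",
           max_matches, "); refine the scaffold pattern")
    }
    # back to full-pose atom indices, deterministic order
    m <- lapply(m, function(v) heavy[v])
    m <- m[order(vapply(m, paste, "", collapse = ","))]
    structure(list(ligand_id = l, mappings = m), class = "scaffold_map")
  })
  names(maps) <- ligs
  maps
}

#' Scaffold coordinates of a pose
#'
#' @param p a [pose].
#' @param mapping integer vector of atom indices in canonical scaffold
#'   order (one element of a scaffold_map's `$mappings`).
#' @return N x 3 coordinate matrix in canonical scaffold order.
#' @export
scaffold_coords <- function(p, mapping) {
  if (any(mapping < 1 | mapping > nrow(p$atoms))) {
    stop("scaffold mapping index out of range for pose ",
         p$ligand_id, "/", p$pose_id)
  }
  if (any(!p$atoms$is_heavy[mapping])) {
    stop("scaffold mapping addresses a hydrogen")
  }
  as.matrix(p$atoms[mapping, c("x", "y", "z")])
}
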