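#' @title Molecular structure input/output
#' @description Readers for receptor (PDB) and ligand (SDF/MOL2) structures,
#'   rotatable-bond detection, and pose-set SDF output. Hydrogens are dropped
#'   on input: scoring, RMSD and torsion detection are heavy-atom only.
#' @name mol_io
NULL

# ---- constructors -----------------------------------------------------------

#' Build a receptor object
#'
#' @param coords n x 3 numeric matrix of heavy-atom coordinates (Angstrom).
#' @param element character vector of element symbols.
#' @param residue_id character vector assigning each atom to a residue.
#' @param serial optional integer atom serials.
#' @return An object of class `gi_receptor`: coordinate matrix, elements,
#'   vdW radii, and the residue partition (named list of atom indices).
#' @export
new_receptor <- function(coords, element, residue_id, serial = seq_len(nrow(coords))) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == length(element),
            length(residue_id) == length(element))
  if (!all(is.finite(coords))) stop("receptor coordinates must be finite")
  residue_id <- as.character(residue_id)
  residues <- split(seq_along(residue_id), factor(residue_id, levels = unique(residue_id)))
  structure(list(
    coords = unname(coords),
    element = normalize_element(element),
    radius = lookup_radii(element),
    residue_id = residue_id,
    residues = residues,
    serial = as.integer(serial)
  ), class = "gi_receptor")
}

#' Build a ligand object from atoms and bonds
#'
#' Hydrogens (and their bonds) are removed; the bond graph must be connected
#' over the remaining heavy atoms. Rotatable torsions, non-bonded
#' intramolecular pairs (graph distance >= 4 bonds) and the bond-graph
#' automorphism group (element- and bond-order-preserving, enumeration capped
#' at 10000 mappings) are precomputed.
#'
#' @param coords n x 3 reference coordinates (Angstrom).
#' @param element element symbols.
#' @param bonds m x 3 integer matrix: atom i, atom j, bond order.
#' @return An object of class `gi_ligand`.
#' @export
new_ligand <- function(coords, element, bonds) {
  coords <- as.matrix(coords)
  element <- normalize_element(element)
  bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 3)
  heavy <- !is_hydrogen(element)
  if (!all(heavy)) {
    keep <- which(heavy)
    remap <- integer(length(element)); remap[keep] <- seq_along(keep)
    bonds <- bonds[heavy[bonds[, 1]] & heavy[bonds[, 2]], , drop = FALSE]
    bonds[, 1] <- remap[bonds[, 1]]; bonds[, 2] <- remap[bonds[, 2]]
    coords <- coords[keep, , drop = FALSE]
    element <- element[keep]
  }
  n <- nrow(coords)
  if (n < 1L) stop("ligand has no heavy atoms")
  if (!all(is.finite(coords))) stop("ligand coordinates must be finite")
  g <- igraph::graph_from_edgelist(bonds[, 1:2, drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  if (igraph::components(g)$no != 1L)
    stop("ligand bond graph is disconnected")
  lig <- structure(list(
    coords = unname(coords),
    element = element,
    radius = lookup_radii(element),
    bonds = bonds,
    graph = g
  ), class = "gi_ligand")
  lig$torsions <- detect_rotatable_bonds(lig)
  d <- igraph::distances(g)
  ip <- which(upper.tri(d) & d >= 4, arr.ind = TRUE)
  lig$internal_pairs <- matrix(as.integer(ip), ncol = 2)
  lig$auto_perms <- ligand_automorphisms(lig)
  lig
}

# Enumerate bond-graph automorphisms as an n_maps x n_atoms index matrix
# (identity first). Colored VF2: vertex color = element, edge color = order.
# Beyond the cap we fall back to the identity mapping with a warning.
ligand_automorphisms <- function(ligand, cap = 10000L) {
  n <- nrow(ligand$coords)
  identity_map <- matrix(seq_len(n), nrow = 1)
  if (nrow(ligand$bonds) == 0L) return(identity_map)
  vc <- as.integer(factor(ligand$element))
  ec <- as.integer(ligand$bonds[, 3])
  g <- ligand$graph
  cnt <- igraph::count_isomorphisms(g, g, method = "vf2",
                                    vertex.color1 = vc, vertex.color2 = vc,
                                    edge.color1 = ec, edge.color2 = ec)
  if (cnt > cap) {
    warning(sprintf("ligand has %d graph automorphisms (cap %d); using identity mapping only",
                    cnt, cap), call. = FALSE)
    return(identity_map)
  }
  maps <- igraph::isomorphisms(g, g, method = "vf2",
                               vertex.color1 = vc, vertex.color2 = vc,
                               edge.color1 = ec, edge.color2 = ec)
  perms <- do.call(rbind, lapply(maps, as.integer))
  # identity first, rest in enumeration order
  is_id <- rowSums(perms != rep(seq_len(n), each = nrow(perms))) == 0
  rbind(identity_map, perms[!is_id, , drop = FALSE])
}

#' Build a pose object
#'
#' @param coords per-ligand-atom coordinate matrix (Angstrom).
#' @param score total energy (lower is better).
#' @param breakdown list with `vdw_attractive`, `vdw_repulsive`, `internal`,
#'   `total` components.
#' @param provenance list with `potential` ("normal" or "soft"),
#'   `conformation_id`, `iteration`, `rank`.
#' @return An object of class `gi_pose`.
#' @export
new_pose <- function(coords, score, breakdown = NULL,
                     provenance = list(potential = "normal", conformation_id = 0L,
                                       iteration = 0L, rank = NA_integer_)) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, is.finite(score))
  need <- c("potential", "conformation_id", "iteration", "rank")
  if (!all(need %in% names(provenance)))
    stop("pose provenance must carry: ", paste(need, collapse = ", "))
  structure(list(coords = unname(coords), score = score,
                 breakdown = breakdown, provenance = provenance),
            class = "gi_pose")
}

# ---- PDB receptor -----------------------------------------------------------

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a receptor from a PDB file
#'
#' Keeps protein `ATOM` records only: waters and HETATM ligands/ions are
#' dropped. For alternate locations the highest-occupancy copy is kept (ties
#' broken by file order); insertion codes are part of the residue key
#' `(chain, resseq, icode)`. Multi-model files use the first MODEL, with a
#' warning. Elements come from the element column, falling back to an
#' atom-name heuristic.
#'
#' @param path PDB file path.
#' @return A [new_receptor()] object.
#' @export
read_receptor <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec_lines <- grep("^(ATOM  |HETATM)", lines)
  for (ln in rec_lines) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[ln], 31, 38),
                                         substr(lines[ln], 39, 46),
                                         substr(lines[ln], 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("PDB parse error at line %d: bad coordinate field", ln))
  }
  if (sum(grepl("^MODEL ", lines)) > 1L)
    warning("multiple MODELs in PDB; using the first", call. = FALSE)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% WATER_RESIDUES), , drop = FALSE]
  if (nrow(at) > 0) {
    # alternate locations: highest occupancy per (chain, resno, icode, name)
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    best <- tapply(seq_len(nrow(at)), key, function(ix) ix[which.max(occ[ix])])
    at <- at[sort(unname(unlist(best))), , drop = FALSE]
  }
  el <- at$elesy
  miss <- is.na(el) | trimws(el) == ""
  el[miss] <- element_from_atom_name(at$elety[miss])
  heavy <- !is_hydrogen(el)
  at <- at[heavy, , drop = FALSE]; el <- el[heavy]
  if (nrow(at) == 0L)
    stop("no protein atoms found in ", path, " (empty structure)")
  icode <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  chain <- ifelse(is.na(at$chain) | at$chain == "", "_", at$chain)
  rid <- paste0(chain, "_", at$resno, icode)
  new_receptor(cbind(at$x, at$y, at$z), el, rid, serial = at$eleno)
}

# PDB atom-name heuristic: strip digits/primes, two-letter symbols only when
# the name starts in column 13 with a recognized two-letter element.
element_from_atom_name <- function(names) {
  vapply(names, function(nm) {
    nm <- gsub("[0-9']", "", trimws(nm))
    two <- normalize_element(substr(nm, 1, 2))
    if (nchar(nm) >= 2 && two %in% names(vdw_radii) && two %in% c("Cl", "Br", "Fe", "Zn", "Mg", "Na", "Se", "Mn", "Ca"))
      return(two)
    substr(nm, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Write a receptor to a PDB file
#'
#' Each atom is written as an `ATOM` record; single-atom synthetic residues
#' round-trip through [read_receptor()].
#'
#' @param receptor a `gi_receptor`.
#' @param path output path.
#' @export
write_receptor <- function(receptor, path) {
  n <- nrow(receptor$coords)
  rid <- factor(receptor$residue_id, levels = unique(receptor$residue_id))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(receptor$coords)),
                   type = rep("ATOM", n),
                   eleno = seq_len(n),
                   elety = sprintf("%s%d", receptor$element,
                                   stats::ave(seq_len(n), rid, FUN = seq_along)),
                   resid = rep("GLY", n),
                   chain = rep("A", n),
                   resno = as.integer(rid),
                   elesy = receptor$element)
  invisible(path)
}

# ---- ligand SDF / MOL2 ------------------------------------------------------

#' Read a ligand from an SDF or MOL2 file
#'
#' The file must contain one molecule with an explicit bond block (use
#' `record` to select one from a multi-record file). Hydrogens are dropped;
#' rotatable torsions are detected automatically.
#'
#' @param path file path.
#' @param format "sdf" or "mol2" (default: from file extension).
#' @param record record index for multi-record files.
#' @return A [new_ligand()] object.
#' @export
read_ligand <- function(path, format = c("auto", "sdf", "mol2"), record = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "sdf"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mol2") {
    if (!requireNamespace("ChemmineOB", quietly = TRUE))
      stop("MOL2 input requires the ChemmineOB package")
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    ChemmineOB::convertFormatFile("MOL2", "SDF", path, tmp)
    path <- tmp
  }
  sdfs <- ChemmineR::read.SDFset(path)
  if (length(sdfs) > 1L && is.null(record))
    stop("file contains ", length(sdfs),
         " molecules; pass `record = <index>` to select one")
  sdf <- sdfs[[if (is.null(record)) 1L else record]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(bb) || nrow(bb) == 0L)
    stop("ligand file has no bond block; explicit bonds are required")
  el <- sub("_.*$", "", rownames(ab))
  new_ligand(ab[, 1:3, drop = FALSE], el, bb[, 1:3, drop = FALSE])
}

#' Detect rotatable bonds
#'
#' A bond is rotatable iff it is a single bond, not part of a ring (a bridge
#' of the bond graph), and both end atoms have at least two heavy-atom
#' neighbours. The moving set is the smaller component left by cutting the
#' bond (ties: the side of the higher-indexed axis atom). Torsions are
#' returned ordered by their sorted atom-index pairs.
#'
#' @param ligand a `gi_ligand` (or any list with `bonds` and `graph`).
#' @return List of torsions, each `list(axis = c(i, j), moving = <indices>)`.
#' @export
detect_rotatable_bonds <- function(ligand) {
  g <- ligand$graph
  if (igraph::components(g)$no != 1L) stop("ligand bond graph is disconnected")
  bonds <- ligand$bonds
  if (nrow(bonds) == 0L) return(list())
  deg <- igraph::degree(g)
  bridge_eids <- as.integer(igraph::bridges(g))
  out <- list()
  for (b in seq_len(nrow(bonds))) {
    i <- min(bonds[b, 1:2]); j <- max(bonds[b, 1:2])
    if (bonds[b, 3] != 1L) next                       # single bonds only
    eid <- igraph::get_edge_ids(g, c(i, j))
    if (!(eid %in% bridge_eids)) next                 # in a ring
    if (deg[i] < 2L || deg[j] < 2L) next              # terminal
    g2 <- igraph::delete_edges(g, eid)
    comp <- igraph::components(g2)$membership
    side_i <- which(comp == comp[i]); side_j <- which(comp == comp[j])
    moving <- if (length(side_j) <= length(side_i)) side_j else side_i
    out[[length(out) + 1L]] <- list(axis = c(i, j), moving = as.integer(moving))
  }
  ord <- order(vapply(out, function(t) t$axis[1], numeric(1)),
               vapply(out, function(t) t$axis[2], numeric(1)))
  out[ord]
}

# ---- pose SDF output --------------------------------------------------------

SDF_ATOM_COLS <- c("C1", "C2", "C3", paste0("C", 5:16))
SDF_BOND_COLS <- c("C1", "C2", "C3", "C4")

#' Write a pose set to a multi-record SDF
#'
#' Each record carries the ligand's bond block and tagged data fields:
#' `GI_score`, `GI_vdw_att`, `GI_vdw_rep`, `GI_internal`, `GI_potential`,
#' `GI_conf_id`, `GI_iteration`, `GI_rank`. Round-trips through
#' [read_poses()] at SDF coordinate precision.
#'
#' @param poses non-empty list of `gi_pose` (or a `gi_pose_set`).
#' @param ligand the `gi_ligand` the poses instantiate.
#' @param path output path.
#' @export
write_poses <- function(poses, ligand, path) {
  if (inherits(poses, "gi_pose_set")) poses <- poses$poses
  if (length(poses) == 0L) stop("empty pose list")
  n <- nrow(ligand$coords); m <- nrow(ligand$bonds)
  bb <- matrix(0L, m, length(SDF_BOND_COLS),
               dimnames = list(seq_len(m), SDF_BOND_COLS))
  if (m > 0) bb[, 1:3] <- ligand$bonds
  recs <- vector("list", length(poses))
  for (k in seq_along(poses)) {
    p <- poses[[k]]
    if (nrow(p$coords) != n)
      stop("pose ", k, " has ", nrow(p$coords), " atoms; ligand has ", n)
    ab <- matrix(0, n, length(SDF_ATOM_COLS),
                 dimnames = list(paste0(ligand$element, "_", seq_len(n)),
                                 SDF_ATOM_COLS))
    ab[, 1:3] <- p$coords
    bd <- p$breakdown
    tags <- c(GI_score = fmt_num(p$score),
              GI_vdw_att = fmt_num(if (is.null(bd)) NA else bd$vdw_attractive),
              GI_vdw_rep = fmt_num(if (is.null(bd)) NA else bd$vdw_repulsive),
              GI_internal = fmt_num(if (is.null(bd)) NA else bd$internal),
              GI_potential = as.character(p$provenance$potential),
              GI_conf_id = as.character(p$provenance$conformation_id),
              GI_iteration = as.character(p$provenance$iteration),
              GI_rank = as.character(if (is.na(p$provenance$rank)) k else p$provenance$rank))
    h <- c(Molecule_Name = sprintf("pose_%d", k), Source = "glowives",
           Comment = "",
           Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
    recs[[k]] <- new("SDF", header = h, atomblock = ab, bondblock = bb,
                     datablock = tags)
  }
  ss <- new("SDFset", SDF = recs, ID = sprintf("pose_%d", seq_along(poses)))
  ChemmineR::write.SDF(ss, path, cid = TRUE)
  invisible(path)
}

fmt_num <- function(x) if (is.null(x) || is.na(x)) "NA" else sprintf("%.6f", x)

#' Read poses back from an SDF written by [write_poses()]
#'
#' @param path SDF path.
#' @param ligand the matching `gi_ligand` (atom-count check).
#' @return List of `gi_pose`.
#' @export
read_poses <- function(path, ligand = NULL) {
  sdfs <- ChemmineR::read.SDFset(path)
  lapply(seq_along(sdfs@SDF), function(k) {
    sdf <- sdfs[[k]]
    ab <- ChemmineR::atomblock(sdf)
    if (!is.null(ligand) && nrow(ab) != nrow(ligand$coords))
      stop("record ", k, " atom count does not match ligand")
    tags <- ChemmineR::datablock(sdf)
    gv <- function(nm, default = NA) if (nm %in% names(tags)) tags[[nm]] else default
    new_pose(ab[, 1:3, drop = FALSE],
             score = suppressWarnings(as.numeric(gv("GI_score", "0"))),
             breakdown = list(
               vdw_attractive = suppressWarnings(as.numeric(gv("GI_vdw_att"))),
               vdw_repulsive = suppressWarnings(as.numeric(gv("GI_vdw_rep"))),
               internal = suppressWarnings(as.numeric(gv("GI_internal"))),
               total = suppressWarnings(as.numeric(gv("GI_score", "0")))),
             provenance = list(potential = gv("GI_potential", "normal"),
                               conformation_id = as.integer(gv("GI_conf_id", "0")),
                               iteration = as.integer(gv("GI_iteration", "0")),
                               rank = as.integer(gv("GI_rank", k))))
  })
}
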