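#' Write an ensemble as a multi-model PDB file
#'
#' Emits one MODEL/ENDMDL block per frame with fixed-width ATOM/HETATM
#' records (HETATM for non-amino-acid residues), chain, author residue
#' numbers and the element column, so generated ensembles round-trip
#' through [loadEnsemble()] at the format's 1e-3 Angstrom precision.
#'
#' @param ensemble an [Ensemble].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEnsemblePDB <- function(ensemble, path) {
  atoms <- atomTable(ensemble)
  het <- !(atoms$resname %in% .AMINO_ACIDS)
  rec <- ifelse(het, "HETATM", "ATOM  ")
  # atom names < 4 characters start in column 14
  nm <- ifelse(nchar(atoms$name) < 4L, paste0(" ", atoms$name), atoms$name)
  con <- file(path, "w")
  on.exit(close(con))
  nf <- nFrames(ensemble)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- coords(ensemble, frame = f)
    lines <- sprintf("%s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, seq_len(nrow(atoms)), nm, "",
                     substr(atoms$resname, 1, 3), atoms$chain, atoms$resid,
                     "", xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
                     atoms$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, F = 18.998, CL = 35.45,
                   BR = 79.904, I = 126.904, NA. = 22.990, K = 39.098,
                   FE = 55.845, ZN = 65.38, MG = 24.305, CA. = 40.078)

.elementOf <- function(name, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    ok <- nzchar(e)
    if (all(ok)) return(e)
  } else e <- character(length(name))
  # fall back to the first alphabetic character of the atom name
  guess <- toupper(sub("^[0-9]*([A-Za-z]).*$", "\\1", name))
  ifelse(nzchar(e), e, guess)
}

.massOf <- function(element) {
  key <- ifelse(element %in% c("NA", "CA"), paste0(element, "."), element)
  m <- .ELEMENT_MASS[key]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Load a coordinate ensemble from standard trajectory formats
#'
#' Reads a topology (PDB; a multi-model PDB may carry the frames itself)
#' and optionally a trajectory (multi-model PDB or DCD), strips water and
#' monatomic-ion residues, applies a frame stride, and records
#' provenance.  Parsing of PDB and DCD is delegated to bio3d.
#'
#' @param topology path to a PDB file.
#' @param trajectory optional path to a multi-model PDB or DCD file
#'   holding the frames; its atom count must match the topology.
#' @param stride keep every `stride`-th frame (default 1).
#' @return an [Ensemble].
#' @export
loadEnsemble <- function(topology, trajectory = NULL, stride = 1L) {
  stopifnot(file.exists(topology))
  pdb <- bio3d::read.pdb(topology, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  element <- .elementOf(atoms$elety, atoms$elesy)
  tab <- data.frame(
    name = toupper(atoms$elety), element = element,
    mass = .massOf(element), resid = as.integer(atoms$resno),
    resname = toupper(atoms$resid),
    chain = ifelse(is.na(atoms$chain), "A", atoms$chain),
    isHeavy = element != "H", stringsAsFactors = FALSE)

  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (!is.null(trajectory)) {
    stopifnot(file.exists(trajectory))
    ext <- tolower(tools::file_ext(trajectory))
    txyz <- switch(ext,
      dcd = bio3d::read.dcd(trajectory, verbose = FALSE),
      pdb = {
        tp <- bio3d::read.pdb(trajectory, multi = TRUE, verbose = FALSE)
        m <- tp$xyz; if (!is.matrix(m)) m <- matrix(m, nrow = 1); m
      },
      stop("unsupported trajectory format '.", ext,
           "' (supported: multi-model PDB, DCD)"))
    if (ncol(txyz) != 3L * nrow(tab))
      stop("atom-count mismatch: topology has ", nrow(tab),
           " atoms but trajectory frames have ", ncol(txyz) / 3)
    xyz <- txyz
  }

  keepFrames <- seq(1L, nrow(xyz), by = as.integer(stride))
  xyz <- xyz[keepFrames, , drop = FALSE]

  keep <- !(tab$resname %in% .SOLVENT_RESNAMES)
  keepCols <- rep(keep, each = 3L)
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  xyz <- xyz[, keepCols, drop = FALSE]

  coords <- array(0, dim = c(nrow(xyz), nrow(tab), 3L))
  for (ax in 1:3) coords[, , ax] <- xyz[, seq(ax, ncol(xyz), by = 3L),
                                        drop = FALSE]
  new("Ensemble", atoms = tab, coords = coords,
      provenance = list(source = topology, trajectory = trajectory,
                        stride = as.integer(stride),
                        strippedSolvent = sum(!keep)))
}

#' Define the network nodes of an ensemble
#'
#' Every selected protein residue becomes one node represented by its
#' C-alpha; the ligand becomes one node represented by the geometric
#' centroid of its heavy atoms; coregulator-peptide residues become
#' nodes flagged `peptide-residue`.  Member sets (used for contacts) are
#' the heavy atoms of each residue/ligand.
#'
#' @param ensemble an [Ensemble].
#' @param proteinSelection selection expression for the protein residues
#'   (default `"protein"`).
#' @param ligandSelection optional selection expression for the ligand.
#' @param peptideSelection optional selection expression for a
#'   coregulator peptide.
#' @return a [NodeSet]; node order is protein residues (chain, then
#'   residue number), peptide residues, then the ligand.
#' @export
defineNodes <- function(ensemble, proteinSelection = "protein",
                        ligandSelection = NULL, peptideSelection = NULL) {
  atoms <- atomTable(ensemble)

  residueNodes <- function(sel, kind) {
    idx <- resolveSelection(ensemble, sel)
    sub <- atoms[idx, , drop = FALSE]
    key <- paste(sub$chain, sub$resid, sep = "\r")
    ord <- order(sub$chain, sub$resid)
    ukey <- unique(key[ord])
    nodes <- list(); members <- list()
    for (k in ukey) {
      rows <- idx[key == k]
      ca <- rows[atoms$name[rows] == "CA"]
      if (!length(ca))
        stop("residue ", atoms$chain[rows[1]], ":", atoms$resid[rows[1]],
             " (", atoms$resname[rows[1]], ") has no C-alpha atom")
      heavy <- rows[atoms$isHeavy[rows]]
      nodes[[k]] <- data.frame(
        kind = kind, resid = atoms$resid[rows[1]],
        resname = atoms$resname[rows[1]], chain = atoms$chain[rows[1]],
        repAtom = ca[1], stringsAsFactors = FALSE)
      members[[k]] <- heavy
    }
    list(nodes = do.call(rbind, nodes), members = unname(members))
  }

  prot <- residueNodes(proteinSelection, "residue")
  nodes <- prot$nodes; members <- prot$members
  if (!is.null(peptideSelection)) {
    pep <- residueNodes(peptideSelection, "peptide-residue")
    nodes <- rbind(nodes, pep$nodes)
    members <- c(members, pep$members)
  }
  if (!is.null(ligandSelection)) {
    lidx <- resolveSelection(ensemble, ligandSelection)
    heavy <- lidx[atoms$isHeavy[lidx]]
    if (!length(heavy))
      stop("ligand selection resolves to zero heavy atoms")
    nodes <- rbind(nodes, data.frame(
      kind = "ligand", resid = atoms$resid[heavy[1]],
      resname = atoms$resname[heavy[1]], chain = atoms$chain[heavy[1]],
      repAtom = NA_integer_, stringsAsFactors = FALSE))
    members <- c(members, list(heavy))
  }
  rownames(nodes) <- NULL
  nodes$id <- seq_len(nrow(nodes))
  nodes$label <- paste(nodes$chain, nodes$resname, nodes$resid, sep = ":")
  nodes <- nodes[c("id", "kind", "resid", "resname", "chain", "label",
                   "repAtom")]
  new("NodeSet", nodes = nodes, members = members)
}

#' Per-frame coordinates of the node representatives
#'
#' C-alpha position for residue nodes, geometric centroid of the heavy
#' members for the ligand node.
#'
#' @param ensemble an [Ensemble].
#' @param nodes a [NodeSet] defined on it.
#' @return numeric array `n_frames x n_nodes x 3`.
#' @export
nodeCoordinates <- function(ensemble, nodes) {
  xyz <- coords(ensemble)
  nf <- dim(xyz)[1]; nn <- nNodes(nodes)
  out <- array(0, dim = c(nf, nn, 3L))
  tab <- nodeTable(nodes); mem <- nodeMembers(nodes)
  for (k in seq_len(nn)) {
    if (!is.na(tab$repAtom[k])) {
      out[, k, ] <- xyz[, tab$repAtom[k], ]
    } else {
      m <- mem[[k]]
      out[, k, ] <- apply(xyz[, m, , drop = FALSE], c(1, 3), mean)
    }
  }
  out
}
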