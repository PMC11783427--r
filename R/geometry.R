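#' Per-frame pair distances
#'
#' Distance between two selections in every frame, in one of three
#' modes:
#' \describe{
#'   \item{`atom`}{both selections must resolve to a single atom.}
#'   \item{`min_heavy`}{minimum over all heavy-atom pairs; the summary
#'     then also reports the contact fraction, the fraction of frames
#'     with distance below `contactCutoff` (4.5 Angstrom, matching the
#'     network contact criterion).}
#'   \item{`com`}{distance between the mass-weighted centers of the two
#'     selections (e.g. a ligand against the center of mass of a
#'     helix).}
#' }
#'
#' @param ensemble an [Ensemble].
#' @param selA,selB selection expressions (see [resolveSelection()]).
#' @param mode `"atom"`, `"min_heavy"` or `"com"`.
#' @param contactCutoff contact threshold for the `min_heavy` summary.
#' @return a list of class `DistanceSeries`: `distances` (per frame,
#'   Angstrom), `mode`, and `summary` (`mean`, `sd`, and
#'   `contactFraction` for `min_heavy`).
#' @export
pairDistance <- function(ensemble, selA, selB,
                         mode = c("atom", "min_heavy", "com"),
                         contactCutoff = 4.5) {
  mode <- match.arg(mode)
  ia <- resolveSelection(ensemble, selA)
  ib <- resolveSelection(ensemble, selB)
  xyz <- coords(ensemble)
  atoms <- atomTable(ensemble)
  d <- switch(mode,
    atom = {
      if (length(ia) != 1L || length(ib) != 1L)
        stop("mode 'atom' requires single-atom selections (got ",
             length(ia), " and ", length(ib), ")")
      .frameDist(xyz, ia, ib)
    },
    min_heavy = {
      ha <- ia[atoms$isHeavy[ia]]; hb <- ib[atoms$isHeavy[ib]]
      if (!length(ha) || !length(hb))
        stop("selections must contain heavy atoms for mode 'min_heavy'")
      minD <- rep(Inf, dim(xyz)[1])
      for (a in ha) for (b in hb)
        minD <- pmin(minD, .frameDist(xyz, a, b))
      minD
    },
    com = {
      ca <- .centerOfMass(xyz, atoms, ia)
      cb <- .centerOfMass(xyz, atoms, ib)
      sqrt(rowSums((ca - cb)^2))
    })
  summary <- list(mean = mean(d), sd = stats::sd(d))
  if (mode == "min_heavy")
    summary$contactFraction <- mean(d < contactCutoff)
  structure(list(distances = d, mode = mode, selA = selA, selB = selB,
                 summary = summary),
            class = "DistanceSeries")
}

.atomTrack <- function(xyz, a) {
  m <- xyz[, a, , drop = FALSE]
  dim(m) <- c(dim(xyz)[1], 3L)
  m
}

.frameDist <- function(xyz, a, b) {
  sqrt((xyz[, a, 1] - xyz[, b, 1])^2 +
       (xyz[, a, 2] - xyz[, b, 2])^2 +
       (xyz[, a, 3] - xyz[, b, 3])^2)
}

.centerOfMass <- function(xyz, atoms, idx) {
  w <- atoms$mass[idx] / sum(atoms$mass[idx])
  out <- matrix(0, dim(xyz)[1], 3)
  for (ax in 1:3)
    out[, ax] <- xyz[, idx, ax, drop = FALSE][, , 1] %*% w
  out
}

#' @export
print.DistanceSeries <- function(x, ...) {
  cat(sprintf("DistanceSeries (%s): %d frames, mean %.3f A (sd %.3f)\n",
              x$mode, length(x$distances), x$summary$mean, x$summary$sd))
  if (!is.null(x$summary$contactFraction))
    cat(sprintf("  contact fraction (< cutoff): %.3f\n",
                x$summary$contactFraction))
  invisible(x)
}

#' Hydrogen-bond occupancy
#'
#' Fraction of frames satisfying the hydrogen-bond criterion:
#' donor-acceptor heavy-atom distance at most `distanceCutoff` (3.0
#' Angstrom default) and, when the hydrogen is given, donor-H-acceptor
#' angle at least `angleCutoff` (135 degrees default).  Both criteria
#' are inclusive at the boundary.  Without an explicit hydrogen the
#' criterion is distance-only (the usual situation for heavy-atom-only
#' topologies).
#'
#' @param ensemble an [Ensemble].
#' @param donor,acceptor selection expressions resolving to one heavy
#'   atom each.
#' @param hydrogen optional selection for the donor hydrogen.
#' @param distanceCutoff heavy-heavy distance cutoff (Angstrom).
#' @param angleCutoff donor-H-acceptor angle cutoff (degrees).
#' @param requireAngle set TRUE to insist on the angular criterion;
#'   an error is raised if no hydrogen is supplied (rather than silently
#'   degrading to distance-only).
#' @return occupancy in [0, 1].
#' @export
hbondOccupancy <- function(ensemble, donor, acceptor, hydrogen = NULL,
                           distanceCutoff = 3.0, angleCutoff = 135,
                           requireAngle = !is.null(hydrogen)) {
  stopifnot(distanceCutoff > 0, angleCutoff > 0, angleCutoff <= 180)
  if (requireAngle && is.null(hydrogen))
    stop("angular criterion requested but no hydrogen given; supply ",
         "'hydrogen' or use distance-only mode (requireAngle = FALSE)")
  id <- resolveSelection(ensemble, donor)
  ia <- resolveSelection(ensemble, acceptor)
  if (length(id) != 1L || length(ia) != 1L)
    stop("donor and acceptor must each resolve to a single atom")
  xyz <- coords(ensemble)
  # inclusive boundaries, with float slack so constructed fixtures that
  # sit exactly on a cutoff are counted
  ok <- .frameDist(xyz, id, ia) <= distanceCutoff + 1e-9
  if (!is.null(hydrogen)) {
    ih <- resolveSelection(ensemble, hydrogen)
    if (length(ih) != 1L)
      stop("hydrogen must resolve to a single atom")
    v1 <- .atomTrack(xyz, id) - .atomTrack(xyz, ih)   # H -> donor
    v2 <- .atomTrack(xyz, ia) - .atomTrack(xyz, ih)   # H -> acceptor
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    ok <- ok & (ang >= angleCutoff - 1e-9)
  }
  mean(ok)
}

# ring atom names by residue type (unweighted centroid convention)
.RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

#' Ring specification for an aromatic residue
#'
#' @param selection selection expression isolating one residue (e.g.
#'   `"chain A and resid 340"`).
#' @param ringAtoms atom names forming the ring; default looked up from
#'   the residue type (PHE/TYR/TRP/HIS).  At least 5 atoms.
#' @return a list of class `RingSpec`.
#' @export
ringSpec <- function(selection, ringAtoms = NULL) {
  structure(list(selection = selection, ringAtoms = ringAtoms),
            class = "RingSpec")
}

.resolveRing <- function(ensemble, spec) {
  idx <- resolveSelection(ensemble, spec$selection)
  atoms <- atomTable(ensemble)
  ringAtoms <- spec$ringAtoms
  if (is.null(ringAtoms)) {
    rn <- unique(atoms$resname[idx])
    if (length(rn) != 1L || !rn %in% names(.RING_ATOMS))
      stop("no default ring atoms for residue type '",
           paste(rn, collapse = ","), "'; give ringAtoms explicitly")
    ringAtoms <- .RING_ATOMS[[rn]]
  }
  if (length(ringAtoms) < 5L)
    stop("a ring needs at least 5 atoms")
  hit <- idx[match(ringAtoms, atoms$name[idx])]
  if (anyNA(hit))
    stop("ring atom(s) missing from '", spec$selection, "': ",
         paste(ringAtoms[is.na(hit)], collapse = ", "))
  hit
}

#' Aromatic ring-centroid distance
#'
#' Per-frame distance between the unweighted centroids of two rings
#' (e.g. the phenylalanine pair probing pi-stacking between helices 5
#' and 7).
#'
#' @param ensemble an [Ensemble].
#' @param ringA,ringB [ringSpec()] objects (bare selection strings are
#'   promoted).
#' @return a `DistanceSeries` with mode `"ring"`.
#' @export
ringDistance <- function(ensemble, ringA, ringB) {
  if (is.character(ringA)) ringA <- ringSpec(ringA)
  if (is.character(ringB)) ringB <- ringSpec(ringB)
  ia <- .resolveRing(ensemble, ringA)
  ib <- .resolveRing(ensemble, ringB)
  xyz <- coords(ensemble)
  ca <- apply(xyz[, ia, , drop = FALSE], c(1, 3), mean)
  cb <- apply(xyz[, ib, , drop = FALSE], c(1, 3), mean)
  d <- sqrt(rowSums((ca - cb)^2))
  structure(list(distances = d, mode = "ring",
                 selA = ringA$selection, selB = ringB$selection,
                 summary = list(mean = mean(d), sd = stats::sd(d))),
            class = "DistanceSeries")
}

#' Evaluate a set of named geometric panels
#'
#' Runs a panel configuration — named distance and hydrogen-bond
#' observables such as an activation-trigger distance, an interhelical
#' distance, or a side-chain hydrogen bond — over one ensemble or a list
#' of replicates, reporting per-panel replicate mean and sd.
#'
#' @param ensemble an [Ensemble] or list of replicate ensembles.
#' @param panels named list; each element is a list with `type`
#'   (`"distance"`, `"ring"` or `"hbond"`) and the arguments of
#'   [pairDistance()], [ringDistance()] or [hbondOccupancy()]
#'   respectively (`selA`/`selB`/`mode`, `ringA`/`ringB`, or
#'   `donor`/`acceptor`/...).
#' @return data.frame: `panel`, `type`, `mean`, `sd` (across replicates;
#'   for a single ensemble the within-trajectory mean and sd of the
#'   distance, or the occupancy with sd 0).
#' @export
namedPanels <- function(ensemble, panels) {
  if (!length(panels)) {
    warning("empty panel configuration")
    return(data.frame(panel = character(0), type = character(0),
                      mean = numeric(0), sd = numeric(0)))
  }
  if (is.null(names(panels)) || any(!nzchar(names(panels))))
    stop("every panel must be named")
  ensembles <- if (is(ensemble, "Ensemble")) list(ensemble) else ensemble
  rows <- lapply(names(panels), function(nm) {
    p <- panels[[nm]]
    vals <- vapply(ensembles, function(e) {
      tryCatch(switch(p$type,
        distance = pairDistance(e, p$selA, p$selB,
                                mode = if (is.null(p$mode)) "atom" else p$mode)$summary$mean,
        ring = ringDistance(e, p$ringA, p$ringB)$summary$mean,
        hbond = hbondOccupancy(e, p$donor, p$acceptor,
                               hydrogen = p$hydrogen,
                               distanceCutoff = if (is.null(p$distanceCutoff)) 3.0 else p$distanceCutoff,
                               angleCutoff = if (is.null(p$angleCutoff)) 135 else p$angleCutoff),
        stop("unknown panel type '", p$type, "'")),
        error = function(e2)
          stop("panel '", nm, "': ", conditionMessage(e2), call. = FALSE))
    }, numeric(1))
    data.frame(panel = nm, type = p$type, mean = mean(vals),
               sd = if (length(vals) > 1L) stats::sd(vals) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
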