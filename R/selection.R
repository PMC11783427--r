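#' Atom selections
#'
#' A small, deterministic selection grammar over the ensemble atom table.
#' An expression is a sequence of clauses joined by `and`; each clause is
#' a keyword followed by values:
#'
#' * `chain A B` — chain identifiers;
#' * `resid 330-340 355` — residue numbers (author/topology numbering),
#'   single values or `lo-hi` ranges;
#' * `resname PHE TYR` — residue names;
#' * `name CA CB` — atom names;
#' * `element C N O` — element symbols;
#' * bare keywords `protein` (standard amino-acid residues), `ligand`
#'   (non-amino, non-solvent residues), `heavy` (element != H), `all`.
#'
#' Resolution is purely set intersection of the clause matches.  An
#' expression that resolves to zero atoms is an error, never a silent
#' empty set.
#'
#' @param ensemble an [Ensemble] (or a bare atom table data.frame).
#' @param expr selection expression, e.g.
#'   `"chain A and resid 330-340 and name CA"`.
#' @return sorted integer vector of atom indices.
#' @examples
#' spec <- syntheticSpec(nHelices = 1, residuesPerHelix = 4, nFrames = 2)
#' ens <- sampleTrajectory(spec)
#' resolveSelection(ens, "name CA and resid 2-3")
#' @export
resolveSelection <- function(ensemble, expr) {
  atoms <- if (is(ensemble, "Ensemble")) ensemble@atoms else ensemble
  stopifnot(is.character(expr), length(expr) == 1L, nzchar(trimws(expr)))
  clauses <- strsplit(trimws(expr), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(atoms))
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    key <- tolower(toks[1])
    vals <- toks[-1]
    if (key %in% c("protein", "ligand", "heavy", "all") && length(vals))
      stop("selection keyword '", key, "' takes no values")
    if (!key %in% c("protein", "ligand", "heavy", "all") && !length(vals))
      stop("selection clause '", cl, "' has no values")
    m <- switch(key,
      chain   = atoms$chain %in% vals,
      resname = atoms$resname %in% toupper(vals),
      name    = atoms$name %in% toupper(vals),
      element = atoms$element %in% toupper(vals),
      resid   = atoms$resid %in% .parseResidValues(vals),
      protein = atoms$resname %in% .AMINO_ACIDS,
      ligand  = !(atoms$resname %in% c(.AMINO_ACIDS, .SOLVENT_RESNAMES)),
      heavy   = atoms$isHeavy,
      all     = rep(TRUE, nrow(atoms)),
      stop("unknown selection keyword: '", key, "'")
    )
    keep <- keep & m
  }
  idx <- which(keep)
  if (!length(idx))
    stop("selection '", expr, "' resolved to zero atoms")
  idx
}

.parseResidValues <- function(vals) {
  out <- integer(0)
  for (v in vals) {
    if (grepl("^-?[0-9]+--?[0-9]+$", v) && grepl("-", sub("^-", "", v))) {
      # lo-hi range (negatives allowed on the lo side only in practice)
      parts <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
      out <- c(out, seq.int(as.integer(parts[2]), as.integer(parts[3])))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else stop("cannot parse resid value '", v, "'")
  }
  out
}

.AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "HIE", "HID", "HIP", "ILE", "LEU", "LYS", "MET",
                  "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

.SOLVENT_RESNAMES <- c("HOH", "WAT", "NA+", "CL-", "NA", "CL", "K+", "K",
                       "SOD", "CLA", "TIP3")
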