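#' Validate a run configuration
#'
#' A run configuration is a named list (or a YAML file holding one)
#' describing an end-to-end analysis: the input ensembles (a
#' [syntheticSpec()], or topology + trajectory files), node selections,
#' source/sink declarations, path and contact parameters, helix
#' annotations, geometric panels, and optional variants with a
#' designated reference.  All selections are dry-resolved against the
#' topology and every problem is collected and reported together.
#'
#' Recognised fields (defaults in parentheses):
#' \describe{
#'   \item{`input`}{list with either `spec` (a [syntheticSpec()]) plus
#'     optional `replicates` (1), or `topology` / `trajectories` /
#'     `stride` file inputs.}
#'   \item{`selections`}{list: `protein` ("protein"), `ligand`
#'     ("ligand", set NULL for apo), `peptide` (NULL).}
#'   \item{`source`}{node label, or "ligand" for the ligand node.}
#'   \item{`sink`}{node label(s), or "peptide" for all peptide nodes.}
#'   \item{`paths`}{list: `delta` (100), `topK` (1000), `maxPaths` (5e6).}
#'   \item{`contact`}{list: `distanceCutoff` (4.5), `occupancyThreshold`
#'     (0.75), `neighborExclusion` (1).}
#'   \item{`wCap`}{weight cap (20).}
#'   \item{`helices`}{data.frame `name`/`start`/`end` (optional).}
#'   \item{`wells`}{list: `window` (7), `depth` (0.5).}
#'   \item{`panels`}{named list for [namedPanels()] (optional).}
#'   \item{`variants`}{named list of `input` lists; `reference` names
#'     exactly one of them when comparisons are requested.}
#' }
#'
#' @param config a named list or path to a YAML file.
#' @return the normalized configuration, classed `RunConfig`.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  errors <- character()
  note <- function(...) errors <<- c(errors, paste0(...))

  config$selections <- utils::modifyList(
    list(protein = "protein", ligand = "ligand", peptide = NULL),
    if (is.null(config$selections)) list() else config$selections)
  config$paths <- utils::modifyList(
    list(delta = 100, topK = 1000L, maxPaths = 5e6),
    if (is.null(config$paths)) list() else config$paths)
  config$contact <- utils::modifyList(
    list(distanceCutoff = 4.5, occupancyThreshold = 0.75,
         neighborExclusion = 1L),
    if (is.null(config$contact)) list() else config$contact)
  config$wells <- utils::modifyList(
    list(window = 7L, depth = 0.5),
    if (is.null(config$wells)) list() else config$wells)
  if (is.null(config$wCap)) config$wCap <- 20
  if (is.null(config$source)) config$source <- "ligand"
  if (is.null(config$sink)) note("no sink declared")

  inputs <- list(main = config$input)
  if (!is.null(config$variants)) {
    if (is.null(names(config$variants)) ||
        any(!nzchar(names(config$variants))))
      note("variants must be a named list")
    refs <- config$reference
    if (is.null(refs))
      note("variants given but no 'reference' variant designated")
    else if (length(refs) != 1L || !refs %in% names(config$variants))
      note("exactly one existing variant must be the reference (got '",
           paste(refs, collapse = ","), "')")
    inputs <- config$variants
  } else if (is.null(config$input)) {
    note("no 'input' (and no 'variants') declared")
  }

  for (nm in names(inputs)) {
    inp <- inputs[[nm]]
    if (is.null(inp)) { note("variant '", nm, "' has no input"); next }
    topo <- tryCatch(.inputTopology(inp), error = function(e) {
      note("variant '", nm, "': ", conditionMessage(e)); NULL
    })
    if (is.null(topo)) next
    for (role in c("protein", "ligand", "peptide")) {
      sel <- config$selections[[role]]
      if (is.null(sel)) next
      ok <- tryCatch({ resolveSelection(topo, sel); TRUE },
                     error = function(e) {
                       note("variant '", nm, "', ", role, " selection: ",
                            conditionMessage(e)); FALSE })
      if (!ok) next
    }
    # dry-resolve source/sink against the node labels
    nodes <- tryCatch(defineNodes(topo, config$selections$protein,
                                  config$selections$ligand,
                                  config$selections$peptide),
                      error = function(e) {
                        note("variant '", nm, "': ", conditionMessage(e))
                        NULL })
    if (!is.null(nodes) && !is.null(config$sink)) {
      for (what in list(c("source", config$source),
                        c("sink", config$sink))) {
        role <- what[1]; val <- what[-1]
        if (identical(val, "ligand") || identical(val, "peptide")) {
          if (!any(nodeTable(nodes)$kind ==
                   ifelse(val == "ligand", "ligand", "peptide-residue")))
            note("variant '", nm, "': ", role, " '", val,
                 "' but no such node exists")
        } else {
          bad <- tryCatch({ .resolveNodeId(nodeLabels(nodes), val); NULL },
                          error = function(e) conditionMessage(e))
          if (!is.null(bad))
            note("variant '", nm, "', ", role, ": ", bad)
        }
      }
    }
  }
  if (length(errors))
    stop("invalid run configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  class(config) <- c("RunConfig", "list")
  config
}

# a single-frame topology ensemble for dry resolution
.inputTopology <- function(input) {
  if (!is.null(input$spec)) return(buildMeanStructure(input$spec))
  if (!is.null(input$topology)) {
    if (!file.exists(input$topology))
      stop("topology file not found: ", input$topology)
    for (tr in input$trajectories)
      if (!file.exists(tr)) stop("trajectory file not found: ", tr)
    return(loadEnsemble(input$topology))
  }
  stop("input needs either a synthetic 'spec' or a 'topology'")
}

# the replicate ensembles of an input
.inputEnsembles <- function(input) {
  if (!is.null(input$spec)) {
    reps <- if (is.null(input$replicates)) 1L else as.integer(input$replicates)
    lapply(seq_len(reps), function(r) {
      spec <- input$spec
      spec@seed <- spec@seed + (r - 1L)
      sampleTrajectory(spec)
    })
  } else if (!is.null(input$trajectories) && length(input$trajectories)) {
    lapply(input$trajectories, function(tr)
      loadEnsemble(input$topology, tr,
                   stride = if (is.null(input$stride)) 1L else input$stride))
  } else {
    list(loadEnsemble(input$topology))
  }
}

#' Run the full communication analysis
#'
#' Orchestrates ensemble construction, per-replicate correlation and
#' contact occupancy, replicate averaging, graph construction,
#' Floyd-Warshall, bounded suboptimal path enumeration, utilization and
#' shortest-distance profiles with well detection, and geometric panels
#' — per variant, followed by percent-change tables against the
#' reference variant.  The run is deterministic for a fixed
#' configuration (all randomness lives in the synthetic specs' seeds).
#'
#' @param config a [validateRunConfig()] result (a raw list is validated
#'   first).
#' @param alignFiles superpose file-based ensembles before correlation
#'   (default TRUE; synthetic ensembles are generated aligned).
#' @return a list of class `RunReport`: `variants` (per-variant results),
#'   `comparisons` (percent changes vs the reference, only between
#'   untruncated counts), `configHash`, `reference`.
#' @export
runPipeline <- function(config, alignFiles = TRUE) {
  if (!inherits(config, "RunConfig")) config <- validateRunConfig(config)
  inputs <- if (!is.null(config$variants)) config$variants else
    list(main = config$input)

  variants <- lapply(names(inputs), function(nm) {
    .runVariant(inputs[[nm]], config, alignFiles)
  })
  names(variants) <- names(inputs)

  comparisons <- NULL
  if (!is.null(config$variants) && length(variants) > 1L) {
    ref <- variants[[config$reference]]
    comparisons <- do.call(rbind, lapply(
      setdiff(names(variants), config$reference), function(nm) {
        v <- variants[[nm]]
        refusable <- v$truncated || ref$truncated
        data.frame(
          variant = nm,
          pathCountChange = if (refusable) NA_real_ else
            compareToReference(v$pathCount, ref$pathCount),
          meanLengthChange = compareToReference(v$meanLength,
                                                ref$meanLength),
          refused = refusable, stringsAsFactors = FALSE)
      }))
  }
  structure(list(variants = variants, comparisons = comparisons,
                 reference = config$reference,
                 configHash = .configHash(unclass(config))),
            class = "RunReport")
}

.runVariant <- function(input, config, alignFiles) {
  ensembles <- .inputEnsembles(input)
  if (alignFiles)
    ensembles <- lapply(ensembles, function(e)
      if (isTRUE(e@provenance$aligned)) e else superpose(e))
  nodes <- defineNodes(ensembles[[1]], config$selections$protein,
                       config$selections$ligand, config$selections$peptide)
  tab <- nodeTable(nodes)

  corr <- averageCorrelation(
    lapply(ensembles, computeCorrelation, nodes = nodes))
  contacts <- contactMap(ensembles, nodes,
                         distanceCutoff = config$contact$distanceCutoff,
                         occupancyThreshold = config$contact$occupancyThreshold,
                         neighborExclusion = config$contact$neighborExclusion)
  graph <- buildGraph(contacts, corr, wCap = config$wCap)

  src <- if (identical(config$source, "ligand"))
    tab$id[tab$kind == "ligand"] else
    .resolveNodeId(tab$label, config$source)
  snk <- if (identical(config$sink, "peptide"))
    tab$id[tab$kind == "peptide-residue"] else
    .resolveNodeId(tab$label, config$sink)

  apd <- floydWarshall(graph)
  ps <- suboptimalPaths(graph, src, snk,
                        params = pathParams(config$paths$delta,
                                            config$paths$topK,
                                            config$paths$maxPaths),
                        apd = apd)
  stats <- pathStatistics(ps)
  util <- residueUtilization(ps, helixAnnotation = config$helices)
  prof <- shortestDistanceProfile(apd, src)
  profRes <- prof[prof$id %in% tab$id[tab$kind == "residue"] &
                  is.finite(prof$distance), , drop = FALSE]
  wells <- detectWells(profRes, window = config$wells$window,
                       depth = config$wells$depth)
  panels <- if (!is.null(config$panels))
    namedPanels(ensembles, config$panels) else NULL

  list(nNodes = nNodes(nodes), nEdges = nrow(edgeTable(graph)),
       cappedEdges = sum(edgeTable(graph)$capped),
       lOpt = stats$lOpt, pathCount = stats$countWithinCutoff,
       truncated = stats$truncated, meanLength = stats$meanLength,
       kEffective = stats$kEffective,
       utilization = util,
       helixUtilization = attr(util, "helixUtilization"),
       distanceProfile = prof, wells = wells, panels = panels)
}

# polynomial rolling hash over the serialized config: provenance tag
# embedded in reports (not cryptographic)
.configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", h)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (config ", x$configHash, ")\n", sep = "")
  for (nm in names(x$variants)) {
    v <- x$variants[[nm]]
    cat(sprintf(
      "  %s: %d nodes, %d edges, L_opt %.4f, %g paths%s, mean top-k length %.4f\n",
      nm, v$nNodes, v$nEdges, v$lOpt, v$pathCount,
      if (v$truncated) " [TRUNCATED]" else "", v$meanLength))
  }
  if (!is.null(x$comparisons)) {
    cat("  vs reference '", x$reference, "':\n", sep = "")
    for (r in seq_len(nrow(x$comparisons)))
      cat(sprintf("    %s: path count %+.1f%%, mean length %+.1f%%%s\n",
                  x$comparisons$variant[r], x$comparisons$pathCountChange[r],
                  x$comparisons$meanLengthChange[r],
                  if (x$comparisons$refused[r]) " [comparison refused: truncation]" else ""))
  }
  invisible(x)
}

#' Write a run report as JSON (plus TSV tables)
#'
#' JSON output is timestamp-free and fully determined by the
#' configuration, so two identical runs produce byte-identical files.
#'
#' @param report a [runPipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slim <- report
  for (nm in names(slim$variants)) {
    v <- slim$variants[[nm]]
    writeProfileTSV(v$utilization,
                    file.path(dir, paste0(nm, "_utilization.tsv")))
    writeProfileTSV(v$distanceProfile,
                    file.path(dir, paste0(nm, "_distance_profile.tsv")))
    v$utilization <- NULL
    v$distanceProfile <- NULL
    v$wells <- as.data.frame(v$wells)
    slim$variants[[nm]] <- v
  }
  jsonlite::write_json(unclass(slim),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
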