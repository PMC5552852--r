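## End-to-end orchestration: read structures, expand, assemble, measure,
## and emit a structured report.

#' Configuration for a full analysis run
#'
#' @param inputs named character vector of structure paths (names become
#'   report keys).
#' @param strandDefs a single strand-definition list (applied to every
#'   input) or a named list of them keyed like `inputs`.
#' @param radius expansion radius, Angstrom.
#' @param nPoints SASA sphere sample points.
#' @param contactCutoff heavy-atom contact cutoff, Angstrom.
#' @param hbondMax hydrogen-bond cutoff, Angstrom.
#' @param anchor dimer-rotation anchor subunit, `"tail"` or `"head"`.
#' @param outputDir directory for JSON/TSV output, or NULL for none.
#' @return a `dixpolConfig` list.
#' @export
analysisConfig <- function(inputs, strandDefs = defaultStrandDefs("toy"),
                           radius = 60, nPoints = 960, contactCutoff = 4.5,
                           hbondMax = 3.5, anchor = "tail",
                           outputDir = NULL) {
  if (!length(inputs)) stop("no input structures given")
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    names(inputs) <- sub("\\.[^.]+$", "", basename(inputs))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")))
  if (radius <= 0 || nPoints < 100 || contactCutoff <= 0 || hbondMax <= 0)
    stop("cutoffs must be positive (and nPoints >= 100)")
  structure(list(inputs = inputs, strandDefs = strandDefs, radius = radius,
                 nPoints = nPoints, contactCutoff = contactCutoff,
                 hbondMax = hbondMax, anchor = anchor, outputDir = outputDir),
            class = "dixpolConfig")
}

strandDefsFor <- function(config, name) {
  sd <- config$strandDefs
  if (!is.null(sd[[name]]) && is.list(sd[[name]]) && !is.null(sd[[name]]$b2))
    sd[[name]]
  else sd
}

analyzeOneStructure <- function(path, strandDefs, config) {
  structure <- readStructure(path)
  copies <- expandNeighborhood(structure, radius = config$radius)
  edges <- detectHeadToTail(copies, strandDefs, dMax = config$hbondMax)
  fm <- buildFilaments(copies, edges, strandDefs,
                       contactCutoff = config$contactCutoff)
  helix <- if (length(fm@protofilaments))
    helixParameters(fm) else NULL

  ## asymmetric-unit pairwise RMSD (CA, common residues), if >= 2 chains
  chains <- chainIds(structure)
  rmsd <- NULL
  if (length(chains) >= 2) {
    sets <- lapply(chains, function(ch) selectCoords(structure, ch))
    names(sets) <- chains
    rmsd <- averagePairwiseRmsd(sets)
  }

  ## head-to-tail interface: mean BSA over unique consecutive pairs of the
  ## longest protofilament, both conventions reported
  iface <- NULL
  if (!is.null(helix) && length(fm@protofilaments)) {
    main <- fm@protofilaments[[which.max(lengths(fm@protofilaments))]]
    tot <- c(); per <- c()
    inv <- NULL
    nPairs <- min(length(main) - 1, 3)  # interfaces repeat by symmetry
    for (k in seq_len(nPairs)) {
      rep <- interfaceFingerprint(fm@copies[[main[k]]], fm@copies[[main[k + 1]]],
                                  strandDefs, waterAtoms = structure@waters,
                                  nPoints = config$nPoints)
      tot <- c(tot, rep@bsaTotal)
      per <- c(per, mean(rep@bsaPerSide))
      if (is.null(inv)) inv <- rep@contacts
    }
    iface <- list(bsa_mean_two_side_sum = mean(tot),
                  bsa_mean_per_side = mean(per),
                  n_pairs_averaged = nPairs,
                  first_pair_contacts = inv)
  }

  ## inter-filament (type II) interface summary for double architectures
  typeII <- NULL
  if (fm@architecture == "double") {
    e <- fm@interfilamentEdges
    sel <- which(e$kind == "interfilament_typeII")
    if (length(sel)) {
      tot <- vapply(utils::head(sel, 3), function(i) {
        interfaceFingerprint(fm@copies[[e$a[i]]], fm@copies[[e$b[i]]],
                             strandDefs, kind = "interfilament",
                             nPoints = config$nPoints)@bsaTotal
      }, numeric(1))
      typeII <- list(bsa_mean_two_side_sum = mean(tot),
                     n_pairs_averaged = length(tot))
    }
  }

  list(path = path, structure = structure, filament = fm,
       helix = helix, rmsd = rmsd, headToTail = iface, typeII = typeII)
}

helixAsList <- function(h) {
  if (is.null(h)) return(NULL)
  list(rise = h@rise, twist = h@twist, pitch = h@pitch,
       subunits_per_turn = h@subunitsPerTurn, handedness = h@handedness,
       n_pairs_averaged = h@nPairsAveraged)
}

#' Run the full helical-polymer analysis
#'
#' For every input structure: read, expand the crystallographic
#' neighborhood, detect head-to-tail beta bridges, assemble protofilaments,
#' classify the architecture, measure helix parameters, the
#' asymmetric-unit pairwise RMSD, and the head-to-tail (and, for double
#' filaments, type II inter-filament) interface areas.  When exactly two
#' inputs are given, the head-to-tail dimers of the two structures are
#' also compared (residual dimer rotation, both anchors reported).
#'
#' Output is deterministic given the config and inputs; when
#' `config$outputDir` is set, a JSON report (floats fixed to 4 decimals)
#' and a TSV summary are written.
#'
#' @param config an [analysisConfig()].
#' @return the report list (invisibly contains full objects under
#'   `details`).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "dixpolConfig"))
    stop("config must come from analysisConfig()")
  results <- list()
  for (name in names(config$inputs)) {
    sd <- strandDefsFor(config, name)
    res <- tryCatch(
      analyzeOneStructure(config$inputs[[name]], sd, config),
      error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
    results[[name]] <- res
  }

  report <- list(schema = "dixpol-report-1",
                 structures = lapply(results, function(r) {
    list(architecture = r$filament@architecture,
         n_protofilaments = length(r$filament@protofilaments),
         helix = helixAsList(r$helix),
         asu_rmsd_mean = if (is.null(r$rmsd)) NULL else r$rmsd$mean,
         head_to_tail_interface = if (is.null(r$headToTail)) NULL else
           r$headToTail[c("bsa_mean_two_side_sum", "bsa_mean_per_side",
                          "n_pairs_averaged")],
         type_II_interface = r$typeII)
  }))

  ## cross-structure dimer comparison for exactly two inputs
  if (length(results) == 2) {
    dimers <- lapply(results, function(r) {
      fm <- r$filament
      if (!length(fm@protofilaments)) return(NULL)
      main <- fm@protofilaments[[which.max(lengths(fm@protofilaments))]]
      list(tail = placedCoords(fm@copies[[main[1]]]),
           head = placedCoords(fm@copies[[main[2]]]))
    })
    if (!any(vapply(dimers, is.null, logical(1)))) {
      report$dimer_rotation_difference_deg <- list(
        tail_anchor = dimerRotationDifference(dimers[[1]], dimers[[2]],
                                              anchor = "tail"),
        head_anchor = dimerRotationDifference(dimers[[1]], dimers[[2]],
                                              anchor = "head"),
        default_anchor = config$anchor)
    }
  }

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report,
                         file.path(config$outputDir, "report.json"),
                         auto_unbox = TRUE, digits = 4, pretty = TRUE,
                         null = "null")
    tsv <- do.call(rbind, lapply(names(report$structures), function(n) {
      s <- report$structures[[n]]
      data.frame(structure = n, architecture = s$architecture,
                 rise = if (is.null(s$helix)) NA else s$helix$rise,
                 twist = if (is.null(s$helix)) NA else s$helix$twist,
                 pitch = if (is.null(s$helix)) NA else s$helix$pitch,
                 subunits_per_turn = if (is.null(s$helix)) NA else
                   s$helix$subunits_per_turn,
                 handedness = if (is.null(s$helix)) NA else s$helix$handedness,
                 asu_rmsd_mean = if (is.null(s$asu_rmsd_mean)) NA else
                   s$asu_rmsd_mean,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(tsv, file.path(config$outputDir, "report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report$details <- results
  invisible(report)
}
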