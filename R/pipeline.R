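#' Run the full island detection and typing pipeline
#'
#' For every genome: locate the flaA2/flaG anchors, excise the intergenic
#' island, compute its G+C metrics, annotate its CDSs against the
#' labelled reference set and call FGI status.  Island proteins of the
#' FGI-positive strains are then clustered into ortholog families, scored
#' into the binary presence/absence matrix (truncated and
#' transposon-disrupted members score 0), converted to a Pearson
#' similarity matrix, clustered by UPGMA, and typed at the similarity
#' cutoff.  Strains whose anchors cannot be located are excluded with a
#' warning and listed in the result.
#'
#' @param genomes list of [Genome-class] objects, or a character vector
#'   of GenBank file paths (at least two genomes).
#' @param anchors an [AnchorSet-class].
#' @param refdb labelled reference \link[Biostrings]{AAStringSet}.
#' @param thresholds an [FgiThresholds-class].
#' @param outDir optional directory for the CSV/TSV/Newick artifacts and
#'   a per-stage log.
#' @param prefilter use the shared-k-mer alignment prefilter (see
#'   [clusterOrthologs()]).
#' @return an [FgiCohortResult-class].
#' @seealso [generateCohort()], [summarizeIslands()]
#' @export
runPipeline <- function(genomes, anchors = defaultAnchorSet(),
                        refdb = defaultReferenceDb(),
                        thresholds = fgiThresholds(), outDir = NULL,
                        prefilter = TRUE) {
  if (is.character(genomes))
    genomes <- lapply(genomes, readGenome)
  if (length(genomes) < 2L)
    stop("runPipeline: need at least two genomes")
  names(genomes) <- vapply(genomes, strainId, "")

  records <- list()
  failures <- character()
  for (sid in names(genomes)) {
    rec <- tryCatch({
      pair <- findAnchors(genomes[[sid]], anchors, thresholds)
      isl <- extractIsland(genomes[[sid]], pair$flaA2, pair$flaG)
      classifyIsland(annotateIsland(isl, refdb, thresholds, prefilter))
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      warning("excluding strain ", sid, ": ", conditionMessage(rec))
      failures[sid] <- conditionMessage(rec)
    } else {
      records[[sid]] <- rec
    }
  }
  if (length(records) < 1L)
    stop("runPipeline: anchor detection failed for every genome")

  plus <- names(records)[vapply(records, fgiStatus, "") == "FGI+"]
  families <- list(); pam <- NULL; typing <- NULL
  typeLabels <- stats::setNames(rep(NA_character_, length(records)),
                                names(records))
  if (length(plus) >= 1L) {
    prots <- lapply(records[plus], islandProteins)
    prots <- lapply(prots, function(p) p[nchar(as.character(p)) > 0L])
    families <- clusterOrthologs(prots, thresholds, prefilter)
    disrupted <- unlist(lapply(records[plus], .disrupted_ids),
                        use.names = FALSE)
    pam <- scoreMatrix(families, sort(plus), thresholds@truncationFrac,
                       disrupted)
    if (length(plus) >= 2L && length(families)) {
      sim <- pearsonSimilarity(pam)
      tree <- upgma(sim)
      typing <- assignTypes(tree, thresholds@typeCutoffPct, sim)
      typeLabels[names(typeOf(typing))] <- typeOf(typing)
    } else {
      typeLabels[plus] <- "I"  # degenerate single-strain cohort
    }
  }

  table <- data.frame(
    strain_id = names(records),
    isolation_source = "",
    fgi_type = unname(typeLabels[names(records)]),
    genome_gc_pct = round(vapply(records, function(r) r@genomeGC, 0), 2),
    island_gc_pct = round(vapply(records, function(r) r@islandGC, 0), 2),
    gc_deviation_pct = round(vapply(records, function(r) r@gcDeviation, 0),
                             2),
    size_kb = round(vapply(records, function(r) r@sizeKb, 0), 1),
    n_cds = vapply(records, function(r) r@nCds, 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  summary <- summarizeIslands(table)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeIslandTable(table, file.path(outDir, "island_metrics.csv"))
    if (!is.null(pam))
      writePresenceAbsence(pam, file.path(outDir, "presence_absence.csv"),
                           file.path(outDir, "presence_absence_long.tsv"))
    if (!is.null(typing)) {
      writeNewick(typing@tree, file.path(outDir, "typing_upgma.nwk"))
      utils::write.table(
        data.frame(strain_id = names(typeOf(typing)),
                   fgi_type = unname(typeOf(typing))),
        file.path(outDir, "typing.tsv"), sep = "\t", row.names = FALSE,
        quote = FALSE)
    }
    writeLines(c(
      sprintf("genomes supplied: %d", length(genomes)),
      sprintf("anchor failures: %d%s", length(failures),
              if (length(failures))
                paste0(" (", paste(names(failures), collapse = ", "), ")")
              else ""),
      sprintf("islands extracted: %d", length(records)),
      sprintf("FGI+: %d  FGI-: %d", summary@nFgiPlus, summary@nFgiMinus),
      sprintf("ortholog families: %d", length(families)),
      sprintf("types at %g%% cutoff: %d", thresholds@typeCutoffPct,
              summary@nTypes)),
      file.path(outDir, "pipeline_log.txt"))
  }

  new("FgiCohortResult", records = records, table = table,
      families = families, pam = pam, typing = typing, summary = summary,
      failures = failures)
}

## feature ids of island CDSs suspected transposon-disrupted: immediately
## adjacent to a transposase-annotated CDS.  scoreMatrix only treats a
## flagged member as disrupted when it is also shorter than its family
## median, so intact genes that merely neighbour a mobile element are
## unaffected.
.disrupted_ids <- function(record) {
  ann <- record@annotations
  if (!length(ann)) return(character())
  ord <- order(start(record@cds))
  ids <- mcols(record@cds)$feature_id[ord]
  lab <- unname(ann[ids])
  isTnp <- lab == "transposase"
  neighbourTnp <- (c(FALSE, isTnp[-length(isTnp)]) |
                     c(isTnp[-1], FALSE))
  ids[!isTnp & neighbourTnp]
}

#' Aggregate a per-strain island metrics table
#'
#' Groups strains by FGI status (a missing type means FGI-negative),
#' computes arithmetic means of the island G+C and of the absolute G+C
#' deviation per group, size and CDS-count ranges per group, and
#' per-type strain counts.  Percentages are rounded to two decimals and
#' sizes to one for reporting.
#'
#' @param rows data.frame in the island table schema (see
#'   [loadIslandTable()]).
#' @return a [CohortSummary-class].
#' @examples
#' tab <- loadIslandTable(system.file("extdata",
#'   "island_metrics_table.csv", package = "fgiTyper"))
#' summarizeIslands(tab)
#' @export
summarizeIslands <- function(rows) {
  stopifnot(nrow(rows) >= 1L)
  isPlus <- !is.na(rows$fgi_type)
  groupRow <- function(sel, name) {
    if (!any(sel))
      return(data.frame(group = name, n = 0L, mean_island_gc_pct = NA_real_,
                        mean_abs_gc_deviation_pct = NA_real_,
                        min_size_kb = NA_real_, max_size_kb = NA_real_,
                        min_n_cds = NA_integer_, max_n_cds = NA_integer_))
    data.frame(
      group = name, n = sum(sel),
      mean_island_gc_pct = round(mean(rows$island_gc_pct[sel],
                                      na.rm = TRUE), 2),
      mean_abs_gc_deviation_pct = round(mean(abs(rows$gc_deviation_pct[sel]),
                                             na.rm = TRUE), 2),
      min_size_kb = round(min(rows$size_kb[sel]), 1),
      max_size_kb = round(max(rows$size_kb[sel]), 1),
      min_n_cds = min(rows$n_cds[sel]),
      max_n_cds = max(rows$n_cds[sel]))
  }
  stats_ <- rbind(groupRow(isPlus, "FGI+"), groupRow(!isPlus, "FGI-"))
  counts <- table(rows$fgi_type[isPlus])
  typeCounts <- stats::setNames(as.integer(counts), names(counts))
  new("CohortSummary",
      nStrains = nrow(rows), nFgiPlus = sum(isPlus),
      nFgiMinus = sum(!isPlus), nTypes = length(typeCounts),
      typeCounts = typeCounts, groupStats = stats_, notes = character())
}
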