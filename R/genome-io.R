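#' G+C content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T), case-insensitive.  IUPAC ambiguity
#' codes (including N) and gap characters are excluded from both the
#' numerator and the denominator, so draft-assembly ambiguity does not
#' bias the estimate.
#'
#' @param seq a character string, \link[Biostrings]{DNAString} or
#'   \link[Biostrings]{DNAStringSet} (a set is treated as concatenated).
#' @return G+C fraction in [0, 1].
#' @examples
#' gcContent("GCGC")   # 1
#' gcContent("ATGNN")  # 1/3: the Ns are excluded
#' @export
gcContent <- function(seq) {
  if (is(seq, "DNAStringSet")) seq <- unlist(seq)
  if (!is(seq, "XString")) {
    s <- toupper(as.character(seq))
    if (length(s) != 1L || is.na(s) || !nzchar(s))
      stop("gcContent: empty sequence")
    seq <- tryCatch(Biostrings::DNAString(s), error = function(e) s)
  }
  if (is(seq, "XString")) {
    if (length(seq) == 0L) stop("gcContent: empty sequence")
    counts <- as.list(Biostrings::letterFrequency(seq, c("A", "C", "G", "T")))
  } else {
    tab <- table(strsplit(seq, "", fixed = TRUE)[[1]])
    counts <- vapply(c("A", "C", "G", "T"), function(b)
      if (b %in% names(tab)) as.numeric(tab[[b]]) else 0, 0)
  }
  gc <- counts[["G"]] + counts[["C"]]
  at <- counts[["A"]] + counts[["T"]]
  if (gc + at == 0)
    stop("gcContent: sequence has no unambiguous bases; content undefined")
  gc / (gc + at)
}

#' Construct a Genome object
#'
#' Features are sorted by (contig, start); the genome G+C cache is
#' computed from the contigs.
#'
#' @param strainId strain identifier.
#' @param contigs named \link[Biostrings]{DNAStringSet} (or named character
#'   vector) of contig sequences.
#' @param features \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{feature_id}, \code{type}, \code{gene}, \code{product},
#'   \code{protein}.
#' @return a [Genome-class].
#' @export
Genome <- function(strainId, contigs, features = GRanges()) {
  if (!is(contigs, "DNAStringSet")) contigs <- DNAStringSet(contigs)
  if (length(features)) {
    ord <- order(as.character(seqnames(features)), start(features))
    features <- features[ord]
  } else if (!ncol(mcols(features))) {
    mcols(features) <- DataFrame(feature_id = character(),
                                 type = character(), gene = character(),
                                 product = character(), protein = character())
  }
  gc <- 100 * gcContent(unlist(contigs))
  new("Genome", strainId = strainId, contigs = contigs,
      features = features, genomeGC = gc)
}

## bacterial translation (code table 11; standard code apart from start
## codons, which do not matter for internal translation of annotated CDSs)
.translate_cds <- function(dna) {
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(dna),
                          if.fuzzy.codon = "X")))
  aa <- sub("\\*$", "", aa)  # strip the stop codon
  aa
}

.feature_mcols <- function(feature_id, gene, product, protein, type = "CDS") {
  DataFrame(feature_id = feature_id, type = type, gene = gene,
            product = product, protein = protein)
}

## extract CDS nucleotide sequence honouring strand
.cds_dna <- function(contigSeq, start, end, strand) {
  s <- Biostrings::subseq(contigSeq, start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# ---------------------------------------------------------------------------
# GenBank flat files.  No installed package parses the flat-file dialect
# offline, so a minimal reader/writer for single-interval (optionally
# complemented) features is provided here.  join() locations collapse to
# their span with a warning.
# ---------------------------------------------------------------------------

.parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    warning("join() location collapsed to its span: ", loc)
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",")[[1]]
    nums <- as.integer(unlist(regmatches(parts, gregexpr("[0-9]+", parts))))
    return(list(start = min(nums), end = max(nums), strand = strand))
  }
  m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
  if (length(m) != 3L) stop("cannot parse GenBank location: ", loc)
  list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand)
}

.parse_gb_record <- function(lines, path, recno) {
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus))
    stop("format error in ", path, " (record ", recno, "): missing LOCUS")
  contig_id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  def <- grep("^DEFINITION", lines, value = TRUE)
  definition <- if (length(def))
    trimws(sub("^DEFINITION", "", def[1])) else NA_character_
  oi <- grep("^ORIGIN", lines)
  if (!length(oi))
    stop("format error in ", path, " (record ", recno,
         ", contig ", contig_id, "): missing ORIGIN")
  seqlines <- lines[(oi[1] + 1):length(lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (!nzchar(seq))
    stop("format error in ", path, " (record ", recno, "): empty sequence")

  fi <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fi)) {
    block <- lines[(fi[1] + 1):(oi[1] - 1)]
    ## feature starts: key in column 6 (5 leading spaces, non-space at 6)
    starts <- grep("^ {5}\\S", block)
    for (k in seq_along(starts)) {
      from <- starts[k]
      to <- if (k < length(starts)) starts[k + 1] - 1 else length(block)
      fl <- block[from:to]
      key <- sub("^ {5}(\\S+).*", "\\1", fl[1])
      loc <- trimws(sub("^ {5}\\S+\\s*", "", fl[1]))
      ## location may continue over lines until the first qualifier
      qstart <- grep("^\\s+/", fl)
      locEnd <- if (length(qstart)) qstart[1] - 1 else length(fl)
      if (locEnd > 1)
        loc <- paste0(loc, paste(trimws(fl[2:locEnd]), collapse = ""))
      quals <- list()
      if (length(qstart)) {
        qlines <- fl[qstart[1]:length(fl)]
        qi <- grep("^\\s+/", qlines)
        for (m in seq_along(qi)) {
          qfrom <- qi[m]
          qto <- if (m < length(qi)) qi[m + 1] - 1 else length(qlines)
          qtxt <- paste(trimws(qlines[qfrom:qto]), collapse = "")
          qname <- sub("^/([^=]+)=?.*$", "\\1", qtxt)
          qval <- if (grepl("=", qtxt))
            gsub("\"", "", sub("^/[^=]+=", "", qtxt)) else TRUE
          quals[[qname]] <- qval
        }
      }
      feats[[length(feats) + 1]] <- list(key = key, loc = loc, quals = quals)
    }
  }
  list(contig_id = contig_id, definition = definition, seq = seq,
       features = feats)
}

#' Read an annotated genome
#'
#' Reads a GenBank flat file (possibly multi-record for draft assemblies)
#' or a FASTA + GFF3 pair into a [Genome-class].  Every CDS gets its
#' protein sequence: from the \code{/translation} qualifier when present,
#' otherwise by translating the spliced CDS sequence with the bacterial
#' code (table 11, stop codon stripped).  A CDS without a usable
#' translation (internal stop) is kept with an empty protein and a
#' warning.
#'
#' @param path GenBank file, or genome FASTA when \code{format = "gff3"}.
#' @param format \code{"genbank"} or \code{"gff3"}.
#' @param gff GFF3 annotation path (required for \code{format = "gff3"}).
#' @param strainId strain identifier; defaults to the GenBank DEFINITION
#'   line, or the file name without extension.
#' @return a [Genome-class] with features sorted by (contig, start).
#' @seealso [writeGenBank()], [gcContent()]
#' @export
readGenome <- function(path, format = c("genbank", "gff3"), gff = NULL,
                       strainId = NULL) {
  format <- match.arg(format)
  if (format == "genbank") .read_genbank(path, strainId)
  else .read_fasta_gff3(path, gff, strainId)
}

.read_genbank <- function(path, strainId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//\\s*$", lines)
  if (!length(ends))
    stop("format error in ", path,
         ": no record terminator '//' (truncated file?)")
  if (max(grep("^LOCUS", lines)) > max(ends))
    stop("format error in ", path, ": truncated final record")
  begins <- c(1L, head(ends, -1L) + 1L)
  contigSeqs <- character()
  featList <- list()
  definition <- NA_character_
  for (r in seq_along(ends)) {
    rec <- .parse_gb_record(lines[begins[r]:(ends[r] - 1L)], path, r)
    if (is.na(definition)) definition <- rec$definition
    contigSeqs[rec$contig_id] <- rec$seq
    for (f in rec$features) {
      if (f$key != "CDS") next
      loc <- .parse_gb_location(f$loc)
      if (loc$end > nchar(rec$seq))
        stop("format error in ", path, ": CDS beyond contig end (",
             rec$contig_id, ":", f$loc, ")")
      q <- f$quals
      prot <- if (!is.null(q$translation)) q$translation else {
        dna <- .cds_dna(Biostrings::DNAString(rec$seq), loc$start, loc$end,
                        loc$strand)
        aa <- .translate_cds(dna)
        if (grepl("\\*", aa)) {
          warning("CDS with internal stop kept with empty protein: ",
                  rec$contig_id, ":", f$loc)
          aa <- ""
        }
        aa
      }
      fid <- if (!is.null(q$locus_tag)) q$locus_tag else
        paste0(rec$contig_id, "_", loc$start)
      featList[[length(featList) + 1]] <- list(
        contig = rec$contig_id, start = loc$start, end = loc$end,
        strand = loc$strand, feature_id = fid,
        gene = if (!is.null(q$gene)) q$gene else "",
        product = if (!is.null(q$product)) q$product else "",
        protein = prot)
    }
  }
  gr <- .features_granges(featList)
  if (is.null(strainId))
    strainId <- if (!is.na(definition) && nzchar(definition)) definition else
      sub("\\.[^.]*$", "", basename(path))
  Genome(strainId, DNAStringSet(contigSeqs), gr)
}

.features_granges <- function(featList) {
  if (!length(featList)) {
    gr <- GRanges()
    mcols(gr) <- .feature_mcols(character(), character(), character(),
                                character(), character())
    return(gr)
  }
  gr <- GRanges(
    seqnames = vapply(featList, `[[`, "", "contig"),
    ranges = IRanges(vapply(featList, `[[`, 0L, "start"),
                     vapply(featList, `[[`, 0L, "end")),
    strand = vapply(featList, `[[`, "", "strand"))
  mcols(gr) <- .feature_mcols(
    vapply(featList, `[[`, "", "feature_id"),
    vapply(featList, `[[`, "", "gene"),
    vapply(featList, `[[`, "", "product"),
    vapply(featList, `[[`, "", "protein"))
  gr
}

.read_fasta_gff3 <- function(path, gff, strainId = NULL) {
  if (is.null(gff)) stop("format 'gff3' needs both a FASTA and a GFF3 path")
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(gff)) stop("no such file: ", gff)
  contigs <- Biostrings::readDNAStringSet(path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  ann <- rtracklayer::import(gff)
  cds <- ann[ann$type == "CDS"]
  featList <- lapply(seq_along(cds), function(i) {
    x <- cds[i]
    ctg <- as.character(seqnames(x))
    if (!ctg %in% names(contigs))
      stop("GFF3 contig not in FASTA: ", ctg)
    strnd <- as.character(strand(x))
    if (!strnd %in% c("+", "-")) strnd <- "+"
    dna <- .cds_dna(contigs[[ctg]], start(x), end(x), strnd)
    aa <- .translate_cds(dna)
    if (grepl("\\*", aa)) {
      warning("CDS with internal stop kept with empty protein: ",
              ctg, ":", start(x), "-", end(x))
      aa <- ""
    }
    id <- if (!is.null(x$ID) && !is.na(x$ID)) as.character(x$ID) else
      paste0(ctg, "_", start(x))
    gene <- if (!is.null(x$gene) && length(x$gene) && !is.na(x$gene[1]))
      as.character(x$gene[1]) else ""
    prod <- if (!is.null(x$product) && length(x$product) &&
                !is.na(x$product[1])) as.character(x$product[1]) else ""
    list(contig = ctg, start = start(x), end = end(x), strand = strnd,
         feature_id = id, gene = gene, product = prod, protein = aa)
  })
  if (is.null(strainId)) strainId <- sub("\\.[^.]*$", "", basename(path))
  Genome(strainId, contigs, .features_granges(featList))
}

.wrap_qualifier <- function(name, value, width = 58) {
  txt <- paste0("/", name, "=\"", value, "\"")
  starts <- seq(1, nchar(txt), by = width)
  paste0("                     ",
         substring(txt, starts, pmin(starts + width - 1, nchar(txt))))
}

#' Write a genome as a GenBank flat file
#'
#' One record per contig; CDS features carry \code{/locus_tag},
#' \code{/gene}, \code{/product} and \code{/translation} qualifiers and
#' round-trip through [readGenome()].
#'
#' @param genome a [Genome-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGenBank <- function(genome, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  ft <- genome@features
  for (ctg in names(genome@contigs)) {
    seq <- as.character(genome@contigs[[ctg]])
    n <- nchar(seq)
    cat(sprintf("LOCUS       %s %d bp    DNA     linear   BCT\n", ctg, n),
        file = con)
    cat("DEFINITION  ", genome@strainId, "\n", sep = "", file = con)
    cat("FEATURES             Location/Qualifiers\n", file = con)
    cat(sprintf("     source          1..%d\n", n), file = con)
    sel <- ft[as.character(seqnames(ft)) == ctg]
    for (i in seq_along(sel)) {
      x <- sel[i]
      loc <- sprintf("%d..%d", start(x), end(x))
      if (as.character(strand(x)) == "-")
        loc <- sprintf("complement(%s)", loc)
      key <- mcols(x)$type
      cat(sprintf("     %-15s %s\n", key, loc), file = con)
      cat(sprintf("                     /locus_tag=\"%s\"\n",
                  mcols(x)$feature_id), file = con)
      if (nzchar(mcols(x)$gene))
        cat(sprintf("                     /gene=\"%s\"\n", mcols(x)$gene),
            file = con)
      if (nzchar(mcols(x)$product))
        cat(sprintf("                     /product=\"%s\"\n",
                    mcols(x)$product), file = con)
      if (key == "CDS" && nzchar(mcols(x)$protein))
        writeLines(.wrap_qualifier("translation", mcols(x)$protein), con)
    }
    cat("ORIGIN\n", file = con)
    pos <- seq(1, n, by = 60)
    for (p in pos) {
      starts <- seq(p, min(p + 59, n), by = 10)
      chunk <- substring(seq, starts, pmin(starts + 9, n))
      cat(sprintf("%9d %s\n", p, tolower(paste(chunk, collapse = " "))),
          file = con)
    }
    cat("//\n", file = con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Island metrics table (the per-strain Table-1-style CSV)
# ---------------------------------------------------------------------------

.island_table_cols <- c("strain_id", "isolation_source", "fgi_type",
                        "genome_gc_pct", "island_gc_pct", "gc_deviation_pct",
                        "size_kb", "n_cds")

#' Load a per-strain island metrics table
#'
#' Reads the CSV schema \code{strain_id, isolation_source, fgi_type,
#' genome_gc_pct, island_gc_pct, gc_deviation_pct, size_kb, n_cds}.
#' FGI-negative strains carry \code{"-"} in \code{fgi_type}, which is
#' parsed to \code{NA}.  Each row is validated against the invariant
#' \code{gc_deviation_pct == island_gc_pct - genome_gc_pct} within 0.02
#' percentage points (the slack that two-decimal rounding can introduce).
#'
#' The packaged fixture
#' \code{system.file("extdata", "island_metrics_table.csv",
#' package = "fgiTyper")} holds the per-strain island metrics of a 36-strain
#' \emph{Geobacillus} genomes.
#'
#' @param path CSV file.
#' @return data.frame with one row per strain; \code{fgi_type} is
#'   \code{NA} for FGI-negative strains.
#' @seealso [writeIslandTable()], [summarizeIslands()]
#' @export
loadIslandTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), .island_table_cols))
    stop("island table header mismatch; expected: ",
         paste(.island_table_cols, collapse = ","))
  df$fgi_type[df$fgi_type %in% c("-", "")] <- NA_character_
  bad <- !is.na(df$island_gc_pct) &
    abs(df$gc_deviation_pct - (df$island_gc_pct - df$genome_gc_pct)) >
      0.02 + 1e-9
  if (any(bad))
    stop("gc deviation inconsistent with island - genome G+C for strain(s): ",
         paste(df$strain_id[bad], collapse = ", "))
  df
}

#' Write a per-strain island metrics table
#'
#' Percentages are written with two decimals and sizes with one, the
#' reporting precision used throughout; FGI-negative strains are written
#' with \code{"-"} in \code{fgi_type}.  Reading the file back with
#' [loadIslandTable()] reproduces the rows.
#'
#' @param rows data.frame in the island table schema.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
writeIslandTable <- function(rows, path) {
  stopifnot(all(.island_table_cols %in% names(rows)))
  out <- rows[, .island_table_cols, drop = FALSE]
  out$fgi_type[is.na(out$fgi_type)] <- "-"
  for (cn in c("genome_gc_pct", "island_gc_pct", "gc_deviation_pct"))
    out[[cn]] <- ifelse(is.na(out[[cn]]), "", sprintf("%.2f", out[[cn]]))
  out$size_kb <- sprintf("%.1f", out$size_kb)
  ok <- try(utils::write.csv(out, path, row.names = FALSE, quote = TRUE),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write to ", path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Protein FASTA and the labelled reference database (`>name|label`)
# ---------------------------------------------------------------------------

#' Write proteins to FASTA
#'
#' Empty sequences are skipped with a warning.
#'
#' @param proteins named \link[Biostrings]{AAStringSet} or named character
#'   vector.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeProteinFasta <- function(proteins, path) {
  if (!is(proteins, "AAStringSet")) proteins <- AAStringSet(proteins)
  empty <- width(proteins) == 0L
  if (any(empty)) {
    warning("skipping ", sum(empty), " empty protein(s): ",
            paste(names(proteins)[empty], collapse = ", "))
    proteins <- proteins[!empty]
  }
  Biostrings::writeXStringSet(proteins, path)
  invisible(path)
}

#' Read a labelled reference protein database
#'
#' FASTA with header syntax \code{>name|label}; the label vocabulary used
#' by the pipeline is \code{glycosyltransferase}, \code{maf},
#' \code{flagellin}, \code{biosynthesis:<pathway>},
#' \code{modification:<class>}, \code{endonuclease}, \code{transposase}
#' and \code{hypothetical}.
#'
#' @param path FASTA file.
#' @return \link[Biostrings]{AAStringSet} named by entry name, with a
#'   \code{label} metadata column.
#' @seealso [defaultReferenceDb()], [annotateIsland()]
#' @export
readReferenceDb <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(sub("\\s.*$", "", names(aa)), "|", fixed = TRUE)
  names(aa) <- vapply(parts, `[`, "", 1L)
  mcols(aa)$label <- vapply(parts, function(p)
    if (length(p) >= 2L) p[2] else "hypothetical", "")
  aa
}

#' @rdname readReferenceDb
#' @param refdb labelled \link[Biostrings]{AAStringSet} (as returned by
#'   [readReferenceDb()] or [defaultReferenceDb()]).
#' @export
writeReferenceDb <- function(refdb, path) {
  out <- refdb
  names(out) <- paste0(names(refdb), "|", mcols(refdb)$label)
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}
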