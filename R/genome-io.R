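#' @include AllClasses.R
#' @importFrom Biostrings readDNAStringSet
#' @importFrom rtracklayer import export
#' @importFrom utils write.table read.delim
NULL

## GFF3 / GenBank feature types mapped to the four region categories.
.categoryForType <- function(type) {
  type <- as.character(type)
  out <- rep(NA_character_, length(type))
  out[type == "CDS"] <- "protein_coding"
  out[type == "tRNA"] <- "tRNA"
  out[type == "rRNA"] <- "rRNA"
  other <- is.na(out) & grepl("RNA$", type) & type != "mRNA"
  out[other] <- "other_RNA"
  out
}

.gffTypeForCategory <- function(category) {
  c(protein_coding = "CDS", tRNA = "tRNA", rRNA = "rRNA",
    other_RNA = "ncRNA")[as.character(category)]
}

#' Construct a GenomeRecord
#'
#' Coordinates are 1-based inclusive.  The sequence is uppercased; non-ACGT
#' symbols are kept (triplet windows containing them are later skipped in
#' counting).  Regions spanning the origin of a circular record must already
#' be split; \code{\link{readGenome}} does this for GenBank joins.
#'
#' @param id identifier string.
#' @param sequence character or \code{DNAString}.
#' @param regions \code{GRanges} with strand and a \code{category} column,
#'   or a data.frame with columns start, end, strand
#'   ("forward"/"backward" or "+"/"-") and category.
#' @param isCircular logical.
#' @return a \linkS4class{GenomeRecord}.
#' @export
GenomeRecord <- function(id, sequence, regions = NULL, isCircular = FALSE) {
  seq <- DNAString(toupper(as.character(sequence)))
  if (is.null(regions)) {
    gr <- GRanges(seqnames = character(), ranges = IRanges(), strand = character())
    mcols(gr)$category <- character()
  } else if (is.data.frame(regions)) {
    std <- ifelse(regions$strand %in% c("forward", "+"), "+", "-")
    gr <- GRanges(seqnames = id,
                  ranges = IRanges(start = regions$start, end = regions$end),
                  strand = std)
    mcols(gr)$category <- as.character(regions$category)
  } else {
    gr <- regions
  }
  new("GenomeRecord", id = id, sequence = seq, regions = gr,
      isCircular = isCircular)
}

#' Read a genome and its annotation
#'
#' Reads the sequence from FASTA or a GenBank flat file and the annotated
#' regions from GFF3 or from the same GenBank file.  Features of type CDS,
#' tRNA, rRNA and other RNA kinds become regions; \code{complement(...)}
#' locations become backward-strand regions; GenBank joins spanning the
#' origin of a circular record are split at the origin.
#'
#' @param seqSource path to a FASTA or GenBank file.
#' @param annotSource path to a GFF3 file, or \code{NULL} when the
#'   annotation is embedded in a GenBank \code{seqSource}.
#' @param id optional record id override (defaults to the id in the file).
#' @return a \linkS4class{GenomeRecord}.
#' @export
readGenome <- function(seqSource, annotSource = NULL, id = NULL) {
  head <- readLines(seqSource, n = 1L)
  if (grepl("^LOCUS", head)) {
    gb <- .parseGenBank(seqSource)
    rec_id <- if (is.null(id)) gb$id else id
    regions <- gb$regions
    if (!is.null(annotSource))
      regions <- .readGFF3Regions(annotSource, rec_id, nchar(gb$sequence))
    return(GenomeRecord(rec_id, gb$sequence, regions, gb$circular))
  }
  if (!grepl("^>", head))
    stop("unrecognized sequence format in ", seqSource,
         " (expected FASTA or GenBank)")
  seqs <- readDNAStringSet(seqSource)
  if (length(seqs) == 0L) stop("no sequences in ", seqSource)
  rec_id <- if (is.null(id)) sub("\\s.*$", "", names(seqs)[1]) else id
  seq <- toupper(as.character(seqs[[1]]))
  regions <- NULL
  if (!is.null(annotSource))
    regions <- .readGFF3Regions(annotSource, rec_id, nchar(seq))
  GenomeRecord(rec_id, seq, regions, isCircular = FALSE)
}

.readGFF3Regions <- function(path, id, N) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- !is.na(.categoryForType(gr$type))
  gr <- gr[keep]
  if (length(gr) && (any(start(gr) < 1L) || any(end(gr) > N)))
    stop("annotation references coordinates beyond the sequence length ", N)
  out <- GRanges(seqnames = id,
                 ranges = IRanges(start = start(gr), end = end(gr)),
                 strand = ifelse(as.character(strand(gr)) == "-", "-", "+"))
  mcols(out)$category <- .categoryForType(gr$type)
  out
}

## Minimal GenBank flat-file parser: LOCUS (length, topology), FEATURES
## (CDS / tRNA / rRNA / *RNA keys with complement()/join() locations) and
## ORIGIN.  Only the subset needed for annotated genome records.
.parseGenBank <- function(path) {
  lines <- readLines(path)
  locus <- lines[grepl("^LOCUS", lines)][1]
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]
  circular <- grepl("circular", locus, ignore.case = TRUE)

  ostart <- grep("^ORIGIN", lines)[1]
  if (is.na(ostart)) stop("GenBank record without ORIGIN section: ", path)
  seqlines <- lines[(ostart + 1L):length(lines)]
  seqlines <- seqlines[!grepl("^//", seqlines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  N <- nchar(sequence)

  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1L):(ostart - 1L)]
    ## feature key lines have the key at column 6; qualifiers start at 22
    is_key <- grepl("^\\s{5}\\S", block)
    key_idx <- which(is_key)
    for (i in seq_along(key_idx)) {
      ln <- block[key_idx[i]]
      key <- sub("^\\s+", "", substr(ln, 1, 20))
      key <- sub("\\s.*$", "", key)
      loc <- trimws(substr(ln, 21, nchar(ln)))
      ## location may continue over lines until a qualifier (/...) or next key
      last <- if (i == length(key_idx)) length(block) else key_idx[i + 1L] - 1L
      j <- key_idx[i] + 1L
      while (j <= last && !grepl("^\\s+/", block[j])) {
        loc <- paste0(loc, trimws(block[j])); j <- j + 1L
      }
      cat_ <- .categoryForType(key)
      if (is.na(cat_)) next
      parsed <- .parseGBLocation(loc, N, circular)
      if (nrow(parsed)) {
        parsed$category <- cat_
        feats[[length(feats) + 1L]] <- parsed
      }
    }
  }
  regions <- if (length(feats)) do.call(rbind, feats) else NULL
  if (!is.null(regions) &&
      (any(regions$start < 1L) || any(regions$end > N)))
    stop("GenBank feature coordinates beyond sequence length ", N)
  list(id = id, sequence = sequence, circular = circular,
       regions = regions)
}

## Parse a GenBank location string into a data.frame(start, end, strand).
## Handles complement(), join(), order(), partial markers (< >) and splits
## origin-spanning spans (a..b with a > b on a circular record) in two.
.parseGBLocation <- function(loc, N, circular) {
  strand <- "forward"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "backward"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- gsub("^(join|order)\\(|\\)$", "", loc)
  parts <- strsplit(loc, ",")[[1]]
  out <- list()
  for (p in parts) {
    p <- gsub("[<>]", "", p)
    if (grepl("\\.\\.", p)) {
      se <- as.integer(strsplit(p, "\\.\\.")[[1]])
    } else {
      se <- rep(as.integer(p), 2L)
    }
    if (any(is.na(se))) next
    if (se[1] > se[2]) {
      if (!circular) stop("descending location on a linear record: ", p)
      out[[length(out) + 1L]] <- data.frame(start = se[1], end = N)
      out[[length(out) + 1L]] <- data.frame(start = 1L, end = se[2])
    } else {
      out[[length(out) + 1L]] <- data.frame(start = se[1], end = se[2])
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      strand = character()))
  res <- do.call(rbind, out)
  res$strand <- strand
  res
}

#' Write a table as TSV
#'
#' Tab-separated, header row, UTF-8, '.' decimal separator, stable column
#' order.  Refuses empty input and leaves no file behind in that case.
#'
#' @param rows a non-empty data.frame.
#' @param path output path.
#' @export
writeTable <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("writeTable: 'rows' must be a non-empty data.frame")
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(NULL)
}

#' Export a record's regions as GFF3
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @param path output path.
#' @export
exportRegionsGFF3 <- function(record, path) {
  gr <- genomeRegions(record)
  mcols(gr)$type <- .gffTypeForCategory(mcols(gr)$category)
  mcols(gr)$source <- "tripletPhase"
  mcols(gr)$phase <- ifelse(mcols(gr)$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(NULL)
}
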