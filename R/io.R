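#' Read a PWM library (JASPAR or TRANSFAC dialect)
#'
#' JASPAR dialect: records of the form
#' \preformatted{
#' >MA0001.1 NAME
#' A [ 3 10 0 ... ]
#' C [ ... ]
#' G [ ... ]
#' T [ ... ]
#' }
#' (brackets optional). TRANSFAC dialect: `AC`/`ID`/`DE` header lines, a
#' `P0 A C G T` column header, one numbered row per motif position, records
#' terminated by `//`.
#'
#' @param path file path.
#' @param dialect `"jaspar"` or `"transfac"`.
#' @param sourceDb label stored on each motif (defaults to the dialect).
#' @return a list of [PWMotif-class] objects. An empty file yields an empty
#'   list with a warning.
#' @export
readMatrixLibrary <- function(path, dialect = c("jaspar", "transfac"),
                              sourceDb = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(sourceDb)) sourceDb <- dialect
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty matrix library: ", path)
    return(list())
  }
  if (dialect == "jaspar") parseJaspar(lines, sourceDb)
  else parseTransfac(lines, sourceDb)
}

parseNums <- function(s, lineno) {
  s <- gsub("[][]", " ", s)
  v <- suppressWarnings(as.numeric(strsplit(trimws(s), "[ \t]+")[[1]]))
  if (any(is.na(v))) stop("malformed matrix record at line ", lineno)
  v
}

parseJaspar <- function(lines, sourceDb) {
  heads <- grep("^>", lines)
  if (!length(heads)) stop("malformed JASPAR library: no '>' header at line 1")
  out <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    h <- heads[i]
    last <- if (i < length(heads)) heads[i + 1] - 1L else length(lines)
    body <- lines[(h + 1L):last]
    if (length(body) != 4L) {
      stop("malformed JASPAR record at line ", h, ": expected 4 base rows")
    }
    toks <- strsplit(sub("^>\\s*", "", lines[h]), "[ \t]+")[[1]]
    id <- toks[1]
    tf <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else toks[1]
    rows <- lapply(seq_along(body), function(j) {
      ln <- body[j]
      base <- sub("^\\s*([ACGTacgt]).*", "\\1", ln)
      if (!toupper(base) %in% DNA_BASES) {
        stop("malformed JASPAR record at line ", h + j,
             ": row must start with a base letter")
      }
      vals <- parseNums(sub("^\\s*[ACGTacgt]", "", ln), h + j)
      list(base = toupper(base), vals = vals)
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, DNA_BASES)) {
      stop("malformed JASPAR record at line ", h, ": need one row per base")
    }
    lens <- vapply(rows, function(r) length(r$vals), integer(1))
    if (length(unique(lens)) != 1L) {
      stop("malformed JASPAR record at line ", h, ": ragged rows")
    }
    cnt <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(cnt) <- bases
    cnt <- cnt[DNA_BASES, , drop = FALSE]
    if (any(cnt < 0)) stop("negative count in matrix ", id)
    out[[i]] <- PWMotif(id, tf, cnt, sourceDb)
  }
  out
}

parseTransfac <- function(lines, sourceDb) {
  out <- list()
  id <- tf <- NA_character_
  rows <- list()
  flush <- function() {
    if (!length(rows)) return(invisible(NULL))
    cnt <- t(do.call(rbind, rows))
    rownames(cnt) <- DNA_BASES
    if (any(cnt < 0)) stop("negative count in matrix ", id)
    out[[length(out) + 1L]] <<- PWMotif(
      if (is.na(id)) paste0("M", length(out) + 1L) else id,
      if (is.na(tf)) id else tf, cnt, sourceDb)
    id <<- NA_character_; tf <<- NA_character_; rows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^//", ln)) { flush(); next }
    if (grepl("^AC\\b", ln)) { id <- trimws(sub("^AC", "", ln)); next }
    if (grepl("^(DE|NA)\\b", ln)) { tf <- trimws(sub("^(DE|NA)", "", ln)); next }
    if (grepl("^(ID|P0|PO|XX|BF|CC)\\b", ln)) next
    if (grepl("^[0-9]+\\s", ln)) {
      v <- parseNums(sub("^[0-9]+", "", ln), i)
      if (length(v) < 4L) stop("malformed TRANSFAC row at line ", i)
      rows[[length(rows) + 1L]] <- v[1:4]
    }
  }
  flush()
  out
}

#' Write motifs in JASPAR format
#'
#' @param motifs list of [PWMotif-class].
#' @param path output file.
#' @export
writeMatrixLibrary <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m@matrixId, " ", m@tfName), con)
    for (b in DNA_BASES) {
      writeLines(paste0(b, "  [ ",
                        paste(format(m@counts[b, ], trim = TRUE),
                              collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Fetch a 1-based inclusive interval from a genome
#'
#' @param genome named character vector or `DNAStringSet`, one element per
#'   chromosome.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive bounds.
#' @return uppercase sequence string of length `end - start + 1`.
#' @examples
#' fetchSequence(c(chr1 = "ACGT"), "chr1", 2, 3) # "CG"
#' @export
fetchSequence <- function(genome, chrom, start, end) {
  s <- chromSeq(genome, chrom)
  if (start < 1 || end > nchar(s) || start > end) {
    stop("interval out of bounds: ", chrom, ":", start, "-", end,
         " (chromosome length ", nchar(s), ")")
  }
  toupper(substr(s, start, end))
}

#' Read a BED3/BED4+ file
#'
#' Track, browser and comment lines are skipped. Coordinates are kept
#' 0-based half-open as in the file; the optional 4th column is kept as
#' `name` (peak name or ChromHMM state label).
#'
#' @param path file path.
#' @param biosample optional biosample label attached to every row (ChromHMM
#'   segmentations carry the biosample in the file name, not in the file).
#' @return data.frame with columns chrom, start, end, name (NA if absent)
#'   and biosample (if given).
#' @export
readBed <- function(path, biosample = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- vapply(parts, length, integer(1))
  if (any(ncols < 3L)) {
    stop("BED line with fewer than 3 columns at line ",
         which(ncols < 3L)[1])
  }
  df <- data.frame(
    chrom = vapply(parts, `[[`, character(1), 1L),
    start = as.integer(vapply(parts, `[[`, character(1), 2L)),
    end = as.integer(vapply(parts, `[[`, character(1), 3L)),
    name = vapply(parts, function(p) if (length(p) >= 4L) p[[4L]]
                  else NA_character_, character(1)),
    stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) {
    stop("BED interval with start >= end at line ",
         which(df$start >= df$end)[1])
  }
  if (!is.null(biosample)) df$biosample <- biosample
  df
}

#' Write 0-based half-open intervals as BED
#' @param df data.frame with chrom, start, end and optional name column.
#' @param path output file.
#' @export
writeBed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  stopifnotCols(df, cols, "BED table")
  out <- df[, cols]
  if ("name" %in% names(df)) out$name <- df$name
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TPM expression matrix (GCT dialect or plain TSV)
#'
#' GCT files start with a `#1.2` version line and a dimensions line, then a
#' table whose first two columns are Name and Description. Plain TSV has
#' gene ids in the first column and one column per tissue.
#'
#' @param path file path.
#' @return numeric matrix genes x tissues.
#' @export
readExpressionMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (grepl("^#1\\.", first)) 2L else 0L
  tab <- read.table(path, sep = "\t", header = TRUE, skip = skip,
                    check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1L]])
  drop <- if (skip > 0 && tolower(names(tab)[2]) == "description") 2L else 1L
  mat <- as.matrix(tab[, -(seq_len(drop)), drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- genes
  if (anyDuplicated(genes)) {
    stop("duplicate gene id(s) in expression matrix: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (any(is.na(mat))) stop("non-numeric TPM entries in ", path)
  if (any(mat < 0)) stop("negative TPM entries in ", path)
  mat
}

#' Write an expression matrix in GCT format
#' @param mat numeric matrix genes x tissues.
#' @param path output file.
#' @export
writeExpressionGct <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(paste(nrow(mat), ncol(mat), sep = "\t"), con)
  df <- data.frame(Name = rownames(mat), Description = rownames(mat),
                   mat, check.names = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a PICS probability table
#'
#' Column layouts of PICS snapshot files vary; `cols` maps the standard
#' field names onto the file's column names.
#'
#' @param path TSV file with a header.
#' @param source `"gwas"` or `"eqtl"`.
#' @param cols named character vector mapping standard fields
#'   (variant_id, locus_id, pics_prob, tissue, egene) to file columns;
#'   fields absent from the file may be omitted (tissue/egene default to "").
#' @return data.frame with columns variant_id, locus_id, pics_prob, source,
#'   tissue, egene.
#' @export
readPicsTable <- function(path, source = c("gwas", "eqtl"),
                          cols = c(variant_id = "variant_id",
                                   locus_id = "locus_id",
                                   pics_prob = "pics_prob",
                                   tissue = "tissue", egene = "egene")) {
  source <- match.arg(source)
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
  get <- function(field, default = "") {
    if (field %in% names(cols) && cols[[field]] %in% names(tab)) {
      tab[[cols[[field]]]]
    } else rep(default, nrow(tab))
  }
  out <- data.frame(
    variant_id = as.character(get("variant_id", NA_character_)),
    locus_id = as.character(get("locus_id", NA_character_)),
    pics_prob = as.numeric(get("pics_prob", NA_real_)),
    source = source,
    tissue = as.character(get("tissue")),
    egene = as.character(get("egene")),
    stringsAsFactors = FALSE)
  if (any(is.na(out$pics_prob)) ||
      any(out$pics_prob < 0 | out$pics_prob > 1)) {
    stop("pics_prob must be in [0, 1]")
  }
  out
}

#' Serialize / read a Markov background model as TSV
#'
#' One row per context with the four next-base probabilities and the
#' stationary probability; header comments carry order, pseudocount and
#' set label.
#'
#' @param bg a [MarkovBackground-class].
#' @param path file path.
#' @export
writeBackgroundModel <- function(bg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# order=%d pseudocount=%g label=%s",
                     bg@order, bg@pseudocount, bg@label), con)
  df <- data.frame(context = rownames(bg@transitions), bg@transitions,
                   stationary = bg@stationary, check.names = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname writeBackgroundModel
#' @return `readBackgroundModel` returns a [MarkovBackground-class].
#' @export
readBackgroundModel <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z]+=[^ ]+", hdr))[[1]]
  kv <- setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  tab <- read.table(path, sep = "\t", header = TRUE, skip = 1L,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = c(context = "character"))
  ctx <- tab$context
  tr <- as.matrix(tab[, DNA_BASES])
  rownames(tr) <- ctx
  st <- setNames(tab$stationary, ctx)
  new("MarkovBackground", order = as.integer(kv[["order"]]),
      transitions = tr, stationary = st,
      label = kv[["label"]], pseudocount = as.numeric(kv[["pseudocount"]]))
}
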