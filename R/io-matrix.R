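#' Read a taxon-area matrix from CSV, TSV or NEXUS
#'
#' Reads a binary area-by-species presence/absence matrix.  Delimited files
#' must carry a header row of species names and a first column of area names;
#' NEXUS files must contain a `data` or `characters` block with symbols drawn
#' from `{0,1}` (`datatype=standard`), interleaved or not, as written by
#' Mesquite-style editors.  Any symbol outside `{0,1}` (including `?` and `-`)
#' is a validation error naming the offending area and character: missing and
#' polymorphic states are unsupported because the Mk engine assumes fully
#' observed tips.
#'
#' Orientation is never guessed from the shape of the file: rows are taken to
#' be areas unless `transpose = TRUE` is given for species-by-area files.
#'
#' @param path path to the file.
#' @param format one of `"auto"`, `"csv"`, `"tsv"`, `"nexus"`.  `"auto"`
#'   inspects the extension and the first line.
#' @param transpose logical; set `TRUE` when the file stores species in rows
#'   and areas in columns.
#' @return A validated [TaxonAreaMatrix-class].
#' @seealso [writeTaxonAreaMatrix()]
#' @export
readTaxonAreaMatrix <- function(path, format = c("auto", "csv", "tsv", "nexus"),
                                transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("nex", "nexus", "nxs")) "nexus"
      else if (ext == "tsv") "tsv"
      else if (ext == "csv") "csv"
      else {
        first <- readLines(path, n = 1L, warn = FALSE)
        if (grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus"
        else if (grepl("\t", first)) "tsv" else "csv"
      }
  }
  m <- switch(format,
    csv = .readDelimMatrix(path, ","),
    tsv = .readDelimMatrix(path, "\t"),
    nexus = .readNexusMatrix(path))
  if (isTRUE(transpose)) m <- t(m)
  .checkBinaryCells(m, path)
  taxonAreaMatrix(m, provenance = path)
}

.readDelimMatrix <- function(path, sep) {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 1L) stop("parse error in ", path, ": no columns found")
  rn <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "numeric")
  rownames(m) <- rn
  m
}

.checkBinaryCells <- function(m, path) {
  bad <- which(is.na(m) | !(m %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop(sprintf(
      "validation error in %s: non-binary state at area '%s', character %d ('%s')",
      path, rownames(m)[i], j, colnames(m)[j]))
  }
  invisible(m)
}

## --- NEXUS characters block ------------------------------------------------

.stripNexusComments <- function(txt) gsub("\\[[^]]*\\]", " ", txt)

# Tokenize a NEXUS name list: single-quoted names keep spaces, '' unescapes
# to a literal quote.
.nexusTokens <- function(line) {
  toks <- character(); chars <- strsplit(line, "")[[1]]
  n <- length(chars); i <- 1L
  ws <- c(" ", "\t", "\r", "\n")
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% ws) { i <- i + 1L; next }
    if (ch == "'") {
      buf <- character(); j <- i + 1L
      repeat {
        if (j > n) stop("parse error: unterminated quoted name")
        if (chars[j] == "'") {
          if (j < n && chars[j + 1L] == "'") { buf <- c(buf, "'"); j <- j + 2L }
          else { j <- j + 1L; break }
        } else { buf <- c(buf, chars[j]); j <- j + 1L }
      }
      toks <- c(toks, paste(buf, collapse = ""))
      i <- j
    } else {
      j <- i
      while (j <= n && !(chars[j] %in% c(ws, "'"))) j <- j + 1L
      toks <- c(toks, paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  toks
}

.readNexusMatrix <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (!length(raw) || !grepl("^\\s*#NEXUS", raw[1L], ignore.case = TRUE))
    stop("parse error in ", path, ": missing #NEXUS header (line 1)")
  txt <- .stripNexusComments(paste(raw, collapse = "\n"))
  low <- tolower(txt)
  beg <- regexpr("begin\\s+(data|characters)\\s*;", low)
  if (beg < 0) stop("parse error in ", path,
                    ": no data or characters block found")
  endpat <- regexpr("end\\s*;", substr(low, beg, nchar(low)))
  if (endpat < 0) stop("parse error in ", path, ": unterminated block")
  block <- substr(txt, beg, beg + endpat + attr(endpat, "match.length") - 2L)
  blow <- tolower(block)

  grab <- function(key) {
    mm <- regexpr(paste0(key, "\\s*=\\s*[0-9]+"), blow)
    if (mm < 0) return(NA_integer_)
    as.integer(sub(paste0(key, "\\s*=\\s*"), "",
                   regmatches(blow, mm)))
  }
  ntax <- grab("ntax"); nchar_ <- grab("nchar")
  if (is.na(ntax) || is.na(nchar_))
    stop("parse error in ", path, ": dimensions line lacks ntax/nchar")

  fm <- regexpr("format[^;]*;", blow)
  if (fm > 0) {
    fmt <- substr(block, fm, fm + attr(fm, "match.length") - 1L)
    sy <- regmatches(fmt, regexpr('symbols\\s*=\\s*"[^"]*"', tolower(fmt)))
    if (length(sy)) {
      sym <- strsplit(gsub('.*"([^"]*)".*', "\\1", sy), "")[[1]]
      if (!all(sym %in% c("0", "1", " ")))
        stop("validation error in ", path,
             ": symbols outside {0,1} are not supported")
    }
  }

  charlabels <- NULL
  cl <- regexpr("charlabels[^;]*;", blow)
  if (cl > 0) {
    seg <- substr(block, cl + nchar("charlabels"), cl + attr(cl, "match.length") - 2L)
    charlabels <- .nexusTokens(gsub("\n", " ", seg))
  } else {
    csl <- regexpr("charstatelabels[^;]*;", blow)
    if (csl > 0) {
      seg <- substr(block, csl + nchar("charstatelabels"),
                    csl + attr(csl, "match.length") - 2L)
      items <- strsplit(seg, ",")[[1]]
      charlabels <- vapply(items, function(it) {
        tk <- .nexusTokens(gsub("\n", " ", it))
        if (length(tk) >= 2L) tk[2L] else NA_character_
      }, character(1), USE.NAMES = FALSE)
    }
  }

  mx <- regexpr("matrix", blow)
  if (mx < 0) stop("parse error in ", path, ": no matrix keyword in block")
  body <- substr(block, mx + nchar("matrix"), nchar(block))
  semi <- regexpr(";", body)
  if (semi < 0) stop("parse error in ", path, ": matrix not terminated by ';'")
  body <- substr(body, 1L, semi - 1L)

  rows <- list(); order <- character()
  for (line in strsplit(body, "\n")[[1]]) {
    toks <- .nexusTokens(line)
    if (!length(toks)) next
    name <- toks[1L]
    states <- strsplit(paste(toks[-1L], collapse = ""), "")[[1]]
    if (!length(states) && nchar_ > 0L) next
    if (is.null(rows[[name]])) { rows[[name]] <- states; order <- c(order, name) }
    else rows[[name]] <- c(rows[[name]], states)   # interleaved continuation
  }
  if (length(order) != ntax)
    stop(sprintf("parse error in %s: matrix has %d taxa but ntax=%d",
                 path, length(order), ntax))
  m <- matrix(NA_real_, nrow = ntax, ncol = nchar_,
              dimnames = list(order, NULL))
  for (name in order) {
    st <- rows[[name]]
    if (length(st) != nchar_)
      stop(sprintf("parse error in %s: taxon '%s' has %d states but nchar=%d",
                   path, name, length(st), nchar_))
    bad <- which(!(st %in% c("0", "1")))
    if (length(bad))
      stop(sprintf(
        "validation error in %s: symbol '%s' at area '%s', character %d",
        path, st[bad[1L]], name, bad[1L]))
    m[name, ] <- as.numeric(st)
  }
  colnames(m) <- if (!is.null(charlabels) && length(charlabels) == nchar_ &&
                     !anyNA(charlabels)) charlabels
                 else if (nchar_ > 0) sprintf("char%d", seq_len(nchar_))
                 else character(0)
  m
}

## --- writers ---------------------------------------------------------------

.nexusQuote <- function(x) {
  needs <- grepl("[^A-Za-z0-9_.+-]", x) | !nzchar(x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Write a taxon-area matrix to CSV, TSV or NEXUS
#'
#' The NEXUS form is a minimal `data` block
#' (`format datatype=standard symbols="01"`) with species names preserved
#' verbatim as quoted `charlabels`, readable by Mesquite/PAUP-style programs
#' and by [readTaxonAreaMatrix()].  CSV/TSV files have a species-name header
#' and area names in the first column.
#'
#' @param x a [TaxonAreaMatrix-class].
#' @param path output path.
#' @param format `"csv"`, `"tsv"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
writeTaxonAreaMatrix <- function(x, path, format = c("csv", "nexus", "tsv")) {
  stopifnot(methods::is(x, "TaxonAreaMatrix"))
  format <- match.arg(format)
  m <- presence(x)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste(c("area", colnames(m)), collapse = sep), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = sep), con)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("#NEXUS", con)
    writeLines("begin data;", con)
    writeLines(sprintf("  dimensions ntax=%d nchar=%d;", nrow(m), ncol(m)), con)
    writeLines('  format datatype=standard symbols="01";', con)
    if (ncol(m) > 0L)
      writeLines(c("  charlabels", paste0("    ",
        paste(.nexusQuote(colnames(m)), collapse = " ")), "  ;"), con)
    writeLines("  matrix", con)
    nm <- .nexusQuote(rownames(m))
    pad <- max(nchar(nm, type = "bytes"), 0L)
    for (i in seq_len(nrow(m)))
      writeLines(sprintf("    %-*s %s", pad, nm[i],
                         paste(m[i, ], collapse = "")), con)
    writeLines(c("  ;", "end;"), con)
  }
  invisible(path)
}
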