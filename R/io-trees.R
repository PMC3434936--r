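#' Read an area tree from Newick
#'
#' Thin validating wrapper around [ape::read.tree()].  Accepts a file path or
#' a literal Newick string.  Branch lengths are optional: when the Newick
#' carries none the returned tree has no `edge.length` component ("unset"),
#' never silently zero.  Duplicate tip labels are rejected.
#'
#' @param x path to a Newick file, or a Newick string (anything containing
#'   `(` and `;` is treated as a string).
#' @return an [ape::read.tree()] `phylo` object over areas.
#' @export
readAreaTree <- function(x) {
  txt <- if (length(x) == 1L && grepl("\\(", x) && grepl(";", x)) x
         else paste(readLines(x, warn = FALSE), collapse = "")
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tr)) stop("parse error: not a valid Newick tree")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length in input tree")
  tr
}

#' Write an area tree to Newick
#'
#' @param tree a `phylo` object.
#' @param path output path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
writeAreaTree <- function(tree, path = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

## --- SIMMAP-annotated Newick ----------------------------------------------

.checkSegments <- function(tree, segments, tol = 1e-9) {
  if (length(segments) != nrow(tree$edge))
    stop("consistency error: need one segment table per edge (",
         nrow(tree$edge), "), got ", length(segments))
  for (e in seq_along(segments)) {
    seg <- segments[[e]]
    if (!all(c("state", "duration") %in% names(seg)))
      stop("segment tables need 'state' and 'duration' columns")
    if (any(seg$duration < 0))
      stop("consistency error: negative segment duration on edge ", e)
    len <- tree$edge.length[e]
    if (abs(sum(seg$duration) - len) > tol * max(1, len))
      stop(sprintf(
        "consistency error: segments on edge %d sum to %.12g but branch length is %.12g",
        e, sum(seg$duration), len))
    if (nrow(seg) > 1L && any(diff(seg$state) == 0))
      stop("consistency error: adjacent segments with equal state on edge ", e)
  }
  invisible(TRUE)
}

#' Write a stochastic character map as SIMMAP-annotated Newick
#'
#' Serialises one sampled character history: each branch is annotated with an
#' ordered list of `(state, duration)` segments, written rootward-to-tipward
#' as `:{state,duration:state,duration:...}`.  Segment durations must
#' partition the branch length (relative tolerance `1e-9`) and adjacent
#' segments must differ in state.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param segments list with one `data.frame(state, duration)` per row of
#'   `tree$edge`, ordered rootward to tipward along each branch.
#' @param path output path, or `NULL` to return the string.
#' @return the annotated Newick string, invisibly when written to a file.
#' @seealso [readSimmap()], [mapCharacter()]
#' @export
writeSimmap <- function(tree, segments, path = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  .checkSegments(tree, segments)
  nt <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmtnum <- function(x) formatC(x, digits = 12, format = "g")
  annot <- function(e) {
    seg <- segments[[e]]
    paste0(":{", paste(sprintf("%s,%s", seg$state, fmtnum(seg$duration)),
                       collapse = ":"), "}")
  }
  rec <- function(node, edgeIn) {
    lab <- if (node <= nt) .nexusQuote(tree$tip.label[node]) else ""
    sub <- if (node <= nt) lab else {
      es <- kids[[as.character(node)]]
      paste0("(", paste(vapply(es, function(e)
        rec(tree$edge[e, 2L], e), character(1)), collapse = ","), ")")
    }
    if (is.na(edgeIn)) sub else paste0(sub, annot(edgeIn))
  }
  root <- nt + 1L
  txt <- paste0(rec(root, NA_integer_), ";")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a SIMMAP-annotated Newick written by [writeSimmap()]
#'
#' @param x path to a file, or the annotated Newick string itself.
#' @return a list with `tree` (a `phylo`; branch lengths are the segment
#'   sums) and `segments` (one `data.frame(state, duration)` per edge, in
#'   `tree$edge` order, rootward first).
#' @export
readSimmap <- function(x) {
  txt <- if (length(x) == 1L && grepl("\\{", x)) x
         else paste(readLines(x, warn = FALSE), collapse = "")
  txt <- gsub("[\r\n]", "", txt)
  pos <- 1L; n <- nchar(txt)
  peek <- function() if (pos > n) "" else substr(txt, pos, pos)
  advance <- function() pos <<- pos + 1L
  tips <- character(); edges <- list()
  # each node: list(label, children = list of edge list(child, segs))
  parseAnnot <- function() {
    if (peek() != ":") return(NULL)
    advance()
    if (peek() != "{") stop("parse error: expected '{' at position ", pos)
    advance()
    buf <- character()
    while (peek() != "}") {
      if (pos > n) stop("parse error: unterminated segment annotation")
      buf <- c(buf, peek()); advance()
    }
    advance()
    parts <- strsplit(paste(buf, collapse = ""), ":", fixed = TRUE)[[1]]
    st <- numeric(); du <- numeric()
    for (p in parts) {
      kv <- strsplit(p, ",", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop("parse error: bad segment '", p, "'")
      st <- c(st, as.numeric(kv[1])); du <- c(du, as.numeric(kv[2]))
    }
    data.frame(state = st, duration = du)
  }
  parseName <- function() {
    if (peek() == "'") {
      advance(); buf <- character()
      repeat {
        ch <- peek()
        if (ch == "") stop("parse error: unterminated quoted label")
        if (ch == "'") {
          advance()
          if (peek() == "'") { buf <- c(buf, "'"); advance() } else break
        } else { buf <- c(buf, ch); advance() }
      }
      paste(buf, collapse = "")
    } else {
      buf <- character()
      while (!(peek() %in% c(":", ",", ")", "(", ";", "{", ""))) {
        buf <- c(buf, peek()); advance()
      }
      paste(buf, collapse = "")
    }
  }
  parseClade <- function() {
    if (peek() == "(") {
      advance()
      children <- list(parseClade())
      while (peek() == ",") { advance(); children <- c(children, list(parseClade())) }
      if (peek() != ")") stop("parse error: expected ')' at position ", pos)
      advance()
      parseName()  # optional internal label, discarded
      list(tip = NA_character_, children = children, segs = parseAnnot())
    } else {
      lab <- parseName()
      if (!nzchar(lab)) stop("parse error: empty tip label at position ", pos)
      list(tip = lab, children = NULL, segs = parseAnnot())
    }
  }
  tree0 <- parseClade()
  if (peek() != ";") stop("parse error: missing terminal ';'")

  # flatten into an ape edge matrix
  tipLabs <- character(); edgeA <- integer(); edgeB <- integer()
  segsOut <- list(); counter <- new.env()
  collectTips <- function(nd) {
    if (!is.na(nd$tip)) tipLabs <<- c(tipLabs, nd$tip)
    else for (ch in nd$children) collectTips(ch)
  }
  collectTips(tree0)
  ntip <- length(tipLabs)
  if (anyDuplicated(tipLabs))
    stop("duplicate tip labels: ",
         paste(unique(tipLabs[duplicated(tipLabs)]), collapse = ", "))
  nextInternal <- ntip + 1L
  tipIdx <- 0L
  assignNum <- function(nd) {
    if (!is.na(nd$tip)) { tipIdx <<- tipIdx + 1L; tipIdx }
    else { id <- nextInternal; nextInternal <<- nextInternal + 1L
           nd$id <- id
           for (ch in nd$children) {
             cid <- assignNum(ch)
             edgeA <<- c(edgeA, id); edgeB <<- c(edgeB, cid)
             segsOut[[length(edgeA)]] <<- ch$segs
           }
           id }
  }
  assignNum(tree0)
  tr <- list(edge = cbind(edgeA, edgeB),
             tip.label = tipLabs,
             Nnode = nextInternal - ntip - 1L + 1L,
             edge.length = vapply(segsOut, function(s)
               if (is.null(s)) NA_real_ else sum(s$duration), numeric(1)))
  dimnames(tr$edge) <- NULL
  tr$Nnode <- nextInternal - (ntip + 1L)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  # reorder.phylo permutes edges; recompute segment order to match
  list(tree = tr, segments = {
    key <- paste(edgeA, edgeB); ord <- match(paste(tr$edge[, 1], tr$edge[, 2]), key)
    segsOut[ord]
  })
}
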