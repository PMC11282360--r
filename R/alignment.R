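# DNA states are held as IUPAC bitmasks: A=1, C=2, G=4, T=8; ambiguity codes
# are the union of their compatible states; gaps/'N'/'?' are full uncertainty
# (15).  Tip partial-likelihood vectors fall directly out of the bit pattern.

.iupac <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
            R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
            B = 14L, D = 13L, H = 11L, V = 7L,
            N = 15L, "-" = 15L, "?" = 15L, "." = 15L)

.state_chars <- c("A", "C", "G", "T")

#' Construct a DNA alignment object
#'
#' @param x character matrix (taxa x sites) of IUPAC nucleotide codes, with
#'   taxon labels as row names, or a named character vector of equal-length
#'   sequence strings.
#' @param drop_allgap drop columns that are entirely gap/unknown (their
#'   likelihood is 1 under any model and they carry no information); the count
#'   of dropped columns is reported with a message.
#' @return an object of class `mast_alignment`: list with `labels`,
#'   `states` (taxa x sites integer bitmask matrix) and `nsites`.
#' @export
mast_alignment <- function(x, drop_allgap = TRUE) {
  if (is.character(x) && is.null(dim(x))) {
    if (is.null(names(x))) stop("sequence vector must be named by taxon")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L)
      stop("sequences differ in length: '", names(x)[which(lens != lens[1L])[1L]],
           "' has ", lens[which(lens != lens[1L])[1L]], " characters, expected ", lens[1L])
    x <- do.call(rbind, lapply(strsplit(toupper(x), ""), identity))
  } else {
    x <- toupper(as.matrix(x))
  }
  labels <- rownames(x)
  if (is.null(labels)) stop("alignment must carry taxon labels")
  if (anyDuplicated(labels))
    stop("duplicate taxon label: '", labels[duplicated(labels)][1L], "'")
  if (ncol(x) < 1L) stop("alignment has no sites")
  states <- matrix(.iupac[x], nrow = nrow(x), dimnames = list(labels, NULL))
  if (anyNA(states)) {
    bad <- which(is.na(states), arr.ind = TRUE)[1L, ]
    stop("record '", labels[bad[1L]], "' contains unrecognized character '",
         x[bad[1L], bad[2L]], "' at site ", bad[2L])
  }
  if (drop_allgap) {
    allgap <- colSums(states == 15L) == nrow(states)
    if (any(allgap)) {
      message("dropping ", sum(allgap), " all-gap/unknown column(s)")
      states <- states[, !allgap, drop = FALSE]
      if (ncol(states) == 0L) stop("alignment has no informative columns")
    }
  }
  structure(list(labels = labels, states = states, nsites = ncol(states)),
            class = "mast_alignment")
}

#' @export
print.mast_alignment <- function(x, ...) {
  cat("DNA alignment:", length(x$labels), "taxa x", x$nsites, "sites\n")
  invisible(x)
}

#' Read a DNA multiple sequence alignment
#'
#' Reads FASTA (via ape) or relaxed sequential PHYLIP (header `ntaxa nsites`;
#' each record a whitespace-separated name followed by its sequence, which may
#' wrap over subsequent lines). Characters are upper-cased and U is mapped to
#' T; gaps and ambiguity codes become partial-uncertainty observations.
#'
#' @param path input file.
#' @param format `"fasta"` or `"phylip"`.
#' @return a [mast_alignment] object.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    seqs <- ape::read.FASTA(path)
    if (length(seqs) == 0L) stop("empty FASTA file: ", path)
    chr <- lapply(as.character(seqs), function(s) toupper(paste(s, collapse = "")))
    lens <- vapply(chr, nchar, 0L)
    if (length(unique(lens)) != 1L) {
      modal <- as.integer(names(which.max(table(lens))))
      off <- names(chr)[which(lens != modal)[1L]]
      stop("ragged alignment: record '", off, "' has ",
           nchar(chr[[off]]), " characters while others have ", modal)
    }
    v <- unlist(chr)
  } else {
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(trimws(ln))]
    if (length(ln) < 2L) stop("empty or truncated PHYLIP file: ", path)
    hdr <- suppressWarnings(as.integer(strsplit(trimws(ln[1L]), "\\s+")[[1L]]))
    if (length(hdr) < 2L || anyNA(hdr[1:2]))
      stop("malformed PHYLIP header: '", ln[1L], "'")
    ntax <- hdr[1L]; nsit <- hdr[2L]
    v <- character(0); i <- 2L
    for (k in seq_len(ntax)) {
      if (i > length(ln)) stop("PHYLIP body ends before record ", k, " of ", ntax)
      tok <- strsplit(trimws(ln[i]), "\\s+")[[1L]]
      nm <- tok[1L]; sq <- paste(tok[-1L], collapse = ""); i <- i + 1L
      while (nchar(sq) < nsit && i <= length(ln)) {
        nxt <- gsub("\\s+", "", ln[i])
        sq <- paste0(sq, nxt); i <- i + 1L
      }
      if (nchar(sq) != nsit)
        stop("record '", nm, "' has ", nchar(sq), " characters, expected ", nsit)
      v[nm] <- toupper(sq)
    }
    if (anyDuplicated(names(v)))
      stop("duplicate taxon label: '", names(v)[duplicated(names(v))][1L], "'")
  }
  mast_alignment(v)
}

#' Write an alignment to FASTA
#'
#' Unknown/gap states are written as `-`; partial ambiguities by their IUPAC
#' code. Round-trips with [read_alignment] up to the gap/`N` equivalence.
#'
#' @param aln a [mast_alignment].
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "mast_alignment"))
  code <- rep(NA_character_, 15L)
  code[.iupac[setdiff(names(.iupac), c("U", "?", "."))]] <-
    setdiff(names(.iupac), c("U", "?", "."))
  lines <- character(2L * length(aln$labels))
  for (i in seq_along(aln$labels)) {
    lines[2L * i - 1L] <- paste0(">", aln$labels[i])
    lines[2L * i] <- paste(code[aln$states[i, ]], collapse = "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Compress an alignment into weighted site patterns
#'
#' Because sites are modelled as independent and identically distributed,
#' identical columns share one likelihood computation; the pattern weight is
#' the column multiplicity and the site map expands per-pattern results back
#' to per-site ones.
#'
#' @param aln a [mast_alignment].
#' @return an object of class `pattern_alignment`: list with `labels`,
#'   `states` (taxa x patterns), `weights` (integer multiplicities summing to
#'   the site count), `site_map` (length-N pattern index per site) and
#'   `nsites`.
#' @export
compress_patterns <- function(aln) {
  stopifnot(inherits(aln, "mast_alignment"))
  key <- apply(aln$states, 2L, paste, collapse = ".")
  first <- which(!duplicated(key))
  site_map <- match(key, key[first])
  weights <- tabulate(site_map, nbins = length(first))
  structure(list(labels = aln$labels,
                 states = aln$states[, first, drop = FALSE],
                 weights = weights, site_map = site_map,
                 nsites = aln$nsites),
            class = "pattern_alignment")
}

#' @export
print.pattern_alignment <- function(x, ...) {
  cat("Pattern alignment:", length(x$labels), "taxa,", length(x$weights),
      "patterns over", x$nsites, "sites\n")
  invisible(x)
}

# Expand a pattern alignment back into a plain alignment (inverse check).
expand_patterns <- function(paln) {
  stopifnot(inherits(paln, "pattern_alignment"))
  structure(list(labels = paln$labels,
                 states = paln$states[, paln$site_map, drop = FALSE],
                 nsites = paln$nsites),
            class = "mast_alignment")
}

# Tip partial-likelihood array (4 x npat x ntaxa) from bitmask states.
tip_partials <- function(paln) {
  bits <- 2L^(0:3)
  st <- paln$states
  out <- array(0, dim = c(4L, ncol(st), nrow(st)))
  for (i in seq_len(nrow(st))) {
    for (s in 1:4) out[s, , i] <- as.numeric(bitwAnd(st[i, ], bits[s]) > 0L)
  }
  out
}
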