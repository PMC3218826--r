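# SOLiD di-base (color-space) encoding and decoding.
#
# Each color symbol 0-3 encodes the transition between two adjacent bases.
# With the 2-bit base codes A=0, C=1, G=2, T=3 the standard SOLiD di-base
# matrix (identical pair -> 0; A<->C = 1; A<->G = 2; A<->T = 3; C<->G = 3;
# C<->T = 2; G<->T = 1) is exactly bitwise XOR of the two codes, which makes
# encoding/decoding vectorisable.

.CS_CODE <- local({
  x <- rep(NA_integer_, 128L)
  x[utf8ToInt("A")] <- 0L; x[utf8ToInt("a")] <- 0L
  x[utf8ToInt("C")] <- 1L; x[utf8ToInt("c")] <- 1L
  x[utf8ToInt("G")] <- 2L; x[utf8ToInt("g")] <- 2L
  x[utf8ToInt("T")] <- 3L; x[utf8ToInt("t")] <- 3L
  x[utf8ToInt("U")] <- 3L; x[utf8ToInt("u")] <- 3L
  x
})

.CS_BASE <- c("A", "C", "G", "T")

## single-string base codes; NA for non-ACGTU characters
.base_codes <- function(s) {
  v <- utf8ToInt(s)
  v[v < 1L | v > 128L] <- 1L
  .CS_CODE[v]
}

.color_codes <- function(s) {
  v <- utf8ToInt(s) - 48L
  v[v < 0L | v > 3L] <- NA_integer_
  v
}

#' Encode a nucleotide sequence into SOLiD color space
#'
#' Converts a DNA/RNA sequence into its di-base color-space representation,
#' anchored on a primer base. Color `i` encodes the transition between base
#' `i-1` and base `i`, with the primer acting as base 0, under the standard
#' SOLiD matrix (identity -> 0, A/C -> 1, A/G -> 2, A/T -> 3, C/G -> 3,
#' C/T -> 2, G/T -> 1).
#'
#' @param seq A single nucleotide sequence (character scalar). `U` is
#'   converted to `T` on ingest, so RNA mature miRNA sequences can be passed
#'   directly.
#' @param primer The anchoring primer base, one of `A`, `C`, `G`, `T`.
#' @return A character scalar: the primer base followed by one color symbol
#'   (`0`-`3`) per input base, so `nchar(result) == nchar(seq) + 1`.
#' @examples
#' encode_colorspace("AAAA", "T")  # "T3000"
#' encode_colorspace("ACGT", "G")  # "G2131"
#' @seealso [decode_colorspace()], [sequence_internal_colors()]
#' @export
encode_colorspace <- function(seq, primer = "T") {
  stopifnot(is.character(seq), length(seq) == 1L, is.character(primer),
            length(primer) == 1L, nchar(primer) == 1L)
  if (nchar(seq) == 0L) stop("sequence must be non-empty")
  b <- .base_codes(seq)
  if (anyNA(b)) stop("sequence contains characters outside {A,C,G,T,U}")
  p <- .base_codes(primer)
  if (anyNA(p)) stop("primer must be one of A, C, G, T")
  x <- c(p, b)
  cols <- bitwXor(x[-length(x)], x[-1L])
  paste0(.CS_BASE[p + 1L], paste(cols, collapse = ""))
}

#' Decode a color-space string back to nucleotides
#'
#' Inverts [encode_colorspace()]: the first character must be the anchoring
#' nucleotide, the remainder color symbols `0`-`3`. Because every color is a
#' reversible transition, the decoded sequence is unique.
#'
#' @param colors_with_primer Character scalar: a nucleotide followed by
#'   colors, e.g. `"T3000"`.
#' @return The decoded nucleotide sequence (without the primer base).
#' @examples
#' decode_colorspace("T3000")  # "AAAA"
#' decode_colorspace("G2131")  # "ACGT"
#' @export
decode_colorspace <- function(colors_with_primer) {
  stopifnot(is.character(colors_with_primer), length(colors_with_primer) == 1L)
  if (nchar(colors_with_primer) < 2L)
    stop("need a primer base plus at least one color")
  p <- .base_codes(substr(colors_with_primer, 1L, 1L))
  if (anyNA(p)) stop("first symbol must be a nucleotide")
  cv <- .color_codes(substring(colors_with_primer, 2L))
  if (anyNA(cv)) stop("malformed color symbol; expected only 0-3 after the primer")
  b <- Reduce(bitwXor, cv, accumulate = TRUE, init = p)[-1L]
  paste(.CS_BASE[b + 1L], collapse = "")
}

#' Reverse a color string (reverse-complement in color space)
#'
#' Colors are invariant under complementation, so the color-space encoding of
#' the reverse complement of a sequence is simply the reverse of the
#' sequence's internal colors. This is how reads sequenced from the 3' end
#' (the second adapter orientation) are brought onto the same strand as 5'
#' reads before matching.
#'
#' @param colors Color string over `0`-`3`, without a primer base.
#' @return The reversed color string.
#' @export
reverse_complement_colors <- function(colors) {
  stopifnot(is.character(colors), length(colors) == 1L)
  if (nchar(colors) == 0L) return("")
  cv <- .color_codes(colors)
  if (anyNA(cv)) stop("colors must be over {0,1,2,3}")
  paste(rev(cv), collapse = "")
}

#' Internal colors of a nucleotide sequence
#'
#' The transitions *within* a sequence (between bases 1-2, 2-3, ...), i.e.
#' its color encoding with the anchor-dependent first color dropped. These
#' are the colors that are directly comparable between a read and a
#' reference window regardless of primer or adapter context.
#'
#' @param seq A single nucleotide sequence.
#' @return A color string of length `nchar(seq) - 1`.
#' @export
sequence_internal_colors <- function(seq) {
  substring(encode_colorspace(seq, "T"), 3L)
}

## ---- bulk (vectorised) codecs used by the simulator and trimmer ----

## base-code matrix (L x N) for N equal-length color strings + per-read primer
.decode_block <- function(colors, primers) {
  n <- length(colors)
  if (n == 0L) return(matrix(integer(0), 0, 0))
  L <- nchar(colors[1L])
  stopifnot(all(nchar(colors) == L))
  v <- utf8ToInt(paste(colors, collapse = "")) - 48L
  M <- matrix(v, nrow = L)
  p <- .CS_CODE[utf8ToInt(paste(primers, collapse = ""))]
  B <- matrix(0L, nrow = L, ncol = n)
  cur <- p
  for (i in seq_len(L)) {
    cur <- bitwXor(cur, M[i, ])
    B[i, ] <- cur
  }
  B
}

## encode a base-code matrix (L x N) into N color strings with primer code p
.encode_block <- function(B, primer_code) {
  L <- nrow(B); n <- ncol(B)
  if (n == 0L) return(character(0))
  C <- matrix(0L, nrow = L, ncol = n)
  C[1L, ] <- bitwXor(primer_code, B[1L, ])
  if (L > 1L)
    C[2:L, ] <- bitwXor(B[1:(L - 1L), , drop = FALSE], B[2:L, , drop = FALSE])
  s <- intToUtf8(as.vector(C) + 48L)
  substring(s, seq(1L, by = L, length.out = n), seq(L, by = L, length.out = n))
}

## base-code matrix -> sequences
.codes_to_seq <- function(B) {
  L <- nrow(B); n <- ncol(B)
  if (n == 0L) return(character(0))
  s <- intToUtf8(utf8ToInt(paste(.CS_BASE, collapse = ""))[as.vector(B) + 1L],
                 multiple = FALSE)
  substring(s, seq(1L, by = L, length.out = n), seq(L, by = L, length.out = n))
}

## ---- csfasta / qual IO ----

#' Construct a set of color-space reads
#'
#' The in-memory representation of csfasta/.qual records: one row per read
#' with the primer base, the color string (one color per sequenced base) and
#' a list-column of per-color integer quality values.
#'
#' @param read_id Character vector of read identifiers.
#' @param primer Character vector (recycled) of primer bases.
#' @param colors Character vector of color strings over `0`-`3`.
#' @param quals List of integer vectors, one quality per color; or `NULL`
#'   for quality-less reads.
#' @param direction `"from_5p"` or `"from_3p"` (recycled): the two
#'   adapter/sequencing orientations of the protocol.
#' @return A `data.frame` of class `color_reads`.
#' @export
color_reads <- function(read_id, primer, colors, quals = NULL,
                        direction = "from_5p") {
  n <- length(read_id)
  stopifnot(length(colors) == n)
  direction <- rep_len(as.character(direction), n)
  stopifnot(all(direction %in% c("from_5p", "from_3p")))
  if (is.null(quals)) quals <- rep(list(NULL), n)
  stopifnot(length(quals) == n)
  nc <- nchar(colors)
  nq <- vapply(quals, length, 0L)
  if (any(nq > 0L & nq != nc))
    stop("each read must carry one quality value per color")
  if (any(vapply(quals, function(q) length(q) > 0L && any(q < 0L), FALSE)))
    stop("quality values must be >= 0")
  df <- data.frame(read_id = as.character(read_id),
                   primer = rep_len(as.character(primer), n),
                   colors = as.character(colors),
                   stringsAsFactors = FALSE)
  df$quals <- quals
  df$direction <- direction
  class(df) <- c("color_reads", "data.frame")
  df
}

#' Read a csfasta file
#'
#' Parses SOLiD csfasta: `#`-prefixed comment lines are allowed, records are
#' `>id` followed by a primer base and colors on one line.
#'
#' @param path Path to the csfasta file.
#' @param qual_path Optional path to the matching `.qual` file
#'   (space-separated integers, one per color, same record order).
#' @param direction Sequencing orientation of the library
#'   (`"from_5p"` or `"from_3p"`).
#' @return A [color_reads()] data frame.
#' @export
read_csfasta <- function(path, qual_path = NULL, direction = "from_5p") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  hdr <- startsWith(lines, ">")
  if (length(lines) && !hdr[1L])
    stop("malformed csfasta in '", path, "': first record line must start with '>'")
  if (sum(hdr) != sum(!hdr))
    stop("malformed csfasta in '", path, "': header/sequence lines unpaired")
  ids <- sub("^>", "", lines[hdr])
  seqs <- lines[!hdr]
  primers <- substr(seqs, 1L, 1L)
  cols <- substring(seqs, 2L)
  bad <- grepl("[^0-3]", cols) | !(primers %in% .CS_BASE)
  if (any(bad))
    stop("malformed csfasta record '", ids[which(bad)[1L]], "' in '", path,
         "' (line ", which(!hdr)[which(bad)[1L]], " of records)")
  quals <- NULL
  if (!is.null(qual_path)) {
    ql <- readLines(qual_path)
    ql <- ql[!startsWith(ql, "#")]
    ql <- ql[nzchar(ql)]
    qh <- startsWith(ql, ">")
    qids <- sub("^>", "", ql[qh])
    if (!identical(qids, ids))
      stop("qual file '", qual_path, "' does not match csfasta record ids")
    quals <- lapply(strsplit(ql[!qh], " +"), as.integer)
  }
  color_reads(ids, primers, cols, quals, direction)
}

#' Write csfasta (and optionally .qual) files
#'
#' @param reads A [color_reads()] data frame.
#' @param path Output csfasta path.
#' @param qual_path Optional output `.qual` path.
#' @return Invisibly, `path`.
#' @export
write_csfasta <- function(reads, path, qual_path = NULL) {
  out <- character(2L * nrow(reads))
  out[c(TRUE, FALSE)] <- paste0(">", reads$read_id)
  out[c(FALSE, TRUE)] <- paste0(reads$primer, reads$colors)
  writeLines(out, path)
  if (!is.null(qual_path)) {
    qs <- vapply(reads$quals, paste, "", collapse = " ")
    qout <- character(2L * nrow(reads))
    qout[c(TRUE, FALSE)] <- paste0(">", reads$read_id)
    qout[c(FALSE, TRUE)] <- qs
    writeLines(qout, qual_path)
  }
  invisible(path)
}

## internal colors of stored reads (drop the primer-adjacent first color)
.read_internal_colors <- function(reads) {
  substring(reads$colors, 2L)
}

## construction without validation, for generators whose output is valid
## by construction
.new_color_reads <- function(read_id, primer, colors, quals, direction) {
  df <- data.frame(read_id = read_id,
                   primer = rep_len(primer, length(read_id)),
                   colors = colors, stringsAsFactors = FALSE)
  df$quals <- quals
  df$direction <- rep_len(direction, length(read_id))
  class(df) <- c("color_reads", "data.frame")
  df
}
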