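# Reference sequences + class-tagged features, ordered by the exclusive
# assignment hierarchy, with a color-space k-mer index over both strands.

#' Default exclusive-assignment hierarchy
#'
#' The order in which annotation classes claim a mapped read: a read
#' overlapping both a human miRNA and a tRNA is a miRNA read. Reads mapped
#' to the genome but overlapping no feature fall through to
#' `non_annotated`.
#'
#' @return Character vector of class names, highest priority first.
#' @export
default_hierarchy <- function() {
  c("miRNA_human", "miRNA_other_species", "transcript", "piRNA",
    "tRNA", "rRNA", "snoRNA", "other_ncRNA")
}

.RNA_CLASSES <- c("miRNA_human", "miRNA_other_species", "transcript",
                  "piRNA", "tRNA", "rRNA", "snoRNA", "other_ncRNA")

#' Load a reference catalog (genome FASTA + GFF3 annotations)
#'
#' Reads the reference contigs and a GFF3 whose features each carry an
#' `rna_class` attribute (one of the small RNA annotation classes), and
#' returns them bundled with the exclusive-assignment hierarchy.
#' Coordinates are 1-based inclusive throughout, following GFF3 and
#' GenomicRanges conventions.
#'
#' @param genome_fasta Path to the reference FASTA.
#' @param annotations_gff3 Path to the GFF3 file. Attributes used: `ID`,
#'   `Parent` (mature miRNA -> precursor), `rna_class`.
#' @param hierarchy Class priority order; must be a subset of the known
#'   classes with no repeats.
#' @return An object of class `annotation_catalog`: a list with `contigs`
#'   (a [Biostrings::DNAStringSet]), `features` (data frame with
#'   `feature_id`, `rna_class`, `contig`, `start`, `end`, `strand`,
#'   `parent`), `granges` (the same features as a
#'   [GenomicRanges::GRanges]) and `hierarchy`.
#' @export
load_catalog <- function(genome_fasta, annotations_gff3,
                         hierarchy = default_hierarchy()) {
  contigs <- Biostrings::readDNAStringSet(genome_fasta)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gff <- rtracklayer::import(annotations_gff3, format = "gff3")
  md <- S4Vectors::mcols(gff)
  n <- length(gff)
  if (n > 0L && is.null(md$rna_class))
    stop("GFF3 features must carry an 'rna_class' attribute")
  feature_id <- if (!is.null(md$ID)) as.character(md$ID) else
    paste0("feature_", seq_len(n))
  parent <- rep(NA_character_, n)
  if (!is.null(md$Parent)) {
    pl <- md$Parent
    has <- lengths(pl) > 0L
    parent[has] <- vapply(pl[has], function(x) as.character(x)[1L], "")
  }
  features <- data.frame(
    feature_id = feature_id,
    rna_class = if (n > 0L) as.character(md$rna_class) else character(0),
    contig = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff),
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    parent = parent,
    stringsAsFactors = FALSE)
  build_catalog(contigs, features, hierarchy)
}

#' Assemble a catalog from in-memory components
#'
#' Validation and construction shared by [load_catalog()] and the synthetic
#' reference generator.
#'
#' @param contigs A named [Biostrings::DNAStringSet] (or named character
#'   vector) of reference sequences.
#' @param features Data frame with columns `feature_id`, `rna_class`,
#'   `contig`, `start`, `end`, `strand` and optionally `parent`.
#' @param hierarchy Class priority order.
#' @return An `annotation_catalog` object; see [load_catalog()].
#' @export
build_catalog <- function(contigs, features,
                          hierarchy = default_hierarchy()) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  if (anyDuplicated(hierarchy) || !all(hierarchy %in% .RNA_CLASSES))
    stop("hierarchy must be distinct values among: ",
         paste(.RNA_CLASSES, collapse = ", "))
  if (is.null(features$parent)) features$parent <- NA_character_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad_class <- setdiff(unique(features$rna_class), .RNA_CLASSES)
  if (length(bad_class))
    stop("unknown rna_class value(s): ", paste(bad_class, collapse = ", "))
  missing_contig <- setdiff(unique(features$contig), names(contigs))
  if (length(missing_contig))
    stop("feature contig(s) not in reference: ",
         paste(missing_contig, collapse = ", "))
  if (nrow(features)) {
    clen <- Biostrings::width(contigs)[match(features$contig, names(contigs))]
    if (any(features$start < 1L | features$end > clen |
            features$start > features$end))
      stop("feature coordinates outside contig bounds")
    if (!all(features$strand %in% c("+", "-")))
      stop("feature strand must be '+' or '-'")
    has_par <- !is.na(features$parent)
    if (any(has_par)) {
      pi <- match(features$parent[has_par], features$feature_id)
      if (anyNA(pi))
        stop("parent feature(s) not present in catalog")
      ok <- features$contig[has_par] == features$contig[pi] &
        features$strand[has_par] == features$strand[pi] &
        features$start[has_par] >= features$start[pi] &
        features$end[has_par] <= features$end[pi]
      if (!all(ok))
        stop("parent features must span their children on the same contig/strand")
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand)
  names(gr) <- features$feature_id
  structure(list(contigs = contigs, features = features, granges = gr,
                 hierarchy = hierarchy),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("annotation_catalog:", length(x$contigs), "contig(s),",
      nrow(x$features), "feature(s)\n")
  if (nrow(x$features)) {
    tb <- table(x$features$rna_class)
    cat("  classes:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  cat("  hierarchy:", paste(x$hierarchy, collapse = " > "), "\n")
  invisible(x)
}

## internal colors of every contig, as character vector
.contig_internal_colors <- function(catalog) {
  vapply(as.character(catalog$contigs), sequence_internal_colors, "",
         USE.NAMES = FALSE)
}

#' Build a color-space k-mer index over both strands of the reference
#'
#' Every window of `k` consecutive internal colors of every contig, on both
#' strands, is retrievable with its origin. A window of `k` colors spans
#' `k + 1` bases; its reported position is the 1-based plus-strand
#' coordinate of the leftmost base of that window. On the minus strand the
#' key is the reversed plus-strand window (colors are
#' complement-invariant).
#'
#' @param catalog An `annotation_catalog`.
#' @param k Number of colors per key; `8 <= k <= 18`.
#' @return An object of class `color_index` (an environment keyed by color
#'   k-mer) supporting [query_color_index()].
#' @export
build_color_index <- function(catalog, k) {
  if (k < 8L) stop("k must be >= 8 (shorter keys index too densely)")
  if (k > 18L) stop("k must be <= 18 (the matching seed length)")
  env <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(key, contig, pos, strand) {
    hit <- data.frame(contig = contig, pos = pos, strand = strand,
                      stringsAsFactors = FALSE)
    env[[key]] <- if (is.null(env[[key]])) hit else rbind(env[[key]], hit)
  }
  cols <- .contig_internal_colors(catalog)
  for (ci in seq_along(cols)) {
    s <- cols[ci]
    n <- nchar(s)
    if (n < k) next
    nm <- names(catalog$contigs)[ci]
    starts <- seq_len(n - k + 1L)
    fwd <- substring(s, starts, starts + k - 1L)
    rvs <- vapply(fwd, function(x) paste(rev(strsplit(x, "")[[1L]]),
                                         collapse = ""), "",
                  USE.NAMES = FALSE)
    for (i in starts) {
      add(fwd[i], nm, i, "+")
      add(rvs[i], nm, i, "-")
    }
  }
  structure(list(env = env, k = k), class = "color_index")
}

#' Query the color-space k-mer index
#'
#' @param index A `color_index` from [build_color_index()].
#' @param colors A color string of exactly `k` colors (the colors as read
#'   along the queried strand).
#' @return A data frame with columns `contig`, `pos` (1-based plus-strand
#'   coordinate of the leftmost base of the `k + 1`-base window) and
#'   `strand`; zero rows when the k-mer is absent.
#' @export
query_color_index <- function(index, colors) {
  stopifnot(inherits(index, "color_index"))
  if (nchar(colors) != index$k)
    stop("query must have exactly k = ", index$k, " colors")
  hit <- index$env[[colors]]
  if (is.null(hit))
    hit <- data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  hit
}
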