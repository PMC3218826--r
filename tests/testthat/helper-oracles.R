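# Independent oracles and small fixture builders shared by the tests.

## random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

## literal brute-force color-space matcher: every offset, both strands,
## mismatch budget applied directly to the internal colors
oracle_match_one <- function(internal, contigs, seed_len = 18L,
                             smax = 1L, tmax = 2L) {
  s <- as.integer(strsplit(internal, "")[[1L]])
  L <- length(s)
  out <- list()
  for (cn in names(contigs)) {
    gseq <- contigs[[cn]]
    nb <- nchar(gseq)
    gcols <- as.integer(strsplit(sequence_internal_colors(gseq), "")[[1L]])
    for (strand in c("+", "-")) {
      g <- if (strand == "+") gcols else rev(gcols)
      n <- length(g)
      if (L > n) next
      sp <- min(seed_len, L)
      noff <- n - L + 1L
      ms <- integer(noff); mt <- integer(noff)
      for (j in seq_len(L)) {
        neq <- s[j] != g[j:(j + noff - 1L)]
        if (j <= sp) ms <- ms + neq else mt <- mt + neq
      }
      ok <- which(ms <= smax & mt <= tmax)
      if (length(ok)) {
        j <- ok - 1L
        out[[length(out) + 1L]] <- data.frame(
          contig = cn,
          start = if (strand == "+") j + 1L else nb - j - L,
          end = if (strand == "+") j + 1L + L else nb - j,
          strand = strand, mm_seed = ms[ok], mm_tail = mt[ok],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mm_seed = integer(0), mm_tail = integer(0)))
  do.call(rbind, out)
}

## canonical sort for hit tables so implementation and oracle compare
sort_hits <- function(h) {
  h <- h[order(h$contig, h$start, h$strand, h$mm_seed, h$mm_tail), ,
         drop = FALSE]
  rownames(h) <- NULL
  h[, c("contig", "start", "end", "strand", "mm_seed", "mm_tail")]
}

## flip ncolors randomly chosen colors of a color string
corrupt_colors <- function(colors, ncolors) {
  cv <- as.integer(strsplit(colors, "")[[1L]])
  pos <- sample(length(cv), ncolors)
  cv[pos] <- (cv[pos] + sample(1:3, ncolors, TRUE)) %% 4L
  paste(cv, collapse = "")
}

## tiny two-contig catalog with one feature per class used across tests
tiny_catalog <- function(seed = 99L) {
  set.seed(seed)
  g1 <- rand_dna(600)
  g2 <- rand_dna(300)
  feats <- data.frame(
    feature_id = c("pre-a", "mat-a-5p", "mat-a-3p", "trna-1", "pi-1",
                   "tx-1"),
    rna_class = c("miRNA_human", "miRNA_human", "miRNA_human", "tRNA",
                  "piRNA", "transcript"),
    contig = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(101L, 105L, 145L, 301L, 401L, 51L),
    end = c(170L, 126L, 166L, 372L, 428L, 250L),
    strand = c("+", "+", "+", "+", "-", "+"),
    parent = c(NA, "pre-a", "pre-a", NA, NA, NA),
    stringsAsFactors = FALSE)
  build_catalog(c(chr1 = g1, chr2 = g2), feats)
}

## read whose colors are the internal colors of a genomic window, with a
## dummy primer-adjacent first color prepended
window_read <- function(catalog, contig, start, end, id = "r1",
                        strand = "+", direction = "from_5p") {
  w <- substr(as.character(catalog$contigs[[contig]]), start, end)
  if (strand == "-")
    w <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
  internal <- sequence_internal_colors(w)
  if (direction == "from_3p")
    internal <- reverse_complement_colors(internal)
  color_reads(id, "T", paste0("0", internal), direction = direction)
}
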