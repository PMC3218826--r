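# Canonical miRNA seed-site scanning in 3'UTRs and hypergeometric
# enrichment of predicted targets among regulated genes.

#' Find canonical miRNA seed-match sites in a 3'UTR
#'
#' Scans the UTR (DNA sense strand) for the four canonical site types
#' defined by complementarity to the miRNA seed: `6mer` (exact complement
#' of miRNA bases 2-7), `7mer_A1` (6mer plus a target adenosine opposite
#' miRNA base 1 — the anchoring A at the site's 3' end), `7mer_m8`
#' (complement of bases 2-8), and `8mer` (7mer-m8 plus the A1). Sites
#' sharing the same 6mer core are reported once, at the strongest type.
#' Wobble (G:U) pairs are not allowed.
#'
#' @param mirna Mature miRNA sequence, 5'->3' (RNA or DNA; length >= 8).
#' @param utr 3'UTR sequence, DNA sense strand.
#' @param mirna_id,utr_id Optional identifiers carried into the result.
#' @return Data frame of class `seed_sites`: `utr_id`, `mirna_id`,
#'   `site_type`, `start`, `end` (1-based inclusive UTR coordinates),
#'   `site_seq`.
#' @export
find_seed_sites <- function(mirna, utr, mirna_id = "miRNA", utr_id = "utr") {
  mirna <- toupper(chartr("Uu", "Tt", mirna))
  utr <- toupper(chartr("Uu", "Tt", utr))
  if (nchar(mirna) < 8L) stop("miRNA must be at least 8 nt")
  if (grepl("[^ACGT]", mirna) || grepl("[^ACGT]", utr))
    stop("sequences must be over {A,C,G,T,U}")
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  core6 <- rc(substr(mirna, 2L, 7L))      # complement of seed bases 2-7
  m8 <- rc(substr(mirna, 8L, 8L))         # base pairing miRNA position 8
  hits <- Biostrings::matchPattern(core6, Biostrings::DNAString(utr))
  n_utr <- nchar(utr)
  rows <- lapply(seq_along(hits), function(i) {
    s <- Biostrings::start(hits)[i]       # 6mer core start
    e <- Biostrings::end(hits)[i]
    has_m8 <- s > 1L && substr(utr, s - 1L, s - 1L) == m8
    has_a1 <- e < n_utr && substr(utr, e + 1L, e + 1L) == "A"
    type <- if (has_m8 && has_a1) "8mer"
    else if (has_m8) "7mer_m8"
    else if (has_a1) "7mer_A1"
    else "6mer"
    st <- if (has_m8) s - 1L else s
    en <- if (has_a1) e + 1L else e
    data.frame(utr_id = utr_id, mirna_id = mirna_id, site_type = type,
               start = st, end = en,
               site_seq = substr(utr, st, en),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(utr_id = character(0), mirna_id = character(0),
               site_type = character(0), start = integer(0),
               end = integer(0), site_seq = character(0),
               stringsAsFactors = FALSE)
  class(out) <- c("seed_sites", "data.frame")
  out
}

#' Hypergeometric enrichment of predicted targets among regulated genes
#'
#' Tests whether genes carrying at least one predicted seed site are
#' over-represented in a regulated gene set, against a gene universe:
#' the upper hypergeometric tail of the observed overlap.
#'
#' @param targets Character vector: genes with >= 1 predicted site
#'   (subset of `universe`).
#' @param regulated Character vector: regulated genes (subset of
#'   `universe`).
#' @param universe Character vector: all assayed genes (non-empty).
#' @return List: `p_value` (P(overlap >= observed)), `fold_enrichment`
#'   (observed / expected overlap), `overlap`, `expected`.
#' @export
enrichment_test <- function(targets, regulated, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("universe must be non-empty")
  targets <- unique(targets); regulated <- unique(regulated)
  if (!all(targets %in% universe) || !all(regulated %in% universe))
    stop("targets and regulated sets must be subsets of the universe")
  N <- length(universe); K <- length(targets); n <- length(regulated)
  k <- length(intersect(targets, regulated))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  expected <- n * K / N
  list(p_value = p,
       fold_enrichment = if (expected > 0) k / expected else NA_real_,
       overlap = k, expected = expected)
}
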