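#' Read candidate-gene windows
#'
#' Reads gene coordinates from BED (0-based half-open, converted to
#' 1-based inclusive on read, gene names from the name column) or from a
#' TSV with columns `gene`, `chrom`, `start`, `end` already 1-based
#' inclusive.
#'
#' @param path file path; format chosen by extension (`.bed` vs anything
#'   else).
#' @return `data.frame` with columns `gene`, `chrom`, `start`, `end`.
#' @export
readGeneWindows <- function(path) {
  if (!file.exists(path)) .configError(paste("gene file not found:", path))
  if (tolower(file_ext(path)) == "bed") {
    gr <- import(path, format = "BED")
    data.frame(gene = if (!is.null(gr$name)) gr$name
                      else paste0("gene", seq_along(gr)),
               chrom = as.character(seqnames(gr)),
               start = start(gr), end = end(gr),
               stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "chrom", "start", "end")
    if (!all(need %in% names(tab)))
      .dataError("gene TSV needs columns gene, chrom, start, end")
    tab[, need]
  }
}

#' Candidate-gene proxy SNP assignment
#'
#' For each gene, selects the top-ranked (lowest interaction P) variant
#' within the gene body extended by `flank` bases on both sides as the
#' gene's proxy. Window bounds are inclusive; coordinates 1-based.
#' Chromosome names are normalised across the `chr` prefix convention.
#' Ties on P are broken by smaller position, then lexicographic id. Genes
#' whose window contains no variant are reported with a zero count and
#' `NA` proxy.
#'
#' @param results summary-statistics table with columns `chrom`, `pos`,
#'   `id`, `p` (as from [runGwis()]); rows with `NA` P are ignored.
#' @param genes gene windows as from [readGeneWindows()] (columns `gene`,
#'   `chrom`, `start`, `end`).
#' @param flank window extension in bases (default 10,000).
#' @return `data.frame`, one row per input gene: `gene`, `chrom`, `start`,
#'   `end`, `n_snps_in_window`, `proxy_id`, `proxy_pos`, `proxy_p`.
#' @export
assignGeneProxy <- function(results, genes, flank = 10000) {
  need <- c("chrom", "pos", "id", "p")
  if (!all(need %in% names(results)))
    .dataError("results need columns chrom, pos, id, p")
  if (!all(c("gene", "chrom", "start", "end") %in% names(genes)))
    .dataError("genes need columns gene, chrom, start, end")
  if (flank < 0) stop("flank must be non-negative")

  res <- results[!is.na(results$p), , drop = FALSE]
  vr <- GRanges(.normChrom(res$chrom), IRanges(res$pos, width = 1L))
  win <- GRanges(.normChrom(genes$chrom),
                 IRanges(pmax(1, genes$start - flank),
                         genes$end + flank))
  hits <- suppressWarnings(findOverlaps(win, vr))
  out <- data.frame(gene = genes$gene, chrom = genes$chrom,
                    start = genes$start, end = genes$end,
                    n_snps_in_window = 0L,
                    proxy_id = NA_character_, proxy_pos = NA_integer_,
                    proxy_p = NA_real_, stringsAsFactors = FALSE)
  for (gi in seq_len(nrow(genes))) {
    vi <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == gi]
    out$n_snps_in_window[gi] <- length(vi)
    if (!length(vi)) next
    cand <- res[vi, , drop = FALSE]
    cand <- cand[order(cand$p, cand$pos, cand$id), , drop = FALSE]
    out$proxy_id[gi] <- cand$id[1]
    out$proxy_pos[gi] <- cand$pos[1]
    out$proxy_p[gi] <- cand$p[1]
  }
  out
}
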