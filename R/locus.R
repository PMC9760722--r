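#' Locus window around a gene's exon span
#'
#' The gene's span runs from the start of its first exon to the end of its
#' last exon, regardless of transcript; the locus window extends that span by
#' `flank` bp on both sides, clamped to [1, chrom_len]. Coordinates are
#' 1-based inclusive throughout.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), all on one chromosome.
#' @param flank Flank size in bp; default 500000 (500 kb).
#' @param chrom_len Chromosome length for clamping.
#' @return List of class `gene_locus`: `chrom`, `exon_span` (start, end),
#'   `window` (start, end).
#' @examples
#' gene_window(data.frame(chrom = "chr1",
#'                        start = c(10000000, 10040000),
#'                        end = c(10010000, 10050000)),
#'             chrom_len = 2e8)
#' @export
gene_window <- function(exons, flank = 500000L, chrom_len) {
  if (!nrow(exons)) stop_gliprio("invalid_params", "no exons supplied")
  if (length(unique(exons$chrom)) != 1L) {
    stop_gliprio("inconsistent_annotation",
                 "exons span multiple chromosomes")
  }
  if (any(exons$start < 1) || any(exons$end < exons$start)) {
    stop_gliprio("invalid_params", "malformed exon intervals")
  }
  span <- c(start = min(exons$start), end = max(exons$end))
  window <- c(start = max(span[["start"]] - flank, 1),
              end = min(span[["end"]] + flank, chrom_len))
  structure(list(chrom = exons$chrom[1], exon_span = span, window = window),
            class = "gene_locus")
}

#' Locus window around a DNA methylation site
#'
#' @param pos 1-based site position, within [1, chrom_len].
#' @param flank Flank size in bp; default 500000.
#' @param chrom_len Chromosome length for clamping.
#' @return Named vector (start, end), clamped.
#' @examples
#' site_window(1000000, chrom_len = 2e8)
#' @export
site_window <- function(pos, flank = 500000L, chrom_len) {
  if (pos < 1 || pos > chrom_len) {
    stop_gliprio("invalid_position", "pos outside [1, chrom_len]")
  }
  c(start = max(pos - flank, 1), end = min(pos + flank, chrom_len))
}

#' Per-gene locus windows from exon-level annotation
#'
#' Merges exons by gene id across transcripts, then applies [gene_window()]
#' per gene against the declared genome.
#'
#' @param annotation data.frame with columns `chrom`, `exon_start`,
#'   `exon_end`, `gene_id` (1-based inclusive, as produced by
#'   [generate_evidence_tables()] or [read_gene_bed()]).
#' @param genome data.frame (`chrom`, `length`), see [synthetic_genome()].
#' @param flank Flank size in bp.
#' @return data.frame: gene_id, chrom, span_start, span_end, window_start,
#'   window_end.
#' @export
gene_windows <- function(annotation, genome, flank = 500000L) {
  if (!nrow(annotation)) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      span_start = integer(0), span_end = integer(0),
                      window_start = integer(0), window_end = integer(0)))
  }
  len <- stats::setNames(genome$length, genome$chrom)
  out <- lapply(split(annotation, annotation$gene_id), function(a) {
    if (!a$chrom[1] %in% names(len)) {
      stop_gliprio("inconsistent_annotation",
                   "chromosome not in genome: ", a$chrom[1])
    }
    gl <- gene_window(data.frame(chrom = a$chrom, start = a$exon_start,
                                 end = a$exon_end),
                      flank = flank, chrom_len = len[[a$chrom[1]]])
    data.frame(gene_id = a$gene_id[1], chrom = gl$chrom,
               span_start = gl$exon_span[["start"]],
               span_end = gl$exon_span[["end"]],
               window_start = gl$window[["start"]],
               window_end = gl$window[["end"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Interval index over locus windows
#'
#' Builds a queryable index (backed by GenomicRanges) over a table of
#' 1-based inclusive windows; point queries return exactly the loci whose
#' window contains the position (both ends inclusive), equivalent to a linear
#' scan.
#'
#' @param windows data.frame with columns `chrom`, `window_start`,
#'   `window_end` plus any payload columns (e.g. `gene_id`).
#' @return An object of class `locus_index`.
#' @export
build_interval_index <- function(windows) {
  gr <- if (nrow(windows)) {
    GenomicRanges::GRanges(
      seqnames = windows$chrom,
      ranges = IRanges::IRanges(start = windows$window_start,
                                end = windows$window_end))
  } else {
    GenomicRanges::GRanges()
  }
  structure(list(gr = gr, windows = windows), class = "locus_index")
}

#' Query a locus index at a genomic position
#'
#' @param index A [build_interval_index()] object.
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @return The rows of the indexed window table whose window contains
#'   (chrom, pos).
#' @export
query_interval_index <- function(index, chrom, pos) {
  stopifnot(inherits(index, "locus_index"))
  if (!length(index$gr) ||
      !chrom %in% GenomeInfoDb::seqlevels(index$gr)) {
    return(index$windows[0, , drop = FALSE])
  }
  q <- GenomicRanges::GRanges(seqnames = chrom,
                              ranges = IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, index$gr)
  index$windows[S4Vectors::subjectHits(hits), , drop = FALSE]
}

#' Read gene annotation from a BED-like TSV
#'
#' On disk the annotation is 0-based half-open (BED convention) with columns
#' chrom, exon_start, exon_end, gene_id, transcript_id; internally the
#' package uses 1-based inclusive coordinates, so starts are shifted by +1 on
#' read.
#'
#' @param path Path to the TSV (with header).
#' @return data.frame with 1-based inclusive `exon_start`, `exon_end`.
#' @export
read_gene_bed <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "exon_start", "exon_end", "gene_id")
  missing <- setdiff(need, names(a))
  if (length(missing)) {
    stop_gliprio("invalid_params", "annotation lacks columns: ",
                 paste(missing, collapse = ", "))
  }
  a$exon_start <- a$exon_start + 1L
  a
}

#' Write gene annotation (or windows) as a BED-like TSV
#'
#' Converts internal 1-based inclusive intervals back to 0-based half-open.
#'
#' @param annotation data.frame with `exon_start`, `exon_end` (1-based).
#' @param path Output path.
#' @export
write_gene_bed <- function(annotation, path) {
  a <- annotation
  a$exon_start <- a$exon_start - 1L
  utils::write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
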