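#' Transcript annotation and strand-aware locus geometry
#'
#' Transcripts are represented as a `transcript_set`: a data frame with one
#' row per transcript (id, gene, chromosome, strand, span, summed exon
#' length, origin) and a list column `exons` holding the sorted, merged
#' exon intervals as two-column matrices. All coordinates are 1-based
#' closed, the GTF convention, so a single exon 100-300 has length 201.
#'
#' @name annotation
NULL

CIS_SUBTYPES <- c("Sense", "AntiSense", "Intronic", "AntiIntronic",
                  "Overlapping", "AntiOverlapping", "Upstream", "Downstream")
OVERLAP_SUBTYPES <- CIS_SUBTYPES[1:6]

new_transcript_set <- function(df) {
  stopifnot(is.data.frame(df))
  class(df) <- c("transcript_set", "data.frame")
  df
}

#' Build a transcript set from vectors of exon coordinates
#'
#' Constructor used by the readers, the simulator and tests. Exons are
#' sorted and merged per transcript; length is the sum of exon widths.
#'
#' @param transcript_id,gene_id,chrom,strand character vectors, one element
#'   per exon record.
#' @param start,end integer exon coordinates (1-based, closed).
#' @param origin `"known_mRNA"` or `"novel_candidate"`; recycled.
#' @return A `transcript_set` data frame with one row per transcript.
#' @export
transcript_set <- function(transcript_id, gene_id, chrom, strand, start, end,
                           origin = "novel_candidate") {
  n <- length(transcript_id)
  stopifnot(length(gene_id) == n, length(chrom) == n, length(strand) == n,
            length(start) == n, length(end) == n, all(end >= start))
  if (any(is.na(transcript_id)) || any(transcript_id == ""))
    stop("record lacking transcript_id at exon record(s): ",
         paste(which(is.na(transcript_id) | transcript_id == ""),
               collapse = ", "))
  if (any(is.na(gene_id)) || any(gene_id == ""))
    stop("record lacking gene_id at exon record(s): ",
         paste(which(is.na(gene_id) | gene_id == ""), collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop("unstranded or invalid strand ('.') records are not supported")
  origin <- rep_len(origin, n)
  ids <- unique(transcript_id)
  rows <- lapply(ids, function(id) {
    k <- transcript_id == id
    if (length(unique(chrom[k])) != 1L || length(unique(strand[k])) != 1L ||
        length(unique(gene_id[k])) != 1L)
      stop("inconsistent chrom/strand/gene_id within transcript ", id)
    ir <- IRanges::reduce(IRanges::IRanges(start[k], end[k]))
    list(transcript_id = id, gene_id = gene_id[k][1L],
         chrom = chrom[k][1L], strand = strand[k][1L],
         start = min(IRanges::start(ir)), end = max(IRanges::end(ir)),
         n_exons = length(ir), length = sum(IRanges::width(ir)),
         origin = origin[k][1L],
         exons = cbind(start = IRanges::start(ir), end = IRanges::end(ir)))
  })
  df <- data.frame(
    transcript_id = vapply(rows, `[[`, "", "transcript_id"),
    gene_id  = vapply(rows, `[[`, "", "gene_id"),
    chrom    = vapply(rows, `[[`, "", "chrom"),
    strand   = vapply(rows, `[[`, "", "strand"),
    start    = vapply(rows, `[[`, 0, "start"),
    end      = vapply(rows, `[[`, 0, "end"),
    n_exons  = vapply(rows, `[[`, 0L, "n_exons"),
    length   = vapply(rows, `[[`, 0, "length"),
    origin   = vapply(rows, `[[`, "", "origin"),
    stringsAsFactors = FALSE)
  df$exons <- lapply(rows, `[[`, "exons")
  new_transcript_set(df)
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x), "transcripts on",
      length(unique(x$chrom)), "chromosome(s)\n")
  print.data.frame(utils::head(x[, setdiff(names(x), "exons")], 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Read a GTF annotation into a transcript set
#'
#' Only exon records are used. Each exon must carry `gene_id` and
#' `transcript_id` attributes; records without them, or transcripts whose
#' exons disagree on chromosome or strand, raise an error naming the
#' offending record.
#'
#' @param path path to a GTF file.
#' @param known_ids optional character vector of transcript ids to mark as
#'   `origin = "known_mRNA"`.
#' @return A `transcript_set`.
#' @export
read_gtf <- function(path, known_ids = character()) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (!is.null(gr$type)) gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in ", path)
  tid <- if (is.null(gr$transcript_id)) rep(NA_character_, length(gr))
         else as.character(gr$transcript_id)
  gid <- if (is.null(gr$gene_id)) rep(NA_character_, length(gr))
         else as.character(gr$gene_id)
  ts <- transcript_set(tid, gid,
                       as.character(GenomicRanges::seqnames(gr)),
                       as.character(GenomicRanges::strand(gr)),
                       GenomicRanges::start(gr), GenomicRanges::end(gr))
  if (length(known_ids))
    ts$origin <- ifelse(ts$transcript_id %in% known_ids,
                        "known_mRNA", "novel_candidate")
  ts
}

ts_row <- function(ts, i) {
  if (is.character(i)) i <- match(i, ts$transcript_id)
  list(transcript_id = ts$transcript_id[i], chrom = ts$chrom[i],
       strand = ts$strand[i], start = ts$start[i], end = ts$end[i],
       exons = ts$exons[[i]])
}

#' Strand-aware geometry between an lncRNA locus and a coding gene
#'
#' Distances are nearest span-to-span gaps in bp (gene boundaries, not exon
#' boundaries): adjacent but non-overlapping spans (e.g. 1-10 and 11-20)
#' have gap 0 bases between them yet do not overlap, so `gap_bp` counts the
#' bases strictly between the two spans. Upstream/downstream orientation is
#' taken relative to the lncRNA and its strand.
#'
#' @param lnc,gene single transcripts: a one-row `transcript_set`, a row
#'   index/id into `ts`, or a list as returned internally.
#' @param ts optional `transcript_set` when `lnc`/`gene` are ids.
#' @return A list of class `locus_geometry`: `lncrna_id`, `gene_id`,
#'   `relation` (`no_overlap_upstream`, `no_overlap_downstream`, `overlap`),
#'   `gap_bp`, `exonic_overlap`, `fully_intronic`, `same_strand`.
#' @export
locus_geometry <- function(lnc, gene, ts = NULL) {
  as_row <- function(x) {
    if (inherits(x, "transcript_set")) {
      stopifnot(nrow(x) == 1L)
      ts_row(x, 1L)
    } else if (is.character(x) || is.numeric(x)) {
      stopifnot(!is.null(ts))
      ts_row(ts, x)
    } else x
  }
  a <- as_row(lnc); b <- as_row(gene)
  if (a$chrom != b$chrom)
    stop("locus_geometry requires both transcripts on one chromosome (",
         a$chrom, " vs ", b$chrom, ")")
  overlap <- a$start <= b$end && b$start <= a$end
  gap <- if (overlap) 0L else max(a$start, b$start) - min(a$end, b$end) - 1L
  relation <- if (overlap) "overlap" else {
    gene_after <- b$start > a$end
    downstream <- if (a$strand == "+") gene_after else !gene_after
    if (downstream) "no_overlap_downstream" else "no_overlap_upstream"
  }
  ex_a <- IRanges::IRanges(a$exons[, "start"], a$exons[, "end"])
  ex_b <- IRanges::IRanges(b$exons[, "start"], b$exons[, "end"])
  exonic <- length(IRanges::findOverlaps(ex_a, ex_b)) > 0L
  intronic <- FALSE
  if (overlap && nrow(b$exons) > 1L) {
    istart <- b$exons[-nrow(b$exons), "end"] + 1L
    iend <- b$exons[-1L, "start"] - 1L
    intronic <- any(a$start >= istart & a$end <= iend)
  }
  structure(list(lncrna_id = a$transcript_id, gene_id = b$transcript_id,
                 relation = relation, gap_bp = as.integer(gap),
                 exonic_overlap = exonic, fully_intronic = intronic,
                 same_strand = a$strand == b$strand),
            class = "locus_geometry")
}

#' Positional subtype of a cis lncRNA-gene pair
#'
#' Overlapping pairs partition into six subtypes by precedence: any exonic
#' overlap gives Sense/AntiSense; else a span fully inside one intron gives
#' Intronic/AntiIntronic; else Overlapping/AntiOverlapping. Strand agreement
#' selects the non-Anti form. Non-overlapping pairs within `window` bp are
#' Upstream or Downstream of the lncRNA locus by its strand.
#'
#' @param geom a `locus_geometry`.
#' @param window maximum span-to-span gap (bp) for the non-overlap labels.
#' @return One of `"Sense"`, `"AntiSense"`, `"Intronic"`, `"AntiIntronic"`,
#'   `"Overlapping"`, `"AntiOverlapping"`, `"Upstream"`, `"Downstream"`.
#' @export
classify_cis_subtype <- function(geom, window = 10000L) {
  if (geom$relation == "overlap") {
    base <- if (geom$exonic_overlap) "Sense"
            else if (geom$fully_intronic) "Intronic"
            else "Overlapping"
    if (geom$same_strand) base else paste0("Anti", base)
  } else {
    if (geom$gap_bp > window)
      stop("pair is beyond the cis window (gap ", geom$gap_bp, " > ",
           window, " bp); not a cis subtype")
    if (geom$relation == "no_overlap_upstream") "Upstream" else "Downstream"
  }
}

#' Tabulate geometry for many lncRNA-gene pairs
#'
#' @param ts a `transcript_set`.
#' @param lnc_ids,gene_ids equal-length id vectors defining the pairs.
#' @param window cis window in bp.
#' @return data frame with one row per same-chromosome pair: ids, relation,
#'   gap_bp, flags, and `subtype` (NA beyond the window).
#' @export
geometry_table <- function(ts, lnc_ids, gene_ids, window = 10000L) {
  stopifnot(length(lnc_ids) == length(gene_ids))
  chrom <- ts$chrom[match(lnc_ids, ts$transcript_id)]
  chrom_g <- ts$chrom[match(gene_ids, ts$transcript_id)]
  out <- lapply(seq_along(lnc_ids), function(i) {
    if (is.na(chrom[i]) || is.na(chrom_g[i]) || chrom[i] != chrom_g[i])
      return(NULL)
    g <- locus_geometry(lnc_ids[i], gene_ids[i], ts = ts)
    sub <- if (g$relation == "overlap" || g$gap_bp <= window)
      classify_cis_subtype(g, window) else NA_character_
    data.frame(lncrna_id = g$lncrna_id, gene_id = g$gene_id,
               relation = g$relation, gap_bp = g$gap_bp,
               exonic_overlap = g$exonic_overlap,
               fully_intronic = g$fully_intronic,
               same_strand = g$same_strand, subtype = sub,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
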