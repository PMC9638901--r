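#' Alignment-record filter
#'
#' Keeps properly paired, uniquely mapped primary alignments: SAM FLAG in
#' the accepted set (83/163 and 99/147, the two orientations of a proper
#' pair) and mapping quality at least \code{mapq_min}.
#'
#' @param flag SAM FLAG value(s).
#' @param mapq mapping quality value(s).
#' @param allowed_flags accepted FLAG set (default c(83, 163, 99, 147)).
#' @param mapq_min minimum MAPQ (default 2).
#' @return logical keep/drop decision, vectorized.
#' @export
filterAlignment <- function(flag, mapq, allowed_flags = c(83L, 163L, 99L, 147L),
                            mapq_min = 2L) {
  flag %in% allowed_flags & !is.na(mapq) & mapq >= mapq_min
}

#' SNP mask construction
#'
#' Positions excluded from mutation counting (and from the covered-base
#' denominators): known variants would otherwise masquerade as
#' recoding-induced mismatches.
#'
#' @param contig character vector of contig names.
#' @param pos 1-based positions.
#' @return character vector of unique \code{"contig:pos"} keys.
#' @export
snpMask <- function(contig, pos) {
  unique(paste0(contig, ":", as.integer(pos)))
}

#' Read SNP positions from a VCF file into a mask
#'
#' Only the positions are consumed; genotypes and alleles are ignored.
#'
#' @param vcf_file path to a VCF file.
#' @return mask as from \code{\link{snpMask}}.
#' @export
readSnpMask <- function(vcf_file) {
  vcf <- VariantAnnotation::readVcf(vcf_file, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  snpMask(as.character(GenomicRanges::seqnames(rr)),
          GenomicRanges::start(rr))
}

#' Read gene models from GTF/GFF or BED12
#'
#' @param file annotation path; format guessed from the extension
#'   (\code{.gtf}/\code{.gff}/\code{.gff2}/\code{.gff3} or \code{.bed}).
#' @return list with \code{genes} (GRanges of gene spans, names = gene ids)
#'   and \code{exons} (GRangesList of exon intervals per gene).
#' @export
readGeneModels <- function(file) {
  ext <- tolower(tools::file_ext(file))
  gr <- rtracklayer::import(file)
  if (ext == "bed") {
    ids <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
    ex <- if (!is.null(gr$blocks)) {
      bl <- gr$blocks
      GenomicRanges::GRangesList(lapply(seq_along(gr), function(i)
        GenomicRanges::shift(
          GenomicRanges::GRanges(GenomicRanges::seqnames(gr)[i], bl[[i]],
                                 strand = GenomicRanges::strand(gr)[i]),
          GenomicRanges::start(gr)[i] - 1L)))
    } else as(gr, "GRangesList")
    names(ex) <- ids
  } else {
    ex_rows <- gr[gr$type == "exon"]
    if (!length(ex_rows)) ex_rows <- gr[gr$type == "gene"]
    ids <- as.character(ex_rows$gene_id)
    ex <- GenomicRanges::split(ex_rows, ids)
  }
  genes <- unlist(range(ex))
  .validate_gene_models(list(genes = genes, exons = ex))
}

.validate_gene_models <- function(models) {
  stopifnot(all(names(models$exons) == names(models$genes)))
  if (any(S4Vectors::elementNROWS(models$exons) == 0))
    stop("gene model with no exon intervals")
  models
}

## reference/query index pairs of the aligned (M/=/X) segments of a CIGAR
.aligned_positions <- function(cigar, pos) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  rpos <- pos; qpos <- 1L
  ref_idx <- integer(0); q_idx <- integer(0)
  for (k in seq_along(ops)) {
    op <- ops[k]; ln <- lens[k]
    if (op %in% c("M", "=", "X")) {
      ref_idx <- c(ref_idx, seq.int(rpos, rpos + ln - 1L))
      q_idx <- c(q_idx, seq.int(qpos, qpos + ln - 1L))
      rpos <- rpos + ln; qpos <- qpos + ln
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + ln
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + ln
    }
  }
  list(ref = ref_idx, query = q_idx)
}

#' Count strand-aware recoding mismatches in one alignment
#'
#' Counts, in transcript-strand space, the covered reference-T positions
#' (\code{n_U}) with their T-to-C mismatches (\code{y_TC}) and the covered
#' reference-G positions (\code{n_G}) with their G-to-A mismatches
#' (\code{y_GA}). For a minus-strand gene the logic is reverse-complemented:
#' reference A / A-to-G events count as U sites / T-to-C, and reference C /
#' C-to-T as G sites / G-to-A. Insertions and soft-clips are skipped;
#' positions in the SNP mask, positions below the base-quality floor and
#' positions listed in \code{exclude_ref_pos} (used for mate-overlap
#' deduplication) contribute to neither numerator nor denominator.
#'
#' @param seq read sequence (character).
#' @param cigar CIGAR string.
#' @param pos 1-based leftmost mapping position.
#' @param contig reference contig name.
#' @param reference named character vector or \code{DNAStringSet} of contig
#'   sequences.
#' @param strand gene strand, \code{"+"} or \code{"-"}.
#' @param qual optional base-quality string (Phred+33).
#' @param mask optional SNP mask from \code{\link{snpMask}}.
#' @param base_qual_min base-quality floor (default 20); ignored when
#'   \code{qual} is NULL.
#' @param exclude_ref_pos integer reference positions to skip entirely.
#' @return named integer vector \code{(n_U, n_G, y_TC, y_GA)} with the
#'   covered reference positions attached as attribute \code{"ref_pos"}.
#' @export
countMismatches <- function(seq, cigar, pos, contig, reference, strand = "+",
                            qual = NULL, mask = NULL, base_qual_min = 20L,
                            exclude_ref_pos = NULL) {
  if (is(reference, "DNAStringSet")) reference <- as.character(reference)
  if (!contig %in% names(reference))
    stop("contig '", contig, "' absent from the reference")
  ap <- .aligned_positions(cigar, pos)
  refseq <- strsplit(reference[[contig]], "")[[1]]
  if (length(ap$ref) && max(ap$ref) > length(refseq))
    stop("alignment runs past the end of contig '", contig, "'")
  rb <- refseq[ap$ref]
  qb <- strsplit(toupper(seq), "")[[1]][ap$query]
  keep <- rep(TRUE, length(ap$ref))
  if (!is.null(qual)) {
    q <- utf8ToInt(qual) - 33L
    keep <- keep & q[ap$query] >= base_qual_min
  }
  if (!is.null(mask))
    keep <- keep & !(paste0(contig, ":", ap$ref) %in% mask)
  if (!is.null(exclude_ref_pos))
    keep <- keep & !(ap$ref %in% exclude_ref_pos)
  rb <- rb[keep]; qb <- qb[keep]
  if (strand == "+") {
    u_site <- rb == "T"; g_site <- rb == "G"
    y_tc <- u_site & qb == "C"; y_ga <- g_site & qb == "A"
  } else {
    u_site <- rb == "A"; g_site <- rb == "C"
    y_tc <- u_site & qb == "G"; y_ga <- g_site & qb == "T"
  }
  out <- c(n_U = sum(u_site), n_G = sum(g_site),
           y_TC = sum(y_tc), y_GA = sum(y_ga))
  attr(out, "ref_pos") <- ap$ref[keep]
  out
}

## strand of the sequenced fragment implied by FLAG bits under a stranded
## protocol; NA when the library is unstranded
.fragment_strand <- function(flag, stranded) {
  if (stranded == "no") return(rep(NA_character_, length(flag)))
  rev_bit <- bitwAnd(flag, 16L) > 0L
  second <- bitwAnd(flag, 128L) > 0L
  plus <- xor(rev_bit, second)  # first-mate-forward fragments
  if (stranded == "reverse") plus <- !plus
  ifelse(plus, "+", "-")
}

#' Assign an aligned read to a gene
#'
#' A read falling within exactly one gene's span is assigned to it:
#' \code{exonic} if all its aligned blocks lie inside that gene's exon
#' intervals, \code{intronic} otherwise. Reads overlapping two or more gene
#' spans are \code{ambiguous} (dropped downstream); reads overlapping none
#' get an NA gene.
#'
#' @param blocks GRanges of the read's aligned blocks (one or more
#'   intervals; junction-spanning reads have several).
#' @param models gene models from \code{\link{readGeneModels}}.
#' @param fragment_strand optional fragment strand (\code{"+"}/\code{"-"});
#'   when given, only genes on that strand are candidates.
#' @return list \code{(gene_id, feature_class)}.
#' @export
assignGene <- function(blocks, models, fragment_strand = NA) {
  cand <- models$genes
  if (!is.na(fragment_strand))
    cand <- cand[as.character(GenomicRanges::strand(cand)) == fragment_strand]
  hits <- unique(names(cand)[S4Vectors::queryHits(
    GenomicRanges::findOverlaps(cand, blocks, ignore.strand = TRUE))])
  if (length(hits) == 0)
    return(list(gene_id = NA_character_, feature_class = "none"))
  if (length(hits) > 1)
    return(list(gene_id = NA_character_, feature_class = "ambiguous"))
  ex <- models$exons[[hits]]
  outside <- GenomicRanges::setdiff(blocks, ex, ignore.strand = TRUE)
  cls <- if (sum(GenomicRanges::width(outside)) == 0) "exonic" else "intronic"
  list(gene_id = hits, feature_class = cls)
}

#' Tally per-read recoding mismatches from a SAM alignment
#'
#' The tallying front end: reads a SAM file, keeps alignments passing
#' \code{\link{filterAlignment}}, assigns each read template to a gene,
#' and counts strand-aware T-to-C and G-to-A mismatches against the
#' reference with SNP masking and a base-quality floor. Paired mates with
#' the same name are combined into a single tally; reference positions
#' covered by both mates are counted once (first mate wins).
#'
#' @param sam_file path to a SAM (or BAM) file.
#' @param fasta_file path to the reference FASTA.
#' @param annotation_file gene annotation (GTF/GFF or BED12).
#' @param sample_id sample identifier recorded in the tallies.
#' @param vcf_file optional VCF whose positions are masked.
#' @param mapq_min,allowed_flags alignment filter settings
#'   (see \code{\link{filterAlignment}}).
#' @param base_qual_min base-quality floor for counting a position
#'   (default 20).
#' @param stranded library strandedness: \code{"no"} (default),
#'   \code{"forward"} or \code{"reverse"}; when stranded, gene candidates
#'   are restricted to the fragment strand.
#' @return per-read tally data.frame (one row per read template) with
#'   columns \code{read_id}, \code{sample_id}, \code{gene_id},
#'   \code{feature_class}, \code{n_U}, \code{n_G}, \code{y_TC},
#'   \code{y_GA}.
#' @export
tallyReads <- function(sam_file, fasta_file, annotation_file, sample_id,
                       vcf_file = NULL, mapq_min = 2L,
                       allowed_flags = c(83L, 163L, 99L, 147L),
                       base_qual_min = 20L,
                       stranded = c("no", "forward", "reverse")) {
  stranded <- match.arg(stranded)
  reference <- as.character(Biostrings::readDNAStringSet(fasta_file))
  names(reference) <- sub("\\s.*", "", names(reference))
  models <- readGeneModels(annotation_file)
  mask <- if (!is.null(vcf_file)) readSnpMask(vcf_file) else NULL

  bam <- if (grepl("\\.bam$", sam_file, ignore.case = TRUE)) sam_file
         else Rsamtools::asBam(sam_file, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
  gal <- GenomicAlignments::readGAlignments(
    bam, use.names = FALSE,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "mapq", "seq", "qual")))
  mc <- S4Vectors::mcols(gal)
  keep <- filterAlignment(mc$flag, mc$mapq, allowed_flags, mapq_min)
  gal <- gal[keep]; mc <- mc[keep, , drop = FALSE]
  if (!length(gal)) return(.empty_tally())
  frag_strand <- .fragment_strand(mc$flag, stranded)
  blocks <- GenomicAlignments::grglist(gal)

  ## one tally per template; mates processed in file order
  ord <- order(mc$qname)
  out <- vector("list", length(unique(mc$qname)))
  oi <- 0L
  i <- 1L
  qn <- mc$qname[ord]
  while (i <= length(ord)) {
    j <- i
    while (j < length(ord) && qn[j + 1L] == qn[i]) j <- j + 1L
    idx <- ord[i:j]
    idx <- idx[order(GenomicRanges::start(gal)[idx])]
    tpl_blocks <- unlist(blocks[idx])
    asn <- assignGene(tpl_blocks, models, frag_strand[idx[1L]])
    gstrand <- if (!is.na(asn$gene_id))
      as.character(GenomicRanges::strand(models$genes[asn$gene_id])) else "+"
    if (gstrand == "*") gstrand <- "+"
    tot <- c(n_U = 0L, n_G = 0L, y_TC = 0L, y_GA = 0L)
    used <- integer(0)
    for (k in idx) {
      cm <- countMismatches(
        as.character(mc$seq[k]), GenomicAlignments::cigar(gal)[k],
        GenomicRanges::start(gal)[k],
        as.character(GenomicRanges::seqnames(gal)[k]), reference,
        strand = gstrand, qual = as.character(mc$qual[k]), mask = mask,
        base_qual_min = base_qual_min, exclude_ref_pos = used)
      tot <- tot + cm
      used <- c(used, attr(cm, "ref_pos"))
    }
    oi <- oi + 1L
    out[[oi]] <- data.frame(
      read_id = qn[i], sample_id = sample_id, gene_id = asn$gene_id,
      feature_class = asn$feature_class,
      n_U = tot[["n_U"]], n_G = tot[["n_G"]],
      y_TC = tot[["y_TC"]], y_GA = tot[["y_GA"]],
      stringsAsFactors = FALSE)
    i <- j + 1L
  }
  res <- do.call(rbind, out[seq_len(oi)])
  rownames(res) <- NULL
  res
}

.empty_tally <- function() {
  data.frame(read_id = character(), sample_id = character(),
             gene_id = character(), feature_class = character(),
             n_U = integer(), n_G = integer(), y_TC = integer(),
             y_GA = integer(), stringsAsFactors = FALSE)
}
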