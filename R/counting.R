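#' Load gene or region annotation for counting
#'
#' Reads a GTF (Ensembl dialect, 1-based inclusive coordinates) or BED
#' (0-based half-open) annotation and returns, per feature, the union of its
#' intervals as a `GRangesList`.  For GTF, `exon` records are grouped by
#' `gene_id` and overlapping exons of a gene are merged, so counting sees
#' each gene as its exon union.  For BED, records are grouped by the name
#' field.  `GRanges` carries 1-based inclusive coordinates internally; both
#' dialects are converted on ingestion by `rtracklayer`.
#'
#' @param path annotation file path.
#' @param format `"auto"` (by extension), `"gtf"`, or `"bed"`.
#' @return a named `GRangesList`, one element per feature, reduced to
#'   disjoint intervals.  An empty file yields an empty list with a warning.
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
    else if (grepl("\\.(gtf|gff2?)$", path, ignore.case = TRUE)) "gtf"
    else stop("cannot infer annotation format from '", path,
              "'; pass format=", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(grep("^[^#[:space:]]", lines))) {
    warning("annotation file '", path, "' contains no records")
    return(GenomicRanges::GRangesList())
  }
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e)
                   stop("failed to parse '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  if (format == "gtf") {
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "exon"))
      gr <- gr[gr$type == "exon"]
    key <- S4Vectors::mcols(gr)$gene_id
    if (is.null(key))
      stop("GTF records lack a gene_id attribute", call. = FALSE)
  } else {
    key <- S4Vectors::mcols(gr)$name
    if (is.null(key))
      stop("BED records need a name field (column 4)", call. = FALSE)
  }
  GenomicRanges::reduce(S4Vectors::split(gr, key))
}

# Read alignments as per-read GRangesList of aligned blocks (CIGAR-aware),
# applying the eligibility filters.  SAM input is converted via asBam.
load_alignments <- function(path, min_mapq = 0, paired = FALSE) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
    path <- bam
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    mapqFilter = if (min_mapq > 0) as.integer(min_mapq) else NA_integer_)
  if (paired) {
    ga <- GenomicAlignments::readGAlignmentPairs(path, param = param)
  } else {
    ga <- GenomicAlignments::readGAlignments(path, param = param)
  }
  GenomicAlignments::grglist(ga)
}

flip_strand <- function(grl) {
  gr <- unlist(grl, use.names = FALSE)
  s <- GenomicRanges::strand(gr)
  levels_map <- c("+" = "-", "-" = "+", "*" = "*")
  GenomicRanges::strand(gr) <- levels_map[as.character(s)]
  IRanges::relist(gr, grl)
}

#' Count reads over gene features
#'
#' Assigns each read (or, for paired-end data, each fragment counted once)
#' to a gene when any aligned base overlaps the gene's exon union, and
#' discards reads that overlap exons of more than one gene as ambiguous.
#' Split reads are matched through their aligned CIGAR blocks, not the
#' start-end span.  Unmapped, secondary, supplementary and below-MAPQ
#' records are never counted.
#'
#' @param path SAM or BAM alignment file.
#' @param annotation `GRangesList` from [read_annotation()].
#' @param stranded `"no"` (ignore strand), `"forward"` (read strand must
#'   match the feature strand) or `"reverse"` (read strand is flipped before
#'   matching, for reverse-stranded protocols).
#' @param min_mapq minimum mapping quality; 0 keeps everything.
#' @param paired treat input as paired-end and count fragments.
#' @return named integer vector of per-feature counts, with attributes
#'   `ambiguous`, `unassigned` and `eligible` (total filtered reads), so
#'   that `sum(counts) + ambiguous + unassigned == eligible`.
#' @export
count_reads <- function(path, annotation, stranded = c("no", "forward",
                                                       "reverse"),
                        min_mapq = 0, paired = FALSE) {
  stranded <- match.arg(stranded)
  if (!file.exists(path))
    stop("alignment file '", path, "' does not exist", call. = FALSE)
  reads <- load_alignments(path, min_mapq = min_mapq, paired = paired)
  if (stranded == "reverse") reads <- flip_strand(reads)
  ov <- GenomicRanges::findOverlaps(reads, annotation,
                                    ignore.strand = (stranded == "no"))
  hits <- unique(data.frame(q = S4Vectors::queryHits(ov),
                            s = S4Vectors::subjectHits(ov)))
  ngenes_per_read <- table(hits$q)
  uniq <- as.integer(names(ngenes_per_read)[ngenes_per_read == 1L])
  assigned <- hits[hits$q %in% uniq, ]
  counts <- tabulate(assigned$s, nbins = length(annotation))
  names(counts) <- names(annotation)
  n_elig <- length(reads)
  n_amb <- sum(ngenes_per_read > 1L)
  structure(as.integer(counts),
            names = names(annotation),
            ambiguous = n_amb,
            unassigned = n_elig - n_amb - length(uniq),
            eligible = n_elig)
}

#' Build a count matrix from several alignment files
#'
#' Runs [count_reads()] on each file and binds the columns.
#'
#' @inheritParams count_reads
#' @param paths character vector of SAM/BAM files.
#' @param sample_names column names; defaults to file base names.
#' @param ... further arguments passed to [count_reads()].
#' @return gene-by-sample integer matrix.
#' @export
count_matrix <- function(paths, annotation, sample_names = NULL, ...) {
  if (is.null(sample_names))
    sample_names <- sub("\\.(sam|bam)$", "", basename(paths),
                        ignore.case = TRUE)
  m <- vapply(paths, function(p) count_reads(p, annotation, ...),
              integer(length(annotation)))
  colnames(m) <- sample_names
  m
}

#' Read a PRE/POST alternative-polyadenylation annotation
#'
#' The APA annotation is a BED file with paired records per gene named
#' `<gene>_PRE` (the shorter isoform's region) and `<gene>_POST` (the longer
#' isoform's extra extension).  Genes missing either member are skipped with
#' a warning.
#'
#' @param path BED file path.
#' @return a list with elements `pre` and `post` (`GRangesList` keyed by
#'   gene) and `geometry` (data frame `gene_id`, `l_pre`, `l_post` with
#'   total region lengths in bases).
#' @export
read_apa_annotation <- function(path) {
  grl <- read_annotation(path, format = "bed")
  nm <- names(grl)
  is_pre <- grepl("_PRE$", nm)
  is_post <- grepl("_POST$", nm)
  if (any(!is_pre & !is_post))
    stop("APA BED names must end in _PRE or _POST; offending: ",
         paste(utils::head(nm[!is_pre & !is_post]), collapse = ", "),
         call. = FALSE)
  genes_pre <- sub("_PRE$", "", nm[is_pre])
  genes_post <- sub("_POST$", "", nm[is_post])
  common <- intersect(genes_pre, genes_post)
  orphan <- setdiff(union(genes_pre, genes_post), common)
  if (length(orphan))
    warning("skipping genes without both PRE and POST records: ",
            paste(orphan, collapse = ", "))
  pre <- grl[paste0(common, "_PRE")]
  post <- grl[paste0(common, "_POST")]
  names(pre) <- names(post) <- common
  geometry <- data.frame(
    gene_id = common,
    l_pre = vapply(pre, function(g) sum(GenomicRanges::width(g)), numeric(1)),
    l_post = vapply(post, function(g) sum(GenomicRanges::width(g)),
                    numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(pre = pre, post = post, geometry = geometry)
}

#' Count reads over PRE and POST APA regions
#'
#' For each gene, `r_pre` counts reads overlapping the PRE region and
#' `r_post` counts reads overlapping the POST extension but not the same
#' gene's PRE region (reads straddling the boundary belong to the shorter
#' isoform's territory and are counted in PRE only).
#'
#' @inheritParams count_reads
#' @param apa a parsed APA annotation from [read_apa_annotation()].
#' @return a list with integer vectors `r_pre` and `r_post` named by gene.
#' @export
count_apa <- function(path, apa, stranded = c("no", "forward", "reverse"),
                      min_mapq = 0, paired = FALSE) {
  stranded <- match.arg(stranded)
  reads <- load_alignments(path, min_mapq = min_mapq, paired = paired)
  if (stranded == "reverse") reads <- flip_strand(reads)
  ig <- stranded == "no"
  ov_pre <- GenomicRanges::findOverlaps(reads, apa$pre, ignore.strand = ig)
  ov_post <- GenomicRanges::findOverlaps(reads, apa$post, ignore.strand = ig)
  key <- function(ov) paste(S4Vectors::queryHits(ov),
                            S4Vectors::subjectHits(ov))
  pre_pairs <- unique(key(ov_pre))
  post_pairs <- setdiff(unique(key(ov_post)), pre_pairs)
  ng <- length(apa$pre)
  r_pre <- tabulate(as.integer(sub("^\\S+ ", "", pre_pairs)), nbins = ng)
  r_post <- tabulate(as.integer(sub("^\\S+ ", "", post_pairs)), nbins = ng)
  list(r_pre = structure(r_pre, names = names(apa$pre)),
       r_post = structure(r_post, names = names(apa$post)))
}
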