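#' Read peak calls from a BED file
#'
#' Reads BED3+ records into a sorted `GRanges`. BED coordinates (0-based,
#' half-open) are converted to the 1-based closed convention of
#' \pkg{GenomicRanges} on read; all downstream interval arithmetic lives in
#' that convention and BED output converts back on write. Malformed records
#' (wrong column count, non-integer coordinates, start >= end) raise an error
#' naming the offending line.
#'
#' @param path Path to a BED file (>= 3 tab-separated columns).
#' @param sample_id Optional sample label stored in `metadata()$sample_id`;
#'   defaults to the file name without extension.
#' @return Sorted `GRanges`; column 5, when present, is kept as `score`.
#' @export
read_bed <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  if (length(lines) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nfield <- lengths(fields)
    if (any(nfield < 3)) {
      bad <- which(nfield < 3)[1]
      stop("malformed BED line ", bad, ": fewer than 3 columns")
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                   end != floor(end))
    if (length(bad) > 0) {
      stop("malformed BED line ", bad[1], ": non-integer coordinates")
    }
    bad <- which(start >= end)
    if (length(bad) > 0) {
      stop("malformed BED line ", bad[1], ": start >= end")
    }
    gr <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start + 1, end = end)
    )
    if (all(nfield >= 5)) {
      score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
      if (!any(is.na(score))) gr$score <- score
    }
    GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
    gr <- GenomicRanges::sort(gr)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]+$", "", basename(path))
  }
  S4Vectors::metadata(gr)$sample_id <- sample_id
  gr
}

#' Write intervals to a BED file
#'
#' Converts back to BED's 0-based half-open convention. A `score` (or the
#' column named by `score_col`, e.g. consensus occupancy) goes in column 5.
#'
#' @param gr `GRanges` to write.
#' @param path Output path.
#' @param score_col Metadata column written as the BED score; `NULL` for BED3.
#' @export
write_bed <- function(gr, path, score_col = "score") {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(score_col) && score_col %in%
        colnames(S4Vectors::mcols(gr))) {
    df$name <- "."
    df$score <- S4Vectors::mcols(gr)[[score_col]]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromosome sizes
#'
#' @param path Two-column TSV: chromosome name, length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chrom.sizes must have two columns")
  sizes <- as.numeric(df[[2]])
  if (any(is.na(sizes)) || any(sizes <= 0)) stop("chromosome lengths must be > 0")
  stats::setNames(sizes, df[[1]])
}

#' Gene models container
#'
#' Bundles gene bodies (a `GRanges` with a `gene_id` column and strand) with
#' their exon structure (a `GRangesList` parallel to the genes). The TSS is
#' the 5' end of the gene body: `start` for `+` genes, `end` for `-` genes.
#'
#' @param genes `GRanges` with `gene_id` metadata column and defined strand.
#' @param exons Optional `GRangesList` of exons, one element per gene, each
#'   inside its gene body and non-overlapping. Defaults to whole-gene exons.
#' @return Object of class `gene_models`.
#' @export
gene_models <- function(genes, exons = NULL) {
  if (length(genes) == 0) stop("gene models must be nonempty")
  if (is.null(genes$gene_id)) stop("genes need a 'gene_id' column")
  if (any(as.character(GenomicRanges::strand(genes)) == "*")) {
    stop("genes need explicit strand")
  }
  if (is.null(exons)) {
    exons <- methods::as(genes, "GRangesList")
  }
  if (length(exons) != length(genes)) {
    stop("exons must be parallel to genes")
  }
  names(exons) <- genes$gene_id
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @exportS3Method base::print
print.gene_models <- function(x, ...) {
  cat("gene_models with", length(x$genes), "genes on",
      length(unique(as.character(GenomicRanges::seqnames(x$genes)))),
      "chromosome(s)\n")
  invisible(x)
}

#' Read gene models from GTF or BED12
#'
#' GTF input goes through \pkg{rtracklayer} (gene and exon features); BED12
#' input parses block structure into exons. Coordinates are converted to the
#' internal 1-based closed convention.
#'
#' @param path Path to a `.gtf`/`.gff` or BED12 file.
#' @param format `"gtf"` or `"bed12"`; guessed from the extension by default.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.g[tf]f[0-9]?(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    genes <- gr[gr$type == "gene"]
    if (length(genes) == 0) {  # tolerate transcript-only GTFs
      genes <- gr[gr$type == "transcript"]
    }
    gid <- genes$gene_id
    exon_gr <- gr[gr$type == "exon"]
    exons <- GenomicRanges::split(exon_gr, factor(exon_gr$gene_id, levels = gid))
    exons <- methods::as(lapply(seq_along(genes), function(i) {
      e <- exons[[i]]
      if (length(e) == 0) genes[i] else GenomicRanges::reduce(e)
    }), "GRangesList")
    genes$gene_id <- gid
    return(gene_models(genes, exons))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("BED12 requires 12 columns")
  genes <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1, end = df[[3]]),
    strand = df[[6]],
    gene_id = df[[4]]
  )
  sizes <- strsplit(df[[11]], ",", fixed = TRUE)
  starts <- strsplit(df[[12]], ",", fixed = TRUE)
  exons <- methods::as(lapply(seq_len(nrow(df)), function(i) {
    bs <- as.numeric(starts[[i]])
    bw <- as.numeric(sizes[[i]])
    GenomicRanges::GRanges(
      seqnames = df[[1]][i],
      ranges = IRanges::IRanges(start = df[[2]][i] + bs + 1,
                                width = bw),
      strand = df[[6]][i]
    )
  }), "GRangesList")
  gene_models(genes, exons)
}

#' Annotation parameters
#'
#' Windows used for peak annotation and peak-to-gene assignment. The promoter
#' is the strand-oriented window `[TSS - promoter_upstream_bp,
#' TSS + promoter_downstream_bp)`; `downstream_bp` bounds the region past the
#' gene's 3' end still called "downstream"; `upstream_window_bp` is the
#' proximity window upstream of the TSS used when coupling peaks to target
#' genes.
#'
#' @param promoter_upstream_bp,promoter_downstream_bp Promoter window (bp).
#' @param downstream_bp 3' downstream window (bp).
#' @param upstream_window_bp Target-gene upstream window (bp), default 20 kb.
#' @return List of class `annotation_params`.
#' @export
annotation_params <- function(promoter_upstream_bp = 3000,
                              promoter_downstream_bp = 0,
                              downstream_bp = 3000,
                              upstream_window_bp = 20000) {
  p <- list(promoter_upstream_bp = promoter_upstream_bp,
            promoter_downstream_bp = promoter_downstream_bp,
            downstream_bp = downstream_bp,
            upstream_window_bp = upstream_window_bp)
  if (any(unlist(p) < 0)) stop("annotation windows must be >= 0")
  structure(p, class = "annotation_params")
}

#' Consensus peaks with sample occupancy
#'
#' Merges the union of all samples' peaks by single-linkage overlap (>= 1 bp)
#' into disjoint regions, counts for each merged region the number of distinct
#' samples contributing at least one overlapping peak (occupancy), and keeps
#' regions supported by at least `min_samples` samples. Identical intervals
#' within one sample are deduplicated before counting.
#'
#' @param peaksets List of `GRanges` (one per sample), or a `GRangesList`.
#' @param min_samples Minimum occupancy k (>= 1). k greater than the number
#'   of samples yields an empty result.
#' @return Sorted, disjoint `GRanges` with an `occupancy` metadata column.
#' @export
consensus_peaks <- function(peaksets, min_samples = 3L) {
  if (length(peaksets) == 0) stop("need at least one peakset")
  if (min_samples < 1) stop("min_samples must be >= 1")
  peaksets <- lapply(peaksets, function(g) unique(GenomicRanges::granges(g)))
  pooled <- do.call(c, unname(peaksets))
  merged <- GenomicRanges::reduce(GenomicRanges::sort(pooled),
                                  min.gapwidth = 0L)
  occupancy <- Reduce(`+`, lapply(peaksets, function(g) {
    as.integer(IRanges::overlapsAny(merged, g))
  }))
  merged$occupancy <- occupancy
  merged[occupancy >= min_samples]
}

#' Annotate peaks by genomic feature
#'
#' Assigns each peak, via its midpoint, to exactly one category with fixed
#' precedence promoter > exon > intron > downstream > distal intergenic.
#' "Intron" is the non-exonic portion of a gene body. Peaks on chromosomes
#' absent from the gene models fall through to distal intergenic.
#'
#' @param peaks `GRanges` of peaks.
#' @param models A [gene_models()] object.
#' @param params An [annotation_params()] object.
#' @return Factor of categories, parallel to `peaks`, with levels
#'   `promoter`, `exon`, `intron`, `downstream`, `distal_intergenic`.
#' @export
annotate_peaks <- function(peaks, models, params = annotation_params()) {
  stopifnot(inherits(models, "gene_models"))
  genes <- models$genes
  midpts <- midpoint_granges(peaks)
  prom <- GenomicRanges::promoters(
    genes,
    upstream = params$promoter_upstream_bp,
    downstream = params$promoter_downstream_bp
  )
  prom <- prom[IRanges::width(prom) > 0]
  exons <- unlist(models$exons, use.names = FALSE)
  down <- GenomicRanges::flank(genes, width = params$downstream_bp,
                               start = FALSE)
  down <- down[IRanges::width(down) > 0]
  cats <- rep("distal_intergenic", length(peaks))
  suppressWarnings({
    in_down <- IRanges::overlapsAny(midpts, down)
    in_body <- IRanges::overlapsAny(midpts, genes)
    in_exon <- IRanges::overlapsAny(midpts, exons)
    in_prom <- IRanges::overlapsAny(midpts, prom)
  })
  cats[in_down] <- "downstream"
  cats[in_body] <- "intron"
  cats[in_body & in_exon] <- "exon"
  cats[in_prom] <- "promoter"
  factor(cats, levels = c("promoter", "exon", "intron", "downstream",
                          "distal_intergenic"))
}

#' Genomic distribution of a peak set
#'
#' Fraction of peaks per annotation category; each peak counted once, and
#' the fractions sum to one.
#'
#' @inheritParams annotate_peaks
#' @return Named numeric vector of fractions over the category levels.
#' @export
genomic_distribution <- function(peaks, models,
                                 params = annotation_params()) {
  if (length(peaks) == 0) stop("empty peakset")
  cats <- annotate_peaks(peaks, models, params)
  table(cats) / length(peaks)
}

#' Per-chromosome enrichment of a peak group
#'
#' Upper-tail binomial test per chromosome: with n = number of group peaks and
#' p0 = the background fraction of peaks (or of genome length) on that
#' chromosome, p = P(X >= observed), X ~ Binomial(n, p0). Chromosomes with
#' group peaks but zero background peaks get p0 floored at
#' 1/(background size + 1) and are flagged.
#'
#' @param group_peaks `GRanges` of the peaks tested for enrichment.
#' @param background_peaks `GRanges` giving the background composition.
#' @param background `"peaks"` (fractions of the background peak set, default)
#'   or `"genome"` (fractions of chromosome length; requires `chrom_sizes`).
#' @param chrom_sizes Named lengths, required when `background = "genome"`.
#' @return data.frame with chrom, observed, n, p0, p_value, flagged.
#' @export
chromosome_enrichment <- function(group_peaks, background_peaks,
                                  background = c("peaks", "genome"),
                                  chrom_sizes = NULL) {
  background <- match.arg(background)
  if (length(group_peaks) == 0 || length(background_peaks) == 0) {
    stop("both peak sets must be nonempty")
  }
  gchr <- as.character(GenomicRanges::seqnames(group_peaks))
  bchr <- as.character(GenomicRanges::seqnames(background_peaks))
  chroms <- sort(unique(c(gchr, bchr)))
  n <- length(group_peaks)
  nb <- length(background_peaks)
  obs <- table(factor(gchr, levels = chroms))
  if (background == "peaks") {
    p0 <- as.numeric(table(factor(bchr, levels = chroms))) / nb
  } else {
    if (is.null(chrom_sizes)) stop("chrom_sizes required for genome background")
    if (!all(chroms %in% names(chrom_sizes))) {
      stop("chrom_sizes missing chromosomes: ",
           paste(setdiff(chroms, names(chrom_sizes)), collapse = ", "))
    }
    p0 <- chrom_sizes[chroms] / sum(chrom_sizes)
  }
  flagged <- p0 == 0 & obs > 0
  p0[flagged] <- 1 / (nb + 1)
  pv <- vapply(seq_along(chroms), function(i) {
    if (p0[i] <= 0 || p0[i] >= 1) {
      if (obs[i] == 0) 1 else as.numeric(p0[i] >= 1)
    } else {
      binomial_upper_tail(as.integer(obs[i]), n, p0[i])
    }
  }, numeric(1))
  data.frame(chrom = chroms, observed = as.integer(obs), n = n,
             p0 = as.numeric(p0), p_value = pv, flagged = as.logical(flagged),
             row.names = NULL)
}

#' RPKM normalization
#'
#' Reads per kilobase of region per million sequenced reads:
#' `RPKM[i, j] = count[i, j] / (length_i / 1000) / (libsize_j / 1e6)`.
#'
#' @param counts Region x sample count matrix (counts >= 0).
#' @param peak_lengths Region lengths in bp (> 0).
#' @param library_sizes Per-sample totals (> 0).
#' @return Matrix of RPKM values, same shape as `counts`.
#' @export
rpkm_matrix <- function(counts, peak_lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (length(peak_lengths) != nrow(counts) ||
        length(library_sizes) != ncol(counts)) {
    stop("dimension mismatch between counts, lengths and library sizes")
  }
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(peak_lengths <= 0)) stop("peak lengths must be > 0")
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  sweep(counts / (peak_lengths / 1000), 2, library_sizes / 1e6, "/")
}

#' Assign peaks to proximal target genes
#'
#' A peak is assigned to a gene if it overlaps the gene body or the
#' strand-oriented window of `upstream_window_bp` (default 20 kb) ending at
#' the transcription start site. One peak may map to several genes and
#' several peaks to one gene; the induced gene list is deduplicated and
#' sorted.
#'
#' @inheritParams annotate_peaks
#' @return List with `assignments` (data.frame of peak index / gene_id pairs)
#'   and `genes` (sorted unique target gene ids).
#' @export
assign_peaks_to_genes <- function(peaks, models,
                                  params = annotation_params()) {
  stopifnot(inherits(models, "gene_models"))
  genes <- models$genes
  # gene body extended by the upstream window at its 5' side (strand-aware)
  proximal <- GenomicRanges::resize(
    genes, IRanges::width(genes) + params$upstream_window_bp, fix = "end"
  )
  proximal$gene_id <- genes$gene_id
  suppressWarnings(
    hits <- GenomicRanges::findOverlaps(peaks, proximal,
                                        ignore.strand = TRUE)
  )
  assignments <- data.frame(
    peak = S4Vectors::queryHits(hits),
    gene_id = proximal$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
  assignments <- unique(assignments)
  assignments <- assignments[order(assignments$peak, assignments$gene_id), ,
                             drop = FALSE]
  rownames(assignments) <- NULL
  list(assignments = assignments,
       genes = sort(unique(assignments$gene_id)))
}

# One-base ranges at interval midpoints. The midpoint is defined in BED
# space, floor((start0 + end0) / 2), so boundary semantics match the
# half-open convention exactly.
midpoint_granges <- function(gr) {
  mid0 <- floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2)
  GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                         IRanges::IRanges(mid0 + 1, width = 1))
}

# chrom:start-end (0-based half-open, BED-style) keys for region tables.
region_keys <- function(gr) {
  paste0(GenomicRanges::seqnames(gr), ":",
         GenomicRanges::start(gr) - 1, "-", GenomicRanges::end(gr))
}
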