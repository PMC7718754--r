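# File-format I/O.  Sequence formats go through Biostrings, annotations
# through rtracklayer; tables are plain TSV with header rows.  All interval
# types are 0-based half-open in memory and converted at the file boundary.

# Accept a named character vector, a DNAStringSet, or a FASTA path.
load_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x)) {
    if (length(x) == 1 && is.null(names(x)) && file.exists(x)) {
      ss <- Biostrings::readDNAStringSet(x)
      out <- as.character(ss)
      names(out) <- sub("\\s.*$", "", names(ss))
      return(out)
    }
    if (is.null(names(x))) names(x) <- paste0("chr", seq_along(x))
    return(toupper(x))
  }
  rs_abort("cannot interpret genome input", "invalid_argument")
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write reads to FASTQ with constant Q40 qualities
#' @param reads Reads data frame (`read_id`, `seq`).
#' @param path Output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read shotgun reads from FASTA/FASTQ
#'
#' @param path FASTA or FASTQ file (plain or gzip); format is inferred from
#'   the extension.
#' @param species_code Species tag to stamp; when `NULL` it is parsed from
#'   the read-name prefix before the first underscore.
#' @return Reads data frame (`read_id`, `species_code`, `seq`).
#' @export
read_reads <- function(path, species_code = NULL) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  ids <- sub("\\s.*$", "", names(ss))
  if (is.null(species_code)) species_code <- sub("_.*$", "", ids)
  as_reads_df(ids, species_code, as.character(ss))
}

#' Read a synchronized pair of FASTQ files
#'
#' @param path1,path2 Mate files; read names must match after stripping the
#'   `/1` and `/2` suffixes, in order.
#' @return List with reads data frames `mate1` and `mate2`.
#' @export
read_paired_fastq <- function(path1, path2) {
  m1 <- read_reads(path1)
  m2 <- read_reads(path2)
  b1 <- sub("/[12]$", "", m1$read_id)
  b2 <- sub("/[12]$", "", m2$read_id)
  if (length(b1) != length(b2) || any(b1 != b2)) {
    first <- if (length(b1) != length(b2)) {
      if (length(b1) > length(b2)) b1[length(b2) + 1L] else b2[length(b1) + 1L]
    } else b1[which(b1 != b2)[1]]
    rs_abort(sprintf("mate files are out of sync at read '%s'", first),
             "desynchronized_mates")
  }
  list(mate1 = m1, mate2 = m2)
}

#' Read a repeat exemplar library
#'
#' Headers follow the RepeatMasker convention `name#superfamily[/clade]`,
#' e.g. `opie#LTR/Copia`.  The superfamily is normalized to one of
#' gypsy/copia/DNA/satellite/other.
#'
#' @param x FASTA path or named character vector of sequences.
#' @return Data frame with `name`, `superfamily`, `classification`, `seq`,
#'   `is_ltr_exemplar` (TRUE when the name ends in `_LTR` or `-LTR`).
#' @export
read_repeat_library <- function(x) {
  seqs <- if (is.character(x) && length(x) == 1 && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else x
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    rs_abort("library records must be named", "invalid_argument")
  hdr <- names(seqs)
  name <- sub("#.*$", "", hdr)
  cls <- ifelse(grepl("#", hdr), sub("^[^#]*#", "", hdr), "other")
  data.frame(name = name,
             superfamily = normalize_superfamily(cls),
             classification = cls,
             seq = toupper(unname(seqs)),
             is_ltr_exemplar = grepl("[_-]LTR$", name, ignore.case = TRUE),
             stringsAsFactors = FALSE)
}

normalize_superfamily <- function(cls) {
  out <- rep("other", length(cls))
  out[grepl("gypsy", cls, ignore.case = TRUE)] <- "gypsy"
  out[grepl("copia", cls, ignore.case = TRUE)] <- "copia"
  out[grepl("^DNA", cls, ignore.case = TRUE)] <- "DNA"
  out[grepl("satellite", cls, ignore.case = TRUE)] <- "satellite"
  out
}

# interval data frame (0-based half-open) -> GRanges
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
}

#' Write gene and TE annotations to GFF3
#'
#' Genes get `type = gene`; TEs get `type = transposable_element` with
#' `Family`, `Superfamily` and `AgeMy` attributes taken from the truth
#' ledger when supplied.  Coordinates convert from 0-based half-open to
#' GFF3 1-based inclusive.
#'
#' @param intervals Interval data frame (`chrom`, `start`, `end`, `strand`,
#'   `feature_id`, `feature_class`).
#' @param path Output path.
#' @param truth Optional truth ledger to source TE attributes from.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(intervals, path, truth = NULL) {
  is_te <- grepl("^TE:", intervals$feature_class)
  type <- ifelse(is_te, "transposable_element", intervals$feature_class)
  attr_str <- paste0("ID=", intervals$feature_id)
  if (any(is_te)) {
    sf <- sub("^TE:", "", intervals$feature_class[is_te])
    extra <- paste0(";Superfamily=", sf)
    if (!is.null(truth)) {
      m <- match(intervals$feature_id[is_te], truth$te_id)
      extra <- paste0(";Family=", truth$family[m], extra,
                      ";AgeMy=", sprintf("%.4f", truth$age_my[m]))
    }
    attr_str[is_te] <- paste0(attr_str[is_te], extra)
  }
  lines <- c("##gff-version 3",
             sprintf("%s\trepeatscape\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     intervals$chrom, type,
                     intervals$start + 1L, intervals$end,
                     intervals$strand, attr_str))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene or TE annotations from GFF3 or BED
#'
#' GFF3 is parsed with rtracklayer and converted to 0-based half-open
#' coordinates; BED passes through as-is (already 0-based half-open).
#' The feature class is `gene` for gene-typed records and `TE:<superfamily>`
#' for transposable-element records (superfamily from a
#' `Superfamily`/`Family` attribute when present, otherwise `other`).
#'
#' @param path Annotation file (`.gff3`/`.gff` or `.bed`).
#' @return Interval data frame (`chrom`, `start`, `end`, `strand`,
#'   `feature_id`, `feature_class`).
#' @export
read_annotation <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path)) {
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    df <- data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
                     strand = if (ncol(bed) >= 6) bed[[6]] else "*",
                     feature_id = if (ncol(bed) >= 4) bed[[4]]
                                  else sprintf("feat%06d", seq_len(nrow(bed))),
                     feature_class = "gene", stringsAsFactors = FALSE)
    return(df)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  sf <- rep("other", length(gr))
  if (!is.null(md$Superfamily)) {
    known <- !is.na(md$Superfamily)
    sf[known] <- normalize_superfamily(as.character(md$Superfamily[known]))
  }
  cls <- ifelse(type %in% c("gene", "mRNA"), "gene", paste0("TE:", sf))
  id <- if (!is.null(md$ID)) as.character(md$ID)
        else sprintf("feat%06d", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             feature_id = id, feature_class = cls,
             stringsAsFactors = FALSE)
}

#' Write a data frame as TSV
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the insertion truth ledger as TSV
#' @param sim An `rs_genome_sim` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  write_tsv(sim$truth, path)
}
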