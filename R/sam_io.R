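#' Read alignments from SAM or BAM
#'
#' SAM text is parsed directly; BAM is read through Rsamtools when available.
#' Only the fields the fingerprinting model needs are retained.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A read-set data.frame with columns `qname`, `flag`, `chrom`,
#'   `pos`, `mapq`, `cigar`, `seq`, `qual`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("reading BAM requires the Rsamtools package")
    }
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    return(data.frame(qname = b$qname, flag = as.integer(b$flag),
                      chrom = as.character(b$rname), pos = as.integer(b$pos),
                      mapq = as.integer(b$mapq), cigar = b$cigar,
                      seq = as.character(b$seq), qual = as.character(b$qual),
                      stringsAsFactors = FALSE))
  }
  read_sam(path)
}

#' Read a SAM text file into a read-set data.frame
#' @param path SAM path.
#' @return Read-set data.frame (see [read_alignments()]).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(qname = character(), flag = integer(),
                      chrom = character(), pos = integer(), mapq = integer(),
                      cigar = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 11L)) {
    stop("malformed SAM record at line ", which(lengths(f) < 11L)[1])
  }
  g <- function(i) vapply(f, `[[`, "", i)
  data.frame(qname = g(1), flag = as.integer(g(2)), chrom = g(3),
             pos = as.integer(g(4)), mapq = as.integer(g(5)), cigar = g(6),
             seq = g(10), qual = g(11), stringsAsFactors = FALSE)
}

#' Write a read-set data.frame as SAM
#'
#' Emits a minimal valid SAM with `@HD`/`@SQ` headers covering the contigs
#' present; mate fields are filled with placeholders (`*`, 0) since the
#' fingerprinting model only uses qname grouping, flags, position and bases.
#'
#' @param reads Read-set data.frame.
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths; defaulted
#'   from the rightmost read end per contig.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(reads, path, contig_lengths = NULL) {
  contigs <- unique(reads$chrom)
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(contigs, function(c_) {
      i <- reads$chrom == c_
      max(reads$pos[i] + nchar(reads$seq[i]))
    }, numeric(1))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", contigs,
                       as.integer(contig_lengths[contigs]))), con)
  if (nrow(reads)) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                       reads$qname, reads$flag, reads$chrom, reads$pos,
                       reads$mapq, reads$cigar, reads$seq, reads$qual), con)
  }
  invisible(path)
}
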