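#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()].
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param width Line wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write paired reads to two FASTQ files
#'
#' Phred+33 with a fixed quality character for every simulated base.
#'
#' @param r1,r2 Character vectors of mate-1 / mate-2 sequences.
#' @param path1,path2 Output files.
#' @param ids Read identifiers (without the /1, /2 suffix).
#' @param quality_char Single quality character (default "I", Q40).
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(r1, r2, path1, path2,
                              ids = sprintf("read_%06d", seq_along(r1)),
                              quality_char = "I") {
  stopifnot(length(r1) == length(r2), length(ids) == length(r1))
  write_one <- function(reads, suffix, path) {
    if (length(reads) == 0L) {
      writeLines(character(0), path)
      return(invisible(NULL))
    }
    qual <- vapply(nchar(reads), function(n) strrep(quality_char, n), character(1))
    writeLines(as.vector(rbind(paste0("@", ids, suffix), reads, "+", qual)), path)
  }
  write_one(r1, "/1", path1)
  write_one(r2, "/2", path2)
  invisible(c(path1, path2))
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (uncompressed).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(setNames(character(0), character(0)))
  stopifnot(length(lines) %% 4L == 0L)
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  ids <- sub("\\s.*$", "", ids)
  setNames(lines[seq(2L, length(lines), by = 4L)], ids)
}

#' Write BED annotation (0-based half-open)
#'
#' @param annotation Data frame with columns `gene_id`, `start`, `end`,
#'   `strand` (0-based half-open coordinates).
#' @param chrom Chromosome/contig name used in column 1.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(annotation, chrom, path) {
  df <- data.frame(chrom = chrom,
                   start = annotation$start,
                   end = annotation$end,
                   name = annotation$gene_id,
                   score = 0L,
                   strand = annotation$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED annotation
#'
#' @param path BED file (>= 4 columns; strand taken from column 6 if present).
#' @return Data frame with `gene_id`, `start`, `end`, `strand` (0-based
#'   half-open), plus `chrom`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(gene_id = df[[4]],
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    strand = if (ncol(df) >= 6) df[[6]] else "+",
                    chrom = df[[1]],
                    stringsAsFactors = FALSE)
  out
}

#' Write a variant table as minimal VCF
#'
#' Emits CHROM, 1-based POS, REF, ALT and an INFO field carrying depth (DP)
#' and alt fraction (AF). Rows with call `ref` or `no_call` are skipped.
#'
#' @param variants A `variant_table` (see [call_variants()]).
#' @param path Output file.
#' @param sample Sample name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample = "sample") {
  keep <- variants$call %in% c("variant", "heterozygous")
  v <- variants[keep, , drop = FALSE]
  header <- c("##fileformat=VCFv4.2",
              paste0("##source=ulvapop"),
              paste0("##sample=", sample),
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt allele fraction\">",
              "##INFO=<ID=HET,Number=0,Type=Flag,Description=\"Heterozygous call\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  reference <- attr(variants, "reference_id") %||% "ref"
  info <- sprintf("DP=%d;AF=%.4f%s", v$depth, v$alt_fraction,
                  ifelse(v$call == "heterozygous", ";HET", ""))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  reference, v$position + 1L, v$ref_allele, v$alt_allele, info)
  writeLines(c(header, body), path)
  invisible(path)
}
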