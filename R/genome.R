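#' Construct a circular genome
#'
#' A `circular_genome` holds a single DNA sequence with 1-based, inclusive
#' coordinates on the plus strand. Mitochondrial genomes are circular, so by
#' default position `length + 1` wraps to position 1; set `circular = FALSE`
#' for linear molecules such as long-PCR amplicons.
#'
#' @param sequence A single string over the alphabet A, C, G, T, N
#'   (lower case accepted, stored upper case).
#' @param name Identifier for the genome (FASTA header word).
#' @param circular Does the sequence wrap around the origin?
#'
#' @return An object of class `circular_genome` with fields `name`,
#'   `sequence`, and `circular`; `length()` returns the sequence length.
#' @examples
#' g <- circular_genome("ACGT", name = "toy")
#' length(g)
#' @export
circular_genome <- function(sequence, name = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    rlang::abort("genome sequence must be non-empty")
  }
  bad <- regmatches(sequence, regexpr("[^ACGTN]", sequence))
  if (length(bad) > 0L) {
    rlang::abort(sprintf("non-DNA character '%s' in sequence '%s'", bad, name))
  }
  structure(
    list(name = as.character(name), sequence = sequence,
         circular = isTRUE(circular)),
    class = "circular_genome"
  )
}

#' @export
length.circular_genome <- function(x) nchar(x$sequence)

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp (%s)\n", x$name, length(x),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a single-record FASTA file as a circular genome
#'
#' @param path Path to a FASTA file containing exactly one DNA record.
#' @param circular Treat the sequence as circular (default `TRUE`).
#' @return A [circular_genome()]; the name is the first word of the header.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("FASTA file not found: %s", path))
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    rlang::abort(sprintf("no FASTA records in %s", path))
  }
  if (length(set) > 1L) {
    rlang::abort(sprintf("multiple records (%d) in %s; expected one genome",
                         length(set), path))
  }
  name <- strsplit(names(set)[1], "\\s+")[[1]][1]
  circular_genome(as.character(set[[1]]), name = name, circular = circular)
}

#' Write a circular genome to FASTA
#'
#' @param genome A [circular_genome()].
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "circular_genome"))
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$name
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# wrap 1-based positions onto [1, L]
wrap_pos <- function(pos, L) ((pos - 1L) %% L) + 1L

genome_chars <- function(genome) strsplit(genome$sequence, "", fixed = TRUE)[[1]]

#' Enumerate CpG sites on both strands
#'
#' Every cytosine in CG dinucleotide context is reported: a plus-strand site
#' is a C immediately followed by G; a minus-strand site is the cytosine of
#' the complementary strand, which sits opposite the plus-strand G and is
#' reported at that G's plus-strand coordinate. For circular genomes the
#' junction dinucleotide (last base, first base) is included, so a CG spanning
#' the origin yields sites at positions `L` (+) and 1 (-). N bases never form
#' sites.
#'
#' @param genome A [circular_genome()].
#' @return A tibble with columns `position` (1-based plus-strand coordinate of
#'   the cytosine), `strand` (`"+"` or `"-"`), and `context` (`"CpG"`),
#'   sorted by position then strand.
#' @examples
#' cpg_sites(circular_genome("ACGACG", circular = FALSE))
#' @export
cpg_sites <- function(genome) {
  stopifnot(inherits(genome, "circular_genome"))
  ch <- genome_chars(genome)
  L <- length(ch)
  nxt <- if (genome$circular) c(ch[-1L], ch[1L]) else c(ch[-1L], "")
  plus <- which(ch == "C" & nxt == "G")
  minus <- wrap_pos(plus + 1L, L)
  if (!genome$circular) minus <- plus + 1L  # never wraps when linear
  out <- tibble::tibble(
    position = c(plus, minus),
    strand = rep(c("+", "-"), c(length(plus), length(minus))),
    context = "CpG"
  )
  dplyr::arrange(out, .data$position, dplyr::desc(.data$strand))
}

#' Compare CpG profiles of two genotypes
#'
#' Genotypes sharing an rCRS-style coordinate system (equal length, no indels)
#' are compared site-by-site. `gained` holds sites present in `a` and absent
#' in `b`; `lost` the reverse. Point substitutions that create or destroy a CG
#' dinucleotide show up as a (+,-) site pair at adjacent coordinates.
#'
#' @param a,b [circular_genome()] objects of equal length.
#' @return A tibble of class `cpg_diff` with columns `position`, `strand`,
#'   `change` (`"gained"` or `"lost"`, relative to `a`), and attributes
#'   `genome_a`, `genome_b`.
#' @export
cpg_diff <- function(a, b) {
  stopifnot(inherits(a, "circular_genome"), inherits(b, "circular_genome"))
  if (length(a) != length(b)) {
    rlang::abort(paste0(
      "genomes differ in length (", length(a), " vs ", length(b), "); ",
      "indel-bearing genotypes are unsupported - compare equal-length ",
      "genotypes in a shared coordinate system"
    ))
  }
  sa <- cpg_sites(a)
  sb <- cpg_sites(b)
  gained <- dplyr::anti_join(sa, sb, by = c("position", "strand"))
  lost <- dplyr::anti_join(sb, sa, by = c("position", "strand"))
  out <- dplyr::bind_rows(
    dplyr::mutate(gained[c("position", "strand")], change = "gained"),
    dplyr::mutate(lost[c("position", "strand")], change = "lost")
  )
  out <- dplyr::arrange(out, .data$position, dplyr::desc(.data$strand))
  attr(out, "genome_a") <- a$name
  attr(out, "genome_b") <- b$name
  class(out) <- c("cpg_diff", class(out))
  out
}

#' Write CpG sites as TSV
#'
#' Two dialects: `"bed"` writes a BED-like table (chrom, 0-based start,
#' end, name, score, strand) and `"table"` writes the 1-based convention used
#' in per-site result tables (position, strand, context).
#'
#' @param sites Tibble from [cpg_sites()].
#' @param path Output path.
#' @param genome_name Sequence name for the BED chrom column.
#' @param format `"bed"` or `"table"`.
#' @return `path`, invisibly.
#' @export
write_cpg_sites <- function(sites, path, genome_name = "genome",
                            format = c("table", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    out <- tibble::tibble(
      chrom = genome_name,
      start = sites$position - 1L,
      end = sites$position,
      name = sites$context,
      score = 0L,
      strand = sites$strand
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(sites, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# reverse complement for plain character strings (vectorised)
revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
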