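# Non-directional bisulfite alignment, PCR deduplication, and per-cytosine
# methylation extraction for mitochondrial-scale circular genomes.

MODE_LETTERS <- c("CT_fwd", "CT_rc", "GA_fwd", "GA_rc")

#' Align paired non-directional bisulfite reads
#'
#' Each mate is C-to-T (and G-to-A) converted and matched against the
#' correspondingly converted reference via seed-and-extend ungapped alignment
#' over the circular sequence, so the alignment is blind to methylation
#' state. The unique best hit per mate is kept (fewest mismatches, strictly
#' better than the runner-up across all four conversion modes); ties leave
#' the mate unmapped. Mates must then align concordantly: complementary
#' conversion modes and a fragment length inside `insert_range`. The strand
#' class of the originating molecule (OT, OB, CTOT, CTOB) is recovered from
#' the mode combination.
#'
#' @param reads Tibble with `read_id`, `seq1`, `seq2` (see
#'   [read_fastq_pair()]), or a length-2 character vector of FASTQ paths.
#' @param genome A [circular_genome()].
#' @param max_mismatches Maximum converted-space mismatches per mate.
#' @param insert_range Allowed fragment length range in bp.
#' @param seed_length k-mer seed length for the reference index.
#' @return A tibble of class `aligned_fragments`: one row per read pair with
#'   `read_id`, `position` (1-based leftmost plus-strand coordinate),
#'   `fragment_length`, `strand_class`, `mismatches` (both mates summed),
#'   `unique`, `mapped`. Non-concordant or ambiguous pairs have
#'   `mapped = FALSE` and NA coordinates; only unique mapped fragments should
#'   proceed downstream.
#' @export
align_bisulfite <- function(reads, genome, max_mismatches = 10L,
                            insert_range = c(50L, 2000L), seed_length = 20L) {
  stopifnot(inherits(genome, "circular_genome"))
  if (is.character(reads) && length(reads) == 2L) {
    reads <- read_fastq_pair(reads[1], reads[2])
  }
  stopifnot(all(c("read_id", "seq1", "seq2") %in% names(reads)))
  n_runs <- gregexpr("N+", genome$sequence)[[1]]
  if (n_runs[1] > 0L) {
    maxrun <- max(attr(n_runs, "match.length"))
    minread <- min(nchar(c(reads$seq1, reads$seq2)))
    if (maxrun >= minread) {
      rlang::warn(sprintf(
        "genome contains an N-run of %d bases, longer than the reads; the region is unmappable",
        maxrun
      ))
    }
  }
  L <- length(genome)
  a1 <- .align_reads_cpp(reads$seq1, genome$sequence, genome$circular,
                         as.integer(seed_length), as.integer(max_mismatches))
  a2 <- .align_reads_cpp(reads$seq2, genome$sequence, genome$circular,
                         as.integer(seed_length), as.integer(max_mismatches))

  m1 <- a1$mode
  m2 <- a2$mode
  both <- !is.na(m1) & !is.na(m2) & a1$unique & a2$unique
  # complementary conversion modes: (1,2)->OT, (2,1)->CTOT, (3,4)->CTOB,
  # (4,3)->OB
  combo <- ifelse(both & m1 == 1L & m2 == 2L, "OT",
           ifelse(both & m1 == 2L & m2 == 1L, "CTOT",
           ifelse(both & m1 == 3L & m2 == 4L, "CTOB",
           ifelse(both & m1 == 4L & m2 == 3L, "OB", NA_character_))))
  r1_left <- combo %in% c("OT", "CTOB")
  left <- ifelse(r1_left, a1$start, a2$start)
  right <- ifelse(r1_left, a2$start, a1$start)
  right_len <- ifelse(r1_left, nchar(reads$seq2), nchar(reads$seq1))
  flen <- if (genome$circular) {
    ((right - left) %% L) + right_len
  } else {
    right - left + right_len
  }
  ok <- !is.na(combo) & !is.na(flen) &
    flen >= insert_range[1] & flen <= insert_range[2] &
    (genome$circular | (right >= left))
  ok[is.na(ok)] <- FALSE

  out <- tibble::tibble(
    read_id = reads$read_id,
    position = ifelse(ok, as.integer(left), NA_integer_),
    fragment_length = ifelse(ok, as.integer(flen), NA_integer_),
    strand_class = ifelse(ok, combo, NA_character_),
    mismatches = ifelse(ok, a1$mismatches + a2$mismatches, NA_integer_),
    unique = ok,
    mapped = ok
  )
  attr(out, "genome_name") <- genome$name
  attr(out, "ambiguity_rate") <- mean(!out$mapped)
  class(out) <- c("aligned_fragments", class(out))
  out
}

#' Remove PCR duplicates by fragment coordinates
#'
#' Fragments are grouped by (leftmost position, fragment length, strand
#' class); the first encountered representative of each group is kept, the
#' standard coordinate-based criterion for PCR duplicate removal. Unmapped or
#' ambiguous fragments are dropped.
#'
#' @param fragments Tibble from [align_bisulfite()].
#' @return The retained fragments, same columns.
#' @export
deduplicate <- function(fragments) {
  kept <- dplyr::filter(fragments, .data$mapped & .data$unique)
  dplyr::distinct(kept, .data$position, .data$fragment_length,
                  .data$strand_class, .keep_all = TRUE)
}

# per-site context and trinucleotide lookup for every cytosine on both strands
cytosine_annotation <- function(genome) {
  ch <- genome_chars(genome)
  L <- length(ch)
  dbl <- paste0(genome$sequence, genome$sequence,
                substr(genome$sequence, 1L, 2L))
  plus <- which(ch == "C")
  minus <- which(ch == "G")
  cg <- cpg_sites(genome)
  tbl <- tibble::tibble(
    position = c(plus, minus),
    strand = rep(c("+", "-"), c(length(plus), length(minus))))
  tbl <- dplyr::left_join(tbl, dplyr::mutate(cg, is_cpg = TRUE),
                          by = c("position", "strand"))
  tbl$context <- ifelse(is.na(tbl$is_cpg), "non-CpG", "CpG")
  tri_plus <- substring(dbl, plus, plus + 2L)
  tri_minus <- revcomp_chr(substring(dbl, pmax(minus - 2L, 1L), minus))
  if (genome$circular) {
    # wrap the upstream context of minus-strand cytosines at position <= 2
    low <- which(minus <= 2L)
    if (length(low) > 0L) {
      tri_minus[low] <- revcomp_chr(substring(dbl, minus[low] - 2L + L,
                                              minus[low] + L))
    }
  }
  tbl$trinucleotide <- c(tri_plus, tri_minus)
  tbl[c("position", "strand", "context", "trinucleotide")]
}

#' Extract per-cytosine methylation calls
#'
#' OT fragments call plus-strand cytosines (read C = methylated, read T =
#' unmethylated, anything else ignored); OB fragments call minus-strand
#' cytosines symmetrically. CTOT/CTOB fragments call the same original
#' strands as OT/OB through the complementary base pair (G = methylated,
#' A = unmethylated), which is what their aligned orientation exposes.
#' Positions covered by both mates of a fragment are counted once (first
#' mate's call wins; mates of a single molecule agree anyway unless a
#' sequencing error hit one of them). Contexts are classified CpG vs
#' non-CpG from the genome with circular wrap-around.
#'
#' @param fragments Tibble from [align_bisulfite()], ideally after
#'   [deduplicate()]. Unmapped rows are ignored.
#' @param reads The read tibble the fragments were aligned from.
#' @param genome The [circular_genome()] aligned against.
#' @return A tibble of class `cytosine_calls` with one row per cytosine on
#'   either strand: `position`, `strand`, `count_methylated`,
#'   `count_unmethylated`, `context` (`"CpG"`/`"non-CpG"`),
#'   `trinucleotide`.
#' @export
extract_methylation <- function(fragments, reads, genome) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- length(genome)
  ch <- genome_chars(genome)
  frag <- dplyr::filter(fragments, .data$mapped & .data$unique)
  frag <- dplyr::inner_join(frag, reads[c("read_id", "seq1", "seq2")],
                            by = "read_id")
  ann <- cytosine_annotation(genome)
  if (nrow(frag) == 0L) {
    out <- dplyr::mutate(ann, count_methylated = 0L, count_unmethylated = 0L)
    out <- out[c("position", "strand", "count_methylated",
                 "count_unmethylated", "context", "trinucleotide")]
    out <- dplyr::arrange(out, .data$position, dplyr::desc(.data$strand))
    attr(out, "genome_name") <- genome$name
    class(out) <- c("cytosine_calls", class(out))
    return(out)
  }
  m <- nrow(frag)
  bad <- frag$position < 1L | frag$position > L
  if (any(bad)) {
    rlang::abort("internal error: fragment position outside the genome")
  }
  r1_left <- frag$strand_class %in% c("OT", "CTOB")
  plus_call <- frag$strand_class %in% c("OT", "CTOT")
  # oriented (plus-strand direction) sequences and start positions per mate
  left_seq <- ifelse(r1_left, frag$seq1, frag$seq2)
  right_seq_raw <- ifelse(r1_left, frag$seq2, frag$seq1)
  right_seq <- revcomp_chr(right_seq_raw)
  left_start <- frag$position
  right_start <- frag$position + frag$fragment_length - nchar(right_seq)

  # first mate listed first so that its call wins at overlapping positions
  seg_seq <- c(ifelse(r1_left, left_seq, right_seq),
               ifelse(r1_left, right_seq, left_seq))
  seg_start <- c(ifelse(r1_left, left_start, right_start),
                 ifelse(r1_left, right_start, left_start))
  seg_frag <- rep(seq_len(m), 2L)

  ul <- unlist(strsplit(seg_seq, "", fixed = TRUE), use.names = FALSE)
  seg_id <- rep(seq_along(seg_seq), nchar(seg_seq))
  off <- sequence(nchar(seg_seq))
  gpos <- wrap_pos(seg_start[seg_id] + off - 1L, L)
  fidx <- seg_frag[seg_id]

  key <- (fidx - 1) * as.numeric(L) + gpos
  keep <- !duplicated(key)

  gch <- ch[gpos]
  pc <- plus_call[fidx]
  is_plus <- keep & pc & gch == "C" & (ul == "C" | ul == "T")
  is_minus <- keep & !pc & gch == "G" & (ul == "G" | ul == "A")
  calls <- tibble::tibble(
    position = c(gpos[is_plus], gpos[is_minus]),
    strand = rep(c("+", "-"), c(sum(is_plus), sum(is_minus))),
    meth = c(ul[is_plus] == "C", ul[is_minus] == "G")
  )
  counts <- dplyr::summarise(
    dplyr::group_by(calls, .data$position, .data$strand),
    count_methylated = sum(.data$meth),
    count_unmethylated = sum(!.data$meth), .groups = "drop"
  )
  out <- dplyr::left_join(ann, counts, by = c("position", "strand"))
  out$count_methylated[is.na(out$count_methylated)] <- 0L
  out$count_unmethylated[is.na(out$count_unmethylated)] <- 0L
  out <- out[c("position", "strand", "count_methylated", "count_unmethylated",
               "context", "trinucleotide")]
  out <- dplyr::arrange(out, .data$position, dplyr::desc(.data$strand))
  attr(out, "genome_name") <- genome$name
  class(out) <- c("cytosine_calls", class(out))
  out
}

#' Filter cytosine calls by minimum coverage
#'
#' Keeps sites covered by at least `min_reads` calls (methylated +
#' unmethylated), the validation depth used throughout the per-site
#' analyses (10 reads by default, inclusive).
#'
#' @param table A `cytosine_calls` tibble.
#' @param min_reads Minimum coverage (>= 1).
#' @return The filtered table.
#' @export
coverage_filter <- function(table, min_reads = 10L) {
  stopifnot(min_reads >= 1L)
  dplyr::filter(table,
                .data$count_methylated + .data$count_unmethylated >= min_reads)
}

#' Write a cytosine report TSV
#'
#' Bismark cytosine-report field order, no header: sequence name, position
#' (1-based), strand, count methylated, count unmethylated, context,
#' trinucleotide.
#'
#' @param table A `cytosine_calls` tibble.
#' @param path Output path.
#' @param genome_name Sequence name for the first column.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(table, path,
                                  genome_name = attr(table, "genome_name") %||% "genome") {
  out <- data.frame(
    name = genome_name, position = table$position, strand = table$strand,
    count_methylated = table$count_methylated,
    count_unmethylated = table$count_unmethylated,
    context = table$context, trinucleotide = table$trinucleotide
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cytosine report TSV
#'
#' Accepts the 7-column Bismark cytosine-report dialect and a minimal
#' 5-column variant (name, position, strand, count methylated, count
#' unmethylated); missing context/trinucleotide come back as `NA`.
#'
#' @param path Input path.
#' @return A `cytosine_calls` tibble.
#' @export
read_cytosine_report <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!ncol(raw) %in% c(5L, 7L)) {
    rlang::abort(sprintf(
      "cytosine report must have 5 or 7 tab-separated columns, found %d",
      ncol(raw)
    ))
  }
  out <- tibble::tibble(
    position = as.integer(raw[[2]]),
    strand = raw[[3]],
    count_methylated = as.integer(raw[[4]]),
    count_unmethylated = as.integer(raw[[5]]),
    context = if (ncol(raw) == 7L) raw[[6]] else NA_character_,
    trinucleotide = if (ncol(raw) == 7L) raw[[7]] else NA_character_
  )
  attr(out, "genome_name") <- raw[[1]][1]
  class(out) <- c("cytosine_calls", class(out))
  out
}
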