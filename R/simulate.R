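# Synthetic bisulfite libraries and qPCR experiments with known truth, so the
# alignment, extraction, normalisation and statistics stages are testable
# offline against the quantities they are supposed to recover.

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic mitochondrial reference genome
#'
#' Builds a random circular sequence that matches the summary statistics of
#' the human mitochondrial reference: 16,569 bp, rCRS-like base composition,
#' and exactly `n_cpg` CG dinucleotides counting the circular junction, so
#' that both-strand CpG enumeration yields `2 * n_cpg` sites (870 with the
#' defaults). This is a synthetic stand-in, not the rCRS sequence itself: use
#' [read_genome_fasta()] on the real NC_012920.1 record when sequence-level
#' fidelity matters.
#'
#' CG placement is controlled directly: the raw random sequence is stripped
#' of every CG, then `n_cpg` CG dinucleotides are planted at random,
#' non-adjacent positions outside `cpg_free`, a construction that cannot
#' create or destroy sites as a side effect.
#'
#' @param length Genome length in bp.
#' @param n_cpg Number of CG dinucleotides to plant (circular junction
#'   included in the count).
#' @param seed Integer seed.
#' @param name Genome name.
#' @param cpg_free Positions that must stay CpG-free (so genotype variants
#'   that create CpGs there can be layered on with [simulate_genotype()]).
#' @param base_freq Named sampling weights for A, C, G, T.
#' @return A [circular_genome()].
#' @export
synthetic_reference_genome <- function(length = 16569L, n_cpg = 435L,
                                       seed = 1L, name = "synthetic-mt-ref",
                                       cpg_free = integer(0),
                                       base_freq = c(A = 0.309, C = 0.313,
                                                     G = 0.131, T = 0.247)) {
  stopifnot(length >= 10L, n_cpg >= 0L, 3L * n_cpg < length)
  with_seed(seed, {
    ch <- sample(names(base_freq), length, replace = TRUE, prob = base_freq)
    # strip every CG (junction included); G -> A cannot create a new CG
    repeat {
      nxt <- c(ch[-1L], ch[1L])
      hit <- which(ch == "C" & nxt == "G")
      if (length(hit) == 0L) break
      ch[wrap_pos(hit + 1L, length)] <- "A"
    }
    # plant CGs at positions >= 2 apart (circularly), outside cpg_free
    blocked <- logical(length)
    blocked[wrap_pos(c(cpg_free, cpg_free - 1L, cpg_free + 1L), length)] <- TRUE
    chosen <- integer(0)
    for (p in sample.int(length)) {
      if (blocked[p]) next
      chosen <- c(chosen, p)
      blocked[wrap_pos(c(p - 1L, p, p + 1L), length)] <- TRUE
      if (length(chosen) == n_cpg) break
    }
    if (length(chosen) < n_cpg) {
      rlang::abort("could not place the requested number of CpG dinucleotides")
    }
    ch[chosen] <- "C"
    ch[wrap_pos(chosen + 1L, length)] <- "G"
    seq <- paste(ch, collapse = "")
    # independent sanity scan of the constructed sequence
    n_cg <- sum(gregexpr("CG", paste0(seq, substr(seq, 1L, 1L)),
                         fixed = TRUE)[[1]] > 0L)
    stopifnot(n_cg == n_cpg)
    circular_genome(seq, name = name)
  })
}

#' Apply point substitutions to a genome
#'
#' Produces a genotype variant of `base` with the given substitutions, the
#' way mitochondrial genotypes differ from one another at CpG-creating or
#' CpG-destroying positions. Length is unchanged; indels are unsupported.
#'
#' @param base A [circular_genome()].
#' @param substitutions A tibble/data frame with columns `position` (1-based)
#'   and `base` (the new base), or a named character vector
#'   (names = positions).
#' @param name Name for the derived genotype.
#' @param ... Unused.
#' @return A [circular_genome()] of the same length.
#' @export
simulate_genotype <- function(base, substitutions, name = paste0(base$name, "-variant"),
                              ...) {
  stopifnot(inherits(base, "circular_genome"))
  if (is.character(substitutions)) {
    substitutions <- tibble::tibble(
      position = as.integer(names(substitutions)),
      base = unname(substitutions)
    )
  }
  substitutions <- tibble::as_tibble(substitutions)
  ch <- genome_chars(base)
  L <- length(ch)
  if (nrow(substitutions) > 0L) {
    pos <- as.integer(substitutions$position)
    new <- toupper(substitutions$base)
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > L)) {
      rlang::abort(sprintf("substitution position out of range [1, %d]", L))
    }
    if (!all(new %in% c("A", "C", "G", "T", "N"))) {
      rlang::abort("substitution bases must be A, C, G, T or N")
    }
    same <- new == ch[pos]
    if (any(same)) {
      rlang::abort(sprintf(
        "substitution at position %d does not change the base (%s)",
        pos[which(same)[1]], new[which(same)[1]]
      ))
    }
    ch[pos] <- new
  }
  circular_genome(paste(ch, collapse = ""), name = name,
                  circular = base$circular)
}

#' Methylome specification
#'
#' Parameters for drawing a "true" methylome: CpG sites get Beta-distributed
#' methylation probabilities (mean 0.10 by default, echoing the ~10%
#' genome-wide CpG methylation regime of mitochondrial bisulfite data);
#' non-CpG cytosines sit at a constant near-zero level. `group_effects`
#' encodes per-group additive shifts at chosen sites, used to inject known
#' differential methylation.
#'
#' @param cpg_mean Mean of the Beta distribution for CpG sites.
#' @param cpg_concentration Beta concentration (shape1 + shape2).
#' @param non_cpg_level Constant methylation probability for non-CpG
#'   cytosines.
#' @param group_effects Named list: group label -> `list(sites = tibble with
#'   position/strand, shift = additive probability shift)`.
#' @return A list of class `methylome_spec`.
#' @export
methylome_spec <- function(cpg_mean = 0.10, cpg_concentration = 20,
                           non_cpg_level = 0.002, group_effects = list()) {
  stopifnot(cpg_mean >= 0, cpg_mean <= 1, cpg_concentration > 0,
            non_cpg_level >= 0, non_cpg_level <= 1)
  structure(
    list(cpg_mean = cpg_mean, cpg_concentration = cpg_concentration,
         non_cpg_level = non_cpg_level, group_effects = group_effects),
    class = "methylome_spec"
  )
}

#' Draw a per-site true methylome
#'
#' Every cytosine on both strands of the genome receives a methylation
#' probability: CpG sites from `Beta(mean * conc, (1 - mean) * conc)`
#' (degenerate means handled as constants), non-CpG cytosines at
#' `non_cpg_level`. If `group` names an entry of `spec$group_effects`, its
#' additive shift is applied at the listed sites and the result clamped to
#' \[0, 1\].
#'
#' @param genome A [circular_genome()].
#' @param spec A [methylome_spec()].
#' @param seed Integer seed.
#' @param group Optional group label selecting an entry of
#'   `spec$group_effects`.
#' @return A tibble with columns `position`, `strand`, `context`
#'   (`"CpG"`/`"non-CpG"`), `true_p`.
#' @export
draw_methylome <- function(genome, spec = methylome_spec(), seed = NULL,
                           group = NULL) {
  stopifnot(inherits(genome, "circular_genome"),
            inherits(spec, "methylome_spec"))
  ch <- genome_chars(genome)
  cg <- cpg_sites(genome)
  tbl <- tibble::tibble(
    position = c(which(ch == "C"), which(ch == "G")),
    strand = rep(c("+", "-"), c(sum(ch == "C"), sum(ch == "G")))
  )
  tbl <- dplyr::left_join(tbl, dplyr::mutate(cg, is_cpg = TRUE),
                          by = c("position", "strand"))
  tbl$context <- ifelse(is.na(tbl$is_cpg), "non-CpG", "CpG")
  tbl$is_cpg <- NULL
  tbl$context <- as.character(tbl$context)
  m <- spec$cpg_mean
  k <- spec$cpg_concentration
  n_cpg <- sum(tbl$context == "CpG")
  with_seed(seed, {
    p_cpg <- if (m <= 0) rep(0, n_cpg) else if (m >= 1) rep(1, n_cpg) else {
      stats::rbeta(n_cpg, shape1 = m * k, shape2 = (1 - m) * k)
    }
    tbl$true_p <- spec$non_cpg_level
    tbl$true_p[tbl$context == "CpG"] <- p_cpg
    if (!is.null(group) && !is.null(spec$group_effects[[group]])) {
      eff <- spec$group_effects[[group]]
      sites <- tibble::as_tibble(eff$sites)
      hit <- match(paste(tbl$position, tbl$strand),
                   paste(sites$position, sites$strand))
      tbl$true_p <- pmin(1, pmax(0, tbl$true_p + ifelse(is.na(hit), 0, eff$shift)))
    }
    dplyr::arrange(tbl, .data$position, dplyr::desc(.data$strand))
  })
}

#' Bisulfite read-simulation configuration
#'
#' Defaults mirror the sequencing regime of deep mitochondrial bisulfite
#' libraries: 150 bp paired-end reads, ~300 bp fragments, 500-fold mean
#' coverage, 99.5% conversion of unmethylated cytosines, 99.5% protection of
#' methylated cytosines, 0.1% per-base sequencing error, 5% PCR duplicates,
#' and a non-directional library in which the four bisulfite strand classes
#' (OT, OB, CTOT, CTOB) are sampled uniformly.
#'
#' @param read_length Read length in bp.
#' @param paired Paired-end reads (only `TRUE` is supported by the
#'   simulator).
#' @param insert_mean,insert_sd Fragment length distribution in bp.
#' @param mean_coverage Target mean read coverage (read bases per genome
#'   base).
#' @param conversion_efficiency Probability an unmethylated C reads as T.
#' @param methylation_protection Probability a methylated C reads as C.
#' @param seq_error Per-base substitution error rate.
#' @param duplicate_fraction Fraction of fragments emitted twice.
#' @param non_directional Sample all four strand classes (otherwise OT/OB
#'   only).
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(read_length = 150L, paired = TRUE,
                            insert_mean = 300, insert_sd = 50,
                            mean_coverage = 500,
                            conversion_efficiency = 0.995,
                            methylation_protection = 0.995,
                            seq_error = 0.001, duplicate_fraction = 0.05,
                            non_directional = TRUE) {
  probs <- c(conversion_efficiency, methylation_protection, seq_error,
             duplicate_fraction)
  stopifnot(all(probs >= 0), all(probs <= 1), mean_coverage > 0,
            read_length >= 20L, insert_mean >= read_length)
  structure(
    list(read_length = as.integer(read_length), paired = isTRUE(paired),
         insert_mean = insert_mean, insert_sd = insert_sd,
         mean_coverage = mean_coverage,
         conversion_efficiency = conversion_efficiency,
         methylation_protection = methylation_protection,
         seq_error = seq_error, duplicate_fraction = duplicate_fraction,
         non_directional = isTRUE(non_directional)),
    class = "read_sim_config"
  )
}

# substitute bases with probability `rate`, uniformly among the other three
add_seq_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  ul <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  id <- rep(seq_along(seqs), nchar(seqs))
  idx <- which(stats::runif(length(ul)) < rate & ul %in% c("A", "C", "G", "T"))
  if (length(idx) > 0L) {
    code <- match(ul[idx], c("A", "C", "G", "T"))
    code <- ((code - 1L + sample.int(3L, length(idx), replace = TRUE)) %% 4L) + 1L
    ul[idx] <- c("A", "C", "G", "T")[code]
  }
  vapply(split(ul, id), paste, character(1), collapse = "", USE.NAMES = FALSE)
}

#' Simulate a non-directional bisulfite-converted read set
#'
#' Fragments are sampled uniformly on the circle (or within `region` for
#' linear molecules such as long-PCR amplicons). Per molecule, each cytosine
#' on the originating strand is methylated with its site's probability from
#' `methylome`; unmethylated cytosines convert to T with
#' `conversion_efficiency`, methylated cytosines stay C with
#' `methylation_protection`. CTOT/CTOB molecules are the complements of
#' converted OT/OB molecules, so their reads carry the same methylation
#' signal on the complementary bases. Sequencing errors are applied last, and
#' a `duplicate_fraction` of fragments is emitted twice to exercise PCR
#' deduplication. Methylation states are drawn once per molecule, so
#' overlapping mates always agree at a site.
#'
#' @param genome A [circular_genome()].
#' @param methylome Tibble from [draw_methylome()] (columns `position`,
#'   `strand`, `true_p`).
#' @param config A [read_sim_config()].
#' @param seed Integer seed; the same seed reproduces the run byte for byte.
#' @param region Optional `c(start, end)` (1-based, inclusive): fragments are
#'   drawn from this linear interval and never cross its ends.
#' @param n_fragments Override the coverage-derived fragment count.
#' @param fastq Optional `c(r1_path, r2_path)` to write gzip- or plain-text
#'   FASTQ.
#' @param id_prefix Prefix for read identifiers.
#' @return A list of class `bisulfite_sim`: `reads` (tibble `read_id`,
#'   `seq1`, `seq2`), `sidecar` (per emitted fragment: `read_id`, `position`,
#'   `fragment_length`, `strand_class`, `duplicate` -- the origin record the
#'   aligner never sees), `truth` (per-site molecule counts `n_meth`,
#'   `n_unmeth` at read-covered positions after collapsing fragments that
#'   share a deduplication key, plus `true_p`), and `coverage` (achieved mean
#'   read coverage).
#' @export
simulate_bisulfite_reads <- function(genome, methylome,
                                     config = read_sim_config(), seed = NULL,
                                     region = NULL, n_fragments = NULL,
                                     fastq = NULL, id_prefix = "frag") {
  stopifnot(inherits(genome, "circular_genome"),
            inherits(config, "read_sim_config"))
  if (!config$paired) {
    rlang::abort("single-end simulation is not supported; set paired = TRUE")
  }
  L <- length(genome)
  RL <- config$read_length
  if (is.null(region)) {
    span_lo <- 1L
    span_hi <- L
    linear <- !genome$circular
  } else {
    stopifnot(length(region) == 2L, region[1] >= 1L, region[2] <= L,
              region[1] < region[2])
    span_lo <- as.integer(region[1])
    span_hi <- as.integer(region[2])
    linear <- TRUE
  }
  span <- span_hi - span_lo + 1L
  if (config$insert_mean > span) {
    rlang::abort("mean insert length exceeds the template length")
  }
  n <- if (is.null(n_fragments)) {
    max(1L, as.integer(round(config$mean_coverage * span / (2 * RL))))
  } else as.integer(n_fragments)

  with_seed(seed, {
    ins <- as.integer(round(stats::rnorm(n, config$insert_mean, config$insert_sd)))
    ins <- pmax(RL, pmin(span, ins))
    if (linear) {
      starts <- span_lo + floor(stats::runif(n) * (span - ins + 1L))
      starts <- as.integer(starts)
    } else {
      starts <- sample.int(L, n, replace = TRUE)
    }
    classes <- if (config$non_directional) {
      sample(c("OT", "OB", "CTOT", "CTOB"), n, replace = TRUE)
    } else {
      sample(c("OT", "OB"), n, replace = TRUE)
    }

    doubled <- paste0(genome$sequence, genome$sequence)
    frag_seq <- substring(doubled, starts, starts + ins - 1L)

    ul <- unlist(strsplit(frag_seq, "", fixed = TRUE), use.names = FALSE)
    fid <- rep.int(seq_len(n), ins)
    off <- sequence(ins)
    gpos <- wrap_pos(starts[fid] + off - 1L, L)

    # per-site probability lookup on each strand
    pplus <- numeric(L)
    pminus <- numeric(L)
    mp <- methylome[methylome$strand == "+", ]
    mm <- methylome[methylome$strand == "-", ]
    pplus[mp$position] <- mp$true_p
    pminus[mm$position] <- mm$true_p

    top_origin <- classes %in% c("OT", "CTOT")
    idxC <- which(top_origin[fid] & ul == "C")
    idxG <- which(!top_origin[fid] & ul == "G")

    methC <- stats::runif(length(idxC)) < pplus[gpos[idxC]]
    methG <- stats::runif(length(idxG)) < pminus[gpos[idxG]]

    conv <- config$conversion_efficiency
    prot <- config$methylation_protection
    ul[idxC] <- ifelse(methC,
                       ifelse(stats::runif(length(idxC)) < prot, "C", "T"),
                       ifelse(stats::runif(length(idxC)) < conv, "T", "C"))
    ul[idxG] <- ifelse(methG,
                       ifelse(stats::runif(length(idxG)) < prot, "G", "A"),
                       ifelse(stats::runif(length(idxG)) < conv, "A", "G"))
    conv_frag <- vapply(split(ul, fid), paste, character(1), collapse = "",
                        USE.NAMES = FALSE)

    # PCR duplicates: a fraction of molecules is emitted twice
    n_dup <- as.integer(round(config$duplicate_fraction * n))
    dup_of <- if (n_dup > 0L) sample.int(n, n_dup) else integer(0)
    emit <- c(seq_len(n), dup_of)
    dup_flag <- c(rep(FALSE, n), rep(TRUE, n_dup))

    first <- substring(conv_frag[emit], 1L, RL)
    last <- substring(conv_frag[emit], ins[emit] - RL + 1L, ins[emit])
    last_rc <- revcomp_chr(last)
    r1_left <- classes[emit] %in% c("OT", "CTOB")
    seq1 <- ifelse(r1_left, first, last_rc)
    seq2 <- ifelse(r1_left, last_rc, first)

    seq1 <- add_seq_errors(seq1, config$seq_error)
    seq2 <- add_seq_errors(seq2, config$seq_error)

    read_id <- sprintf("%s_%07d%s", id_prefix, emit,
                       ifelse(dup_flag, "_dup", ""))
    reads <- tibble::tibble(read_id = read_id, seq1 = seq1, seq2 = seq2)
    sidecar <- tibble::tibble(
      read_id = read_id,
      position = starts[emit],
      fragment_length = ins[emit],
      strand_class = classes[emit],
      duplicate = dup_flag
    )

    # truth: per-site molecule counts at read-covered positions, collapsing
    # fragments that share a deduplication key (position, length, class)
    keep_frag <- !duplicated(paste(starts, ins, classes))
    st_idx <- c(idxC, idxG)
    st <- tibble::tibble(
      position = gpos[st_idx],
      strand = rep(c("+", "-"), c(length(idxC), length(idxG))),
      meth = c(methC, methG),
      fid = fid[st_idx],
      off = off[st_idx]
    )
    st <- st[keep_frag[st$fid] &
               (st$off <= RL | st$off > ins[st$fid] - RL), ]
    counts <- dplyr::summarise(
      dplyr::group_by(st, .data$position, .data$strand),
      n_meth = sum(.data$meth), n_unmeth = sum(!.data$meth),
      .groups = "drop"
    )
    truth <- dplyr::left_join(
      methylome[c("position", "strand", "true_p")], counts,
      by = c("position", "strand")
    )
    truth$n_meth[is.na(truth$n_meth)] <- 0L
    truth$n_unmeth[is.na(truth$n_unmeth)] <- 0L

    out <- structure(
      list(reads = reads, sidecar = sidecar, truth = truth,
           coverage = length(emit) * 2 * RL / span, config = config,
           region = if (linear) c(span_lo, span_hi) else NULL),
      class = "bisulfite_sim"
    )
    if (!is.null(fastq)) write_fastq_pair(reads, fastq[1], fastq[2])
    out
  })
}

#' Write paired reads as FASTQ
#'
#' Constant `I` base qualities; `.gz` suffixes trigger gzip compression.
#'
#' @param reads Tibble with `read_id`, `seq1`, `seq2`.
#' @param r1_path,r2_path Output paths.
#' @return The two paths, invisibly.
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  write_one <- function(ids, seqs, path) {
    qual <- strrep("I", nchar(seqs))
    lines <- as.vector(rbind(paste0("@", ids), seqs, "+", qual))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    writeLines(lines, con)
  }
  write_one(paste0(reads$read_id, "/1"), reads$seq1, r1_path)
  write_one(paste0(reads$read_id, "/2"), reads$seq2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a read tibble
#'
#' @param r1_path,r2_path FASTQ paths (gzip accepted). Mate suffixes
#'   (`/1`, `/2`) are stripped from identifiers.
#' @return Tibble with `read_id`, `seq1`, `seq2`.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    ids <- sub("/[12]$", "", sub("\\s.*$", "", names(x)))
    tibble::tibble(read_id = ids, seq = as.character(unname(x)))
  }
  a <- rd(r1_path)
  b <- rd(r2_path)
  if (!identical(a$read_id, b$read_id)) {
    rlang::abort("FASTQ mates are not in matching order")
  }
  tibble::tibble(read_id = a$read_id, seq1 = a$seq, seq2 = b$seq)
}

#' Long-PCR control specification
#'
#' The study's control design: the genome is covered by two overlapping
#' long-PCR amplicons (~8.5 kb each). PCR products carry no methylation, so
#' untreated amplicons are the negative (fully unmethylated) control, and
#' amplicons treated with the M.SssI CpG methyltransferase are the positive
#' control, with a per-site enzyme efficiency drawn from a Beta distribution
#' (mean 0.90 by default) rather than perfect methylation.
#'
#' @param amplicons List of `c(start, end)` 1-based inclusive intervals that
#'   jointly cover the genome.
#' @param positive_enzyme_mean Mean per-CpG methylation efficiency of the
#'   in-vitro methyltransferase.
#' @param positive_enzyme_concentration Beta concentration of the per-site
#'   efficiency.
#' @return A list of class `control_spec`.
#' @export
control_spec <- function(amplicons = list(c(1L, 9000L), c(8500L, 16569L)),
                         positive_enzyme_mean = 0.90,
                         positive_enzyme_concentration = 50) {
  stopifnot(positive_enzyme_mean >= 0, positive_enzyme_mean <= 1,
            positive_enzyme_concentration > 0)
  structure(
    list(amplicons = amplicons,
         positive_enzyme_mean = positive_enzyme_mean,
         positive_enzyme_concentration = positive_enzyme_concentration),
    class = "control_spec"
  )
}

check_amplicon_cover <- function(amplicons, L) {
  covered <- logical(L)
  for (amp in amplicons) {
    stopifnot(length(amp) == 2L)
    if (amp[1] < 1L || amp[2] > L || amp[1] >= amp[2]) {
      rlang::abort("amplicon interval outside [1, genome length]")
    }
    if (amp[2] - amp[1] + 1L >= L) {
      rlang::abort("each amplicon must be shorter than the genome")
    }
    covered[amp[1]:amp[2]] <- TRUE
  }
  if (!all(covered)) {
    gap <- range(which(!covered))
    rlang::abort(sprintf(
      "amplicons leave a coverage gap (positions %d-%d); controls must span the whole genome",
      gap[1], gap[2]
    ))
  }
  invisible(TRUE)
}

#' Simulate negative and positive long-PCR control libraries
#'
#' Negative reads are drawn only from the linear amplicon intervals with an
#' all-zero methylome (PCR erases methylation); positive reads are drawn
#' identically but with per-CpG methylation probabilities from the enzyme
#' efficiency distribution (non-CpG cytosines stay at zero). Fragments never
#' cross an amplicon end: the molecules are linear. Each amplicon is
#' sequenced to the configured mean coverage, so overlap regions receive
#' roughly double coverage, as pooled equal-mass amplicons would.
#'
#' @param genome A [circular_genome()] (the genotype being controlled).
#' @param spec A [control_spec()].
#' @param config A [read_sim_config()].
#' @param seed Integer seed.
#' @return A list of class `control_sim` with elements `negative` and
#'   `positive` (each merging reads/sidecar/truth across amplicons) and
#'   `positive_methylome`.
#' @export
simulate_controls <- function(genome, spec = control_spec(),
                              config = read_sim_config(), seed = NULL) {
  stopifnot(inherits(genome, "circular_genome"),
            inherits(spec, "control_spec"))
  L <- length(genome)
  check_amplicon_cover(spec$amplicons, L)

  neg_meth <- draw_methylome(
    genome, methylome_spec(cpg_mean = 0, non_cpg_level = 0), seed = 0L
  )
  with_seed(seed, {
    pos_meth <- neg_meth
    is_cpg <- pos_meth$context == "CpG"
    m <- spec$positive_enzyme_mean
    k <- spec$positive_enzyme_concentration
    pos_meth$true_p[is_cpg] <- if (m <= 0) 0 else if (m >= 1) 1 else {
      stats::rbeta(sum(is_cpg), m * k, (1 - m) * k)
    }

    sim_set <- function(methylome, label) {
      parts <- lapply(seq_along(spec$amplicons), function(i) {
        simulate_bisulfite_reads(
          genome, methylome, config,
          seed = sample.int(.Machine$integer.max, 1L),
          region = spec$amplicons[[i]],
          id_prefix = sprintf("%s_amp%d", label, i)
        )
      })
      truth <- dplyr::summarise(
        dplyr::group_by(
          dplyr::bind_rows(lapply(parts, `[[`, "truth")),
          .data$position, .data$strand, .data$true_p
        ),
        n_meth = sum(.data$n_meth), n_unmeth = sum(.data$n_unmeth),
        .groups = "drop"
      )
      list(
        reads = dplyr::bind_rows(lapply(parts, `[[`, "reads")),
        sidecar = dplyr::bind_rows(lapply(parts, `[[`, "sidecar")),
        truth = truth,
        coverage = sum(vapply(parts, function(p) {
          p$coverage * (p$region[2] - p$region[1] + 1)
        }, numeric(1))) / L
      )
    }

    structure(
      list(negative = sim_set(neg_meth, "neg"),
           positive = sim_set(pos_meth, "pos"),
           positive_methylome = pos_meth, spec = spec),
      class = "control_sim"
    )
  })
}

#' qPCR simulation configuration
#'
#' @param intercept_ct Ct observed at unit relative quantity.
#' @param efficiency Amplification factor per cycle, in (1, 2].
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param replicates Technical replicates per measurement.
#' @return A list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(intercept_ct = 25, efficiency = 2.0,
                            noise_sd = 0.15, replicates = 3L) {
  stopifnot(efficiency > 1, efficiency <= 2, noise_sd >= 0, replicates >= 1L)
  structure(
    list(intercept_ct = intercept_ct, efficiency = efficiency,
         noise_sd = noise_sd, replicates = as.integer(replicates)),
    class = "qpcr_sim_config"
  )
}

#' Simulate qPCR Ct values from relative quantities
#'
#' `Ct = intercept - log(quantity) / log(efficiency) + noise`: doubling the
#' template lowers Ct by one cycle at efficiency 2.
#'
#' @param quantities Named numeric vector of relative quantities (> 0), or a
#'   tibble with columns `sample` and `quantity`.
#' @param config A [qpcr_sim_config()].
#' @param seed Integer seed.
#' @return Tibble with `sample`, `replicate`, `ct`.
#' @export
simulate_qpcr_ct <- function(quantities, config = qpcr_sim_config(),
                             seed = NULL) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  if (is.data.frame(quantities)) {
    q <- quantities$quantity
    names(q) <- quantities$sample
    quantities <- q
  }
  if (any(quantities <= 0)) {
    rlang::abort("relative quantities must be positive")
  }
  n <- length(quantities)
  reps <- config$replicates
  with_seed(seed, {
    ct0 <- config$intercept_ct - log(quantities) / log(config$efficiency)
    tibble::tibble(
      sample = rep(names(quantities) %||% as.character(seq_len(n)),
                   each = reps),
      replicate = rep(seq_len(reps), times = n),
      ct = rep(unname(ct0), each = reps) +
        stats::rnorm(n * reps, 0, config$noise_sd)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
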