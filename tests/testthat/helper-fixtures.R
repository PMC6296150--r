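# shared fixtures: everything is generated in code at test time

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small test reference: 4 kb circular genome with 100 planted CpGs
test_reference <- function(seed = 42L, length = 4000L, n_cpg = 100L, ...) {
  synthetic_reference_genome(length = length, n_cpg = n_cpg, seed = seed,
                             name = "testref", ...)
}

# align -> dedup -> extract shortcut
pipeline_calls <- function(sim, genome, ...) {
  aln <- align_bisulfite(sim$reads, genome, ...)
  extract_methylation(deduplicate(aln), sim$reads, genome)
}

# low-coverage config for fast unit tests
quick_cfg <- function(mean_coverage = 30, ...) {
  read_sim_config(mean_coverage = mean_coverage, ...)
}

# bisulfite-convert a top-strand chunk, protecting plus-strand CpG cytosines
# (emulates a fully methylated-at-CpG, fully converted-elsewhere molecule)
convert_protect_cpg <- function(genome, start, len) {
  dbl <- paste0(genome$sequence, genome$sequence)
  ch <- strsplit(substr(dbl, start, start + len - 1L), "")[[1]]
  gpos <- ((start + seq_len(len) - 2L) %% length(genome)) + 1L
  cg <- cpg_sites(genome)
  protected <- gpos %in% cg$position[cg$strand == "+"]
  conv <- ch == "C" & !protected
  ch[conv] <- "T"
  paste(ch, collapse = "")
}

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
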