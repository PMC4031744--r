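# Shared fixtures, generated once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small trio for fast structural tests (not used for recall assertions)
small_trio <- function() fixture("small_trio", function() {
  spec <- simulation_spec(reference_length = 30000L, n_genes = 3L,
                          coverage = 40L, n_denovo_snv = 2L,
                          n_denovo_indel = 1L, seed = 42L)
  sim <- simulate_trio(spec)
  list(spec = spec, sim = sim)
})

# the default study conditions: 100 kb, 80x, 0.5% error, 5 de novo SNVs +
# 1 small indel at VAF 0.5
default_trio <- function() fixture("default_trio", function() {
  spec <- simulation_spec(seed = 1L)
  sim <- simulate_trio(spec)
  run <- run_trio(sim$reads$proband, sim$reads$mother, sim$reads$father,
                  sim$reference, sim$targets, vectors = sim$vectors,
                  gene_models = sim$genes)
  list(spec = spec, sim = sim, run = run)
})

# brute-force canonical k-mer census, independent of the package's
# counter: string windows + Biostrings reverse complement + table()
oracle_count_kmers <- function(seqs, k) {
  wins <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }))
  wins <- wins[!grepl("[^ACGT]", wins)]
  if (!length(wins))
    return(data.frame(kmer = character(), count = integer()))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(wins)))
  canon <- ifelse(wins <= rc, wins, rc)
  tab <- table(canon)
  data.frame(kmer = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)[order(names(tab), method = "radix"), ]
}

random_reads <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

random_kmer_table <- function(n, k) {
  km <- unique(random_reads(n, k))
  km <- canonicalize(km)
  km <- unique(km)
  kmer_table(km, sample.int(50L, length(km), replace = TRUE), k)
}

# classification rule shared with the annotation oracle
classify_aa <- function(aa0, aa1) {
  if (aa0 == aa1) "synonymous" else if (aa1 == "*") "nonsense"
  else "missense"
}
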